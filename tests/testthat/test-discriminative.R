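test_that("pooling weights follow the closed form", {
  expect_equal(pooling_weights(3), c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(pooling_weights(1), 1)
  expect_error(pooling_weights(0), "positive")
  for (T_ in c(2, 17, 400, 10000)) {
    w <- pooling_weights(T_)
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_true(all(diff(w) > 0))
    expect_equal(w, seq_len(T_) / (T_ * (T_ + 1) / 2))
  }
})

test_that("echo embedding pools only the second copy with position weights", {
  tok <- word_tokenizer("one two three")
  lm <- tiny_lm(length(tok$vocab), dim = 5, hidden = 7, seed = 11)
  prompt <- "one two three"
  phi <- echo_embed(lm, prompt, tok)
  # direct weighted-sum oracle over the hidden states of the doubled input
  e <- encode(tok, prompt)
  ids <- c(tok$bos_id, e, tok$sep_id, e)
  h <- hidden_states(lm, ids)
  rows <- (length(e) + 2) + seq_along(e)
  expect_equal(phi, as.numeric(h[rows[1], ] / 6 + 2 * h[rows[2], ] / 6 +
                                 3 * h[rows[3], ] / 6),
               tolerance = 1e-12)
  # determinism
  expect_identical(phi, echo_embed(lm, prompt, tok))
  # one-token second copy: the pooled embedding is that token's hidden state
  phi1 <- echo_embed(lm, "two", tok)
  ids1 <- c(tok$bos_id, encode(tok, "two"), tok$sep_id, encode(tok, "two"))
  expect_equal(phi1, as.numeric(hidden_states(lm, ids1)[4, ]))
})

test_that("pooling is position-sensitive", {
  tok <- word_tokenizer("one two three")
  lm <- tiny_lm(length(tok$vocab), dim = 5, hidden = 7, seed = 11)
  expect_false(isTRUE(all.equal(echo_embed(lm, "one two three", tok),
                                echo_embed(lm, "three two one", tok))))
})

test_that("an untrained zero head yields a uniform distribution", {
  cat <- make_ontology(2, 4, 8, seed = 1)
  tok <- word_tokenizer(cat$entries$title)
  lm <- tiny_lm(length(tok$vocab), dim = 5, hidden = 7, seed = 1)
  clf <- structure(list(model = lm,
                        head = unclass(classifier_head(7, cat$entries$code))[c("W", "b")],
                        labels = cat$entries$code,
                        template = default_template(), tokenizer = tok),
                   class = "icd_classifier")
  d <- classify(clf, certificate("anything"))
  expect_equal(unname(as.numeric(d)), rep(1 / 8, 8))
  expect_equal(attr(d, "provenance"), "discriminative")
})

test_that("classify returns normalized full-support distributions", {
  pipe <- recovery_pipeline()
  recs <- pipe$split$test[1:100]
  res <- classify_all(pipe$classifier, recs)
  expect_equal(unname(rowSums(res$distributions)), rep(1, 100), tolerance = 1e-6)
  expect_true(all(res$distributions > 0))  # full support, unlike generative
  expect_equal(ncol(res$distributions), length(pipe$classifier$labels))
})

test_that("classifier gradients match finite differences through the pooled path", {
  tok <- word_tokenizer("alpha beta gamma delta")
  lm <- tiny_lm(length(tok$vocab), dim = 4, hidden = 5, seed = 13)
  labels <- c("A00", "A01")
  Wc <- matrix(stats::rnorm(5 * 2, sd = 0.3), 5, 2)
  ei <- gencoder:::echo_ids(tok, "alpha beta gamma", "<sep>")
  y <- 2L
  loss_fn <- function(m, W) {
    h <- hidden_states(m, ei$ids)
    w <- pooling_weights(length(ei$rows))
    phi <- as.numeric(crossprod(h[ei$rows, , drop = FALSE], w))
    -gencoder:::log_softmax_vec(as.numeric(phi %*% W))[y]
  }
  # analytic gradient for the backbone
  fw <- gencoder:::lm_forward(lm, ei$ids)
  w <- pooling_weights(length(ei$rows))
  phi <- as.numeric(crossprod(fw$h[ei$rows, , drop = FALSE], w))
  pr <- exp(gencoder:::log_softmax_vec(as.numeric(phi %*% Wc)))
  dlog <- pr; dlog[y] <- dlog[y] - 1
  dphi <- as.numeric(Wc %*% dlog)
  dh <- matrix(0, length(ei$ids), 5)
  dh[ei$rows, ] <- outer(w, dphi)
  g <- gencoder:::lm_backward(lm, ei$ids, fw, dh_extra = dh)
  dE <- matrix(0, length(tok$vocab), 4)
  rs <- rowsum(g$de, g$x)
  dE[as.integer(rownames(rs)), ] <- rs
  grads <- list(E = dE, W1 = g$dW1, b1 = g$db1)
  h_ <- 1e-5
  for (k in names(grads)) {
    set.seed(7)
    for (r in 1:10) {
      i <- sample(length(lm$params[[k]]), 1)
      mp <- lm; mp$params[[k]][i] <- mp$params[[k]][i] + h_
      mm <- lm; mm$params[[k]][i] <- mm$params[[k]][i] - h_
      fd <- (loss_fn(mp, Wc) - loss_fn(mm, Wc)) / (2 * h_)
      expect_equal(grads[[k]][i], fd, tolerance = 1e-5)
    }
  }
})

test_that("a two-class separable problem is fit to training accuracy 1", {
  cat <- make_ontology(2, 2, 2, seed = 17)
  records <- sample_certificates(cat, 120, zipf = 0, noise = 0, multi_rate = 0,
                                 seed = 17)
  tpl <- default_template()
  tok <- corpus_tokenizer(records, cat, tpl)
  lm <- tiny_lm(length(tok$vocab), dim = 8, hidden = 12, seed = 17)
  clf <- fine_tune_classifier(lm, records, tpl, tok,
                              train_config(lr = 5e-2, epochs_finetune = 8,
                                           patience = 8, seed = 17))
  res <- classify_all(clf, records)
  gold <- vapply(records, function(r) r$gold_ucod, character(1))
  expect_equal(mean(res$codes == gold), 1)
})

test_that("classifier checkpoints round-trip", {
  cat <- make_ontology(2, 2, 2, seed = 17)
  records <- sample_certificates(cat, 40, zipf = 0, noise = 0, multi_rate = 0,
                                 seed = 17)
  tpl <- default_template()
  tok <- corpus_tokenizer(records, cat, tpl)
  lm <- tiny_lm(length(tok$vocab), dim = 6, hidden = 8, seed = 17)
  clf <- fine_tune_classifier(lm, records, tpl, tok,
                              train_config(lr = 5e-2, epochs_finetune = 2,
                                           patience = 2, seed = 17))
  dir <- withr::local_tempdir()
  save_classifier(clf, dir)
  back <- load_classifier(dir)
  r <- records[[1]]
  expect_equal(as.numeric(classify(back, r)), as.numeric(classify(clf, r)),
               tolerance = 1e-12)
  expect_identical(back$labels, clf$labels)
})
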
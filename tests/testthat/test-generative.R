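test_that("sequence score is the mean token log-probability", {
  expect_equal(sequence_score(c(-1.0, -2.0)), -1.5)
  expect_equal(sequence_score(-0.7), -0.7)
  expect_error(sequence_score(numeric(0)), "empty")
  expect_error(sequence_score(c(-1, -Inf)), "non-finite")
})

test_that("sampled sequence scores match the chain-rule joint log-probability", {
  cat <- toy_catalog()
  tok <- word_tokenizer(c(cat$entries$title, "chest pain answer :"))
  trie <- build_trie(cat, tok)
  lm <- tiny_lm(length(tok$vocab), dim = 6, hidden = 8, seed = 6)
  prompt <- c(tok$bos_id, encode(tok, "chest pain answer :"))
  scored <- constrained_sample(lm, trie, prompt, decoding_config(k = 6, seed = 1))
  for (s in scored) {
    # chain rule: per-step log-probability from the full prefix each time
    lps <- vapply(seq_along(s$ids), function(j) {
      next_token_logprobs(lm, c(prompt, s$ids[seq_len(j - 1L)]))[s$ids[j]]
    }, numeric(1))
    expect_equal(s$score, mean(lps), tolerance = 1e-9)
    expect_equal(s$score, sum(lps) / length(lps), tolerance = 1e-9)
  }
})

test_that("constrained sampling is seeded, merged by code, and trie-valid", {
  cat <- make_ontology(3, 8, 40, seed = 2)
  tok <- word_tokenizer(c(cat$entries$title, "prompt words"))
  trie <- build_trie(cat, tok)
  lm <- tiny_lm(length(tok$vocab), dim = 8, hidden = 10, seed = 2)
  prompt <- c(tok$bos_id, encode(tok, "prompt words"))
  a <- constrained_sample(lm, trie, prompt, decoding_config(seed = 9))
  b <- constrained_sample(lm, trie, prompt, decoding_config(seed = 9))
  expect_identical(a, b)
  codes <- vapply(a, `[[`, character(1), "code")
  expect_false(anyDuplicated(codes) > 0)
  expect_true(all(codes %in% cat$entries$code))
  expect_lte(length(a), 10)
  # scores sorted decreasing
  sc <- vapply(a, `[[`, numeric(1), "score")
  expect_true(all(diff(sc) <= 0))
})

test_that("uniform model on the toy trie reaches both branch codes", {
  cat <- toy_catalog()
  tok <- toy_tokenizer(cat)
  trie <- restrict_trie(build_trie(cat, tok), c("I21", "I64"))
  lm <- tiny_lm(length(tok$vocab), dim = 4, hidden = 4, seed = 1)
  lm$params <- lapply(lm$params, function(p) p * 0)  # exactly uniform logits
  prompt <- encode(tok, "acute")
  scored <- constrained_sample(lm, trie, prompt, decoding_config(k = 50, seed = 3))
  expect_setequal(vapply(scored, `[[`, character(1), "code"), c("I21", "I64"))
})

test_that("code distribution matches the hand-computed softmax", {
  cat <- toy_catalog()
  scored <- list(list(code = "I21", score = -1.5),
                 list(code = "I64", score = -1.6))
  d <- code_distribution(scored, cat, temperature = 0.01)
  expect_equal(unname(d["I21"]), 1 / (1 + exp(-10)), tolerance = 1e-9)
  expect_equal(unname(d["I64"]), exp(-10) / (1 + exp(-10)), tolerance = 1e-9)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(unname(d["C80.9"]), 0)
  expect_equal(attr(d, "provenance"), "generative")

  single <- code_distribution(list(list(code = "I64", score = -2)), cat, 0.01)
  expect_equal(unname(single["I64"]), 1)

  equal3 <- code_distribution(list(list(code = "I21", score = -1),
                                   list(code = "I64", score = -1),
                                   list(code = "C80.9", score = -1)), cat, 0.5)
  expect_equal(unname(equal3[cat$entries$code]), rep(1 / 3, 3))
  expect_error(code_distribution(scored, cat, temperature = 0), "positive")
})

test_that("temperature limit gives a point mass on the best-scored code", {
  cat <- toy_catalog()
  scored <- list(list(code = "I21", score = -1.2),
                 list(code = "I64", score = -1.3),
                 list(code = "C80.9", score = -4))
  d <- code_distribution(scored, cat, temperature = 1e-6)
  expect_equal(unname(d["I21"]), 1)
})

test_that("distribution argmax equals the best-scored sequence across random draws", {
  cat <- make_ontology(3, 10, 30, seed = 4)
  set.seed(4)
  for (i in 1:1000) {
    n <- sample(1:10, 1)
    codes <- sample(cat$entries$code, n)
    scores <- stats::rnorm(n, -2, 1)
    scored <- Map(function(cd, s) list(code = cd, score = s), codes, scores)
    d <- code_distribution(scored, cat, temperature = 0.01)
    expect_equal(names(which.max(d)), codes[which.max(scores)])
    expect_equal(sum(d), 1, tolerance = 1e-9)
    expect_lte(sum(d > 0), n)
  }
})

test_that("restricting the trie restricts the support of predictions", {
  pipe_cat <- make_ontology(3, 8, 40, seed = 2)
  tok <- word_tokenizer(c(pipe_cat$entries$title, "prompt words answer :"))
  trie <- build_trie(pipe_cat, tok)
  lm <- tiny_lm(length(tok$vocab), dim = 8, hidden = 10, seed = 2)
  keep <- sample(pipe_cat$entries$code, 12)
  sub <- restrict_trie(trie, keep)
  r <- certificate("prompt words", gold_ucod = pipe_cat$entries$code[1])
  pr <- predict_ucod(lm, sub, r, default_template(), tok,
                     decoding_config(seed = 5), pipe_cat)
  expect_true(all(names(pr$distribution)[pr$distribution > 0] %in% keep))
  expect_true(pr$code %in% keep)
  # single-code restriction: that code with probability one
  one <- restrict_trie(trie, keep[1])
  pr1 <- predict_ucod(lm, one, r, default_template(), tok,
                      decoding_config(seed = 5), pipe_cat)
  expect_equal(pr1$code, keep[1])
  expect_equal(unname(pr1$distribution[keep[1]]), 1)
})

test_that("multi-cause generation memorizes small multi-label corpora", {
  cat <- make_ontology(2, 4, 10, seed = 21)
  tpl <- default_template()
  cd <- cat$entries$code
  base <- list(
    certificate("field one", part2 = "other conditions", gold_ucod = cd[1],
                gold_causes = cd[c(1, 5)], id = "a"),
    certificate("field two", gold_ucod = cd[2],
                gold_causes = cd[c(2, 7, 9)], id = "b"),
    certificate("field three", gold_ucod = cd[4],
                gold_causes = cd[4], id = "c")
  )
  records <- rep(base, 40)
  tok <- corpus_tokenizer(records, cat, tpl)
  trie <- build_trie(cat, tok)
  texts <- vapply(records, render_training_text, character(1),
                  template = tpl, task = "causes", catalog = cat)
  lm <- tiny_lm(length(tok$vocab), dim = 10, hidden = 20, seed = 21)
  res <- train_causal(lm, texts, tok, train_config(lr = 5e-2, epochs_pretrain = 30,
                                                   patience = 30, seed = 21),
                      val_texts = texts[1:3])
  for (r in base) {
    got <- predict_multiple_causes(res$model, trie, r, tpl, tok,
                                   decoding_config(seed = 13, top_k = 1), cat)
    expect_setequal(got, r$gold_causes)
  }
})
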
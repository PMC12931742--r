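#' Position-weighted pooling weights
#'
#' Weight of token `i` among `T` tokens is `i / (1 + 2 + ... + T)`, i.e.
#' `i / (T (T + 1) / 2)` with 1-based positions: weights sum to one and grow
#' linearly, so tokens at the end of the prompt are given more importance than
#' the initial ones.
#'
#' @param T_ number of tokens (>= 1).
#' @return Numeric vector of length `T_` summing to 1.
#' @export
#' @examples
#' pooling_weights(3) # 1/6, 1/3, 1/2
pooling_weights <- function(T_) {
  if (length(T_) != 1 || is.na(T_) || T_ < 1) {
    stop("argument error: T must be a positive integer")
  }
  seq_len(T_) / (T_ * (T_ + 1) / 2)
}

echo_ids <- function(tokenizer, prompt, separator = "<sep>") {
  e <- encode(tokenizer, prompt)
  sep <- encode(tokenizer, separator)
  ids <- c(tokenizer$bos_id, e, sep, e)
  rows <- (1L + length(e) + length(sep)) + seq_along(e)
  list(ids = ids, rows = rows)
}

#' Echo embedding of a prompt
#'
#' The prompt is repeated twice around a separator; because the model is
#' autoregressive, tokens of the second copy can attend over the complete
#' first copy, emulating bidirectional context. Only the second copy's hidden
#' states are pooled, with [pooling_weights()].
#'
#' @param lm a `tiny_lm`.
#' @param prompt prompt text (the full rendered prompt, instruction and output
#'   prefix included).
#' @param tokenizer a `word_tokenizer`.
#' @param separator separator between the two copies (default `"<sep>"`).
#' @return Numeric vector: the pooled document embedding.
#' @export
echo_embed <- function(lm, prompt, tokenizer, separator = "<sep>") {
  ei <- echo_ids(tokenizer, prompt, separator)
  h <- hidden_states(lm, ei$ids)
  w <- pooling_weights(length(ei$rows))
  as.numeric(crossprod(h[ei$rows, , drop = FALSE], w))
}

#' Linear classification head
#'
#' @param hidden backbone hidden width.
#' @param labels character vector: the label space (code strings).
#' @return A `classifier_head` (zero-initialized: before any training the
#'   output distribution is uniform).
#' @export
classifier_head <- function(hidden, labels) {
  structure(list(W = matrix(0, hidden, length(labels)),
                 b = numeric(length(labels)), labels = labels),
            class = "classifier_head")
}

#' Fine-tune the backbone and classification head
#'
#' Trains all parameters of the language model jointly with a linear
#' classification head on the echo embedding, minimizing categorical
#' cross-entropy. Training monitors macro-F1 (full-code level) over the
#' validation records and stops early with the configured patience, returning
#' the best-validation checkpoint.
#'
#' @param lm a `tiny_lm` (typically after continual pre-training).
#' @param records list of labeled `certificate` objects (training split).
#' @param template a `prompt_template`.
#' @param tokenizer a `word_tokenizer`.
#' @param config a [train_config()].
#' @param val_records validation records; when `NULL`, `config$val_frac` of
#'   `records` is held out.
#' @param labels label space; defaults to the codes observed in `records`
#'   (every assignable code is guaranteed to appear in training data).
#' @param freeze_backbone if `TRUE`, only the head is trained (ablation; off
#'   by default because the reference procedure trains all parameters).
#' @param verbose print per-epoch validation macro-F1.
#' @return An object of class `icd_classifier` with elements `model`, `head`,
#'   `labels`, `history`.
#' @export
fine_tune_classifier <- function(lm, records, template, tokenizer,
                                 config = train_config(), val_records = NULL,
                                 labels = NULL, freeze_backbone = FALSE,
                                 verbose = FALSE) {
  if (length(records) == 0) stop("data error: no training records")
  golds <- vapply(records, function(r) r$gold_ucod, character(1))
  if (anyNA(golds)) stop("data error: record without gold_ucod")
  if (is.null(labels)) labels <- sort(unique(golds))
  if (!all(golds %in% labels)) {
    stop("data error: gold label outside the classifier's label space: ",
         paste(setdiff(golds, labels), collapse = ", "))
  }
  set.seed(config$seed)
  if (is.null(val_records)) {
    n_val <- max(1L, floor(length(records) * config$val_frac))
    vi <- sample(length(records), n_val)
    val_records <- records[vi]
    records <- records[-vi]
    golds <- golds[-vi]
  }
  val_gold <- vapply(val_records, function(r) r$gold_ucod, character(1))
  enc <- lapply(records, function(r) {
    echo_ids(tokenizer, render_prompt(r, template, "ucod"), template$echo_separator)
  })
  val_enc <- lapply(val_records, function(r) {
    echo_ids(tokenizer, render_prompt(r, template, "ucod"), template$echo_separator)
  })
  y <- match(golds, labels)
  head <- classifier_head(lm$hidden, labels)
  params <- lm$params
  Wc <- head$W; bc <- head$b
  opt <- adamw_init(params)
  optc <- list(m = list(W = Wc * 0, b = bc * 0), v = list(W = Wc * 0, b = bc * 0), t = 0L)
  best <- list(f1 = -Inf, params = params, Wc = Wc, bc = bc, epoch = 0L)
  val_hist <- numeric(0)
  hist <- list()
  nlab <- length(labels)
  for (epoch in seq_len(config$epochs_finetune)) {
    ord <- sample(length(enc))
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      acc <- zero_grads(params)
      dWc <- Wc * 0; dbc <- bc * 0
      lm$params <- params
      for (j in idx) {
        ei <- enc[[j]]
        fw <- lm_forward(lm, ei$ids)
        w <- pooling_weights(length(ei$rows))
        h2 <- fw$h[ei$rows, , drop = FALSE]
        phi <- as.numeric(crossprod(h2, w))
        logits <- as.numeric(phi %*% Wc) + bc
        pr <- exp(log_softmax_vec(logits))
        dlog <- pr
        dlog[y[j]] <- dlog[y[j]] - 1
        dWc <- dWc + outer(phi, dlog)
        dbc <- dbc + dlog
        if (!freeze_backbone) {
          dphi <- as.numeric(Wc %*% dlog)
          dh <- matrix(0, length(ei$ids), lm$hidden)
          dh[ei$rows, ] <- outer(w, dphi)
          acc <- acc_grads(acc, lm_backward(lm, ei$ids, fw, dh_extra = dh))
        }
      }
      nb <- length(idx)
      if (!freeze_backbone) {
        st <- adamw_step(params, lapply(acc, function(g) g / nb), opt,
                         config$lr, config$weight_decay)
        params <- st$params; opt <- st$opt
      }
      stc <- adamw_step(list(W = Wc, b = bc), list(W = dWc / nb, b = dbc / nb),
                        optc, config$lr, config$weight_decay)
      Wc <- stc$params$W; bc <- stc$params$b
      optc <- stc$opt
      i <- i + config$batch_size
    }
    lm$params <- params
    clf <- structure(list(model = lm, head = list(W = Wc, b = bc),
                          labels = labels, template = template,
                          tokenizer = tokenizer),
                     class = "icd_classifier")
    val_pred <- vapply(val_enc, function(ei) {
      labels[which.max(classify_ids(clf, ei))]
    }, character(1))
    f1 <- macro_f1(val_pred, val_gold)
    hist[[epoch]] <- c(epoch = epoch, val_macro_f1 = f1)
    if (verbose) message(sprintf("epoch %d: val macro-F1 %.4f", epoch, f1))
    val_hist <- c(val_hist, -f1)
    if (f1 > best$f1) {
      best <- list(f1 = f1, params = params, Wc = Wc, bc = bc, epoch = epoch)
    }
    if (stop_early(val_hist, config$patience)) break
  }
  lm$params <- best$params
  h <- do.call(rbind, hist)
  structure(list(model = lm, head = list(W = best$Wc, b = best$bc),
                 labels = labels, template = template, tokenizer = tokenizer,
                 history = tibble::tibble(epoch = h[, "epoch"],
                                          val_macro_f1 = h[, "val_macro_f1"]),
                 best_epoch = best$epoch),
            class = "icd_classifier")
}

# logits -> probabilities for pre-encoded echo ids
classify_ids <- function(classifier, ei) {
  h <- hidden_states(classifier$model, ei$ids)
  w <- pooling_weights(length(ei$rows))
  phi <- as.numeric(crossprod(h[ei$rows, , drop = FALSE], w))
  exp(log_softmax_vec(as.numeric(phi %*% classifier$head$W) + classifier$head$b))
}

#' Classify a record with the fine-tuned discriminative coder
#'
#' @param classifier an `icd_classifier`.
#' @param record a `certificate`.
#' @param template optional template override (defaults to the one used for
#'   training).
#' @return A `code_distribution` over the classifier's label space (full
#'   support), provenance `"discriminative"`.
#' @export
classify <- function(classifier, record, template = NULL) {
  stopifnot(inherits(classifier, "icd_classifier"))
  tpl <- if (is.null(template)) classifier$template else template
  ei <- echo_ids(classifier$tokenizer, render_prompt(record, tpl, "ucod"),
                 tpl$echo_separator)
  p <- classify_ids(classifier, ei)
  structure(stats::setNames(p, classifier$labels),
            provenance = "discriminative", class = "code_distribution")
}

#' Batch classification
#'
#' @param classifier an `icd_classifier`.
#' @param records list of `certificate` objects.
#' @return List with `codes` (argmax predictions) and `distributions`
#'   (matrix records x labels).
#' @export
classify_all <- function(classifier, records) {
  dists <- matrix(0, length(records), length(classifier$labels),
                  dimnames = list(NULL, classifier$labels))
  for (i in seq_along(records)) {
    dists[i, ] <- as.numeric(classify(classifier, records[[i]]))
  }
  list(codes = classifier$labels[max.col(dists, ties.method = "first")],
       distributions = dists)
}

#' @export
print.icd_classifier <- function(x, ...) {
  cat(sprintf("<icd_classifier> %d labels, hidden %d\n",
              length(x$labels), x$model$hidden))
  invisible(x)
}
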
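#' Training configuration
#'
#' Defaults follow the study settings used throughout the package: effective
#' batch size 32, AdamW with a constant learning rate of 2e-5 and no warm-up,
#' continual pre-training for at most 5 epochs monitoring validation loss,
#' fine-tuning for at most 20 epochs monitoring validation macro-F1, and early
#' stopping with a patience of 2 epochs in both phases. The 2e-5 rate is a
#' setting for billion-parameter backbones; the desk-scale reference model
#' trains from scratch and is normally run with a larger rate (see the methods
#' vignette), which is why `lr` is a plain parameter here.
#'
#' @param batch_size effective batch size (realized by gradient accumulation).
#' @param lr constant learning rate for AdamW.
#' @param epochs_pretrain maximum causal pre-training epochs.
#' @param epochs_finetune maximum classifier fine-tuning epochs.
#' @param patience early-stopping patience (epochs without improvement).
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_frac fraction of the corpus held out for validation when no
#'   explicit validation set is given.
#' @param seed RNG seed for initialization and data order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, lr = 2e-5, epochs_pretrain = 5,
                         epochs_finetune = 20, patience = 2,
                         weight_decay = 0.01, val_frac = 0.1, seed = 1L) {
  stopifnot(batch_size >= 1, lr > 0, epochs_pretrain >= 1,
            epochs_finetune >= 1, patience >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Tiny reference causal language model
#'
#' A small self-contained autoregressive model used for desk-scale
#' experiments. At each position `t` the prediction input is the pair
#' (mean of the embeddings of tokens 1..t, embedding of token t): a global
#' bag-of-context channel plus a local channel, passed through one tanh layer.
#' The LM head projects the hidden state to vocabulary logits; the same hidden
#' states serve as the contextual token embeddings pooled by the
#' discriminative coder. The model is causal by construction (position `t`
#' sees only tokens 1..t) and reproducible under a fixed seed.
#'
#' @param vocab_size vocabulary size.
#' @param dim embedding dimension (default 24).
#' @param hidden hidden-layer width (default 64).
#' @param seed RNG seed for initialization.
#' @return An object of class `tiny_lm` satisfying the causal-LM contract:
#'   [next_token_logprobs()] and [hidden_states()].
#' @export
tiny_lm <- function(vocab_size, dim = 24, hidden = 64, seed = 1L) {
  stopifnot(vocab_size >= 2, dim >= 1, hidden >= 1)
  set.seed(seed)
  init <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)
  params <- list(
    E  = init(vocab_size, dim, 0.3),
    W1 = init(2 * dim, hidden, 1 / sqrt(2 * dim)),
    b1 = numeric(hidden),
    W2 = init(hidden, vocab_size, 1 / sqrt(hidden)),
    b2 = numeric(vocab_size)
  )
  structure(list(params = params, vocab_size = as.integer(vocab_size),
                 dim = as.integer(dim), hidden = as.integer(hidden),
                 seed = as.integer(seed)),
            class = "tiny_lm")
}

#' @export
print.tiny_lm <- function(x, ...) {
  cat(sprintf("<tiny_lm> vocab %d, dim %d, hidden %d\n",
              x$vocab_size, x$dim, x$hidden))
  invisible(x)
}

log_softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  logits - (mx + log(rowSums(exp(logits - mx))))
}

log_softmax_vec <- function(logits) {
  mx <- max(logits)
  logits - (mx + log(sum(exp(logits - mx))))
}

# Full forward pass; returns intermediates needed for backprop.
lm_forward <- function(lm, x) {
  p <- lm$params
  T_ <- length(x)
  e <- p$E[x, , drop = FALSE]
  cs <- if (T_ == 1L) e else apply(e, 2, cumsum)
  m <- cs / seq_len(T_)
  inp <- cbind(m, e)
  h <- tanh(inp %*% p$W1 + rep(p$b1, each = T_))
  logits <- h %*% p$W2 + rep(p$b2, each = T_)
  list(e = e, inp = inp, h = h, logp = log_softmax_rows(logits))
}

#' Next-token log-probabilities
#'
#' @param lm a `tiny_lm`.
#' @param prefix non-empty integer vector of token ids.
#' @return Numeric vector of log-probabilities over the vocabulary
#'   (log-sum-exp equals 0 up to floating-point error).
#' @export
next_token_logprobs <- function(lm, prefix) {
  stopifnot(length(prefix) >= 1)
  p <- lm$params
  e_last <- p$E[prefix[length(prefix)], ]
  m_last <- colMeans(p$E[prefix, , drop = FALSE])
  h <- tanh(as.vector(c(m_last, e_last) %*% p$W1) + p$b1)
  log_softmax_vec(as.vector(h %*% p$W2) + p$b2)
}

#' Per-token contextual hidden states
#'
#' @param lm a `tiny_lm`.
#' @param ids non-empty integer vector of token ids.
#' @return A `length(ids) x hidden` matrix; row `t` depends only on tokens
#'   `1..t`.
#' @export
hidden_states <- function(lm, ids) {
  stopifnot(length(ids) >= 1)
  lm_forward(lm, ids)$h
}

# Incremental decoding state: running embedding sum avoids re-encoding the
# prompt at every generation step.
lm_state_init <- function(lm, ids) {
  list(sum_e = colSums(lm$params$E[ids, , drop = FALSE]),
       t = length(ids), last = ids[length(ids)])
}

lm_state_step <- function(lm, state, id) {
  list(sum_e = state$sum_e + lm$params$E[id, ],
       t = state$t + 1L, last = id)
}

lm_state_logprobs <- function(lm, state) {
  p <- lm$params
  h <- tanh(as.vector(c(state$sum_e / state$t, p$E[state$last, ]) %*% p$W1) + p$b1)
  log_softmax_vec(as.vector(h %*% p$W2) + p$b2)
}

# Early-stopping rule shared by both training loops: stop after the epoch at
# which the best monitored value is `patience` epochs old. `history` is the
# per-epoch monitored quantity, oriented so that smaller is better.
stop_early <- function(history, patience) {
  length(history) - which.min(history) >= patience
}

zero_grads <- function(params) {
  list(E = array(0, dim(params$E)), W1 = array(0, dim(params$W1)),
       b1 = numeric(length(params$b1)), W2 = array(0, dim(params$W2)),
       b2 = numeric(length(params$b2)))
}

# Backprop through one sequence. Upstream gradients may arrive on the logits
# (language modeling) and/or directly on the hidden states (pooled classifier).
# Returns per-parameter gradients; the embedding gradient comes back as the
# dense per-position matrix `de` plus the token index `x` so the caller can
# scatter-add cheaply.
lm_backward <- function(lm, x, fw, dlogits = NULL, dh_extra = NULL) {
  p <- lm$params
  T_ <- length(x)
  d <- lm$dim
  dh <- if (is.null(dh_extra)) matrix(0, T_, lm$hidden) else dh_extra
  dW2 <- NULL; db2 <- NULL
  if (!is.null(dlogits)) {
    dW2 <- crossprod(fw$h, dlogits)
    db2 <- colSums(dlogits)
    dh <- dh + dlogits %*% t(p$W2)
  }
  dpre <- dh * (1 - fw$h^2)
  dW1 <- crossprod(fw$inp, dpre)
  db1 <- colSums(dpre)
  dinp <- dpre %*% t(p$W1)
  dm <- dinp[, seq_len(d), drop = FALSE]
  de <- dinp[, d + seq_len(d), drop = FALSE]
  g <- dm / seq_len(T_)
  # mean channel: e_i feeds every m_t with t >= i, weight 1/t
  rev_cumsum <- if (T_ == 1L) g else apply(g[T_:1, , drop = FALSE], 2, cumsum)[T_:1, , drop = FALSE]
  de <- de + rev_cumsum
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, de = de, x = x)
}

acc_grads <- function(acc, g) {
  acc$W1 <- acc$W1 + g$dW1
  acc$b1 <- acc$b1 + g$db1
  if (!is.null(g$dW2)) {
    acc$W2 <- acc$W2 + g$dW2
    acc$b2 <- acc$b2 + g$db2
  }
  rs <- rowsum(g$de, g$x)
  rows <- as.integer(rownames(rs))
  acc$E[rows, ] <- acc$E[rows, , drop = FALSE] + rs
  acc
}

adamw_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adamw_step <- function(params, grads, opt, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (k in names(grads)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    step <- (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + eps)
    params[[k]] <- params[[k]] - lr * (step + weight_decay * params[[k]])
  }
  list(params = params, opt = opt)
}

#' Mean next-token cross-entropy over a set of encoded sequences
#'
#' The loss is applied to every token of every instance (prompt and expected
#' output alike): each sequence is prefixed with `<bos>` so that all of its
#' own tokens are predicted.
#'
#' @param lm a `tiny_lm`.
#' @param ids_list list of integer token-id vectors (each already starting
#'   with `<bos>`).
#' @return Mean cross-entropy per predicted token (nats).
#' @export
causal_loss <- function(lm, ids_list) {
  tot <- 0; ntok <- 0L
  for (ids in ids_list) {
    T_ <- length(ids)
    if (T_ < 2L) next
    fw <- lm_forward(lm, ids[-T_])
    tot <- tot - sum(fw$logp[cbind(seq_len(T_ - 1L), ids[-1L])])
    ntok <- ntok + T_ - 1L
  }
  tot / ntok
}

encode_corpus <- function(tokenizer, texts) {
  lapply(texts, function(t) c(tokenizer$bos_id, encode(tokenizer, t)))
}

#' Continual causal pre-training
#'
#' Trains the model with the causal language-modeling objective (next-token
#' prediction, cross-entropy over all tokens of each instance) using AdamW
#' with a constant learning rate, monitoring the loss over a validation set
#' and stopping early when it fails to improve for `config$patience`
#' consecutive epochs. The parameters from the best validation epoch are
#' returned.
#'
#' @param lm a `tiny_lm`.
#' @param texts character vector of training texts.
#' @param tokenizer a `word_tokenizer`.
#' @param config a [train_config()].
#' @param val_texts optional explicit validation texts; when `NULL` a fraction
#'   `config$val_frac` of `texts` is held out.
#' @param verbose print per-epoch losses.
#' @return List with elements `model` (the trained `tiny_lm`) and `history`
#'   (tibble: epoch, train_loss, val_loss).
#' @export
train_causal <- function(lm, texts, tokenizer, config = train_config(),
                         val_texts = NULL, verbose = FALSE) {
  if (length(texts) == 0) stop("data error: empty training corpus")
  set.seed(config$seed)
  if (is.null(val_texts)) {
    n_val <- max(1L, floor(length(texts) * config$val_frac))
    vi <- sample(length(texts), n_val)
    val_texts <- texts[vi]
    texts <- texts[-vi]
    if (length(texts) == 0) stop("data error: corpus too small to split")
  }
  train_ids <- encode_corpus(tokenizer, texts)
  val_ids <- encode_corpus(tokenizer, val_texts)
  params <- lm$params
  opt <- adamw_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  val_hist <- numeric(0)
  hist <- list()
  for (epoch in seq_len(config$epochs_pretrain)) {
    ord <- sample(length(train_ids))
    ep_loss <- 0; ep_tok <- 0L
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      acc <- zero_grads(params)
      btok <- 0L
      lm$params <- params
      for (j in idx) {
        ids <- train_ids[[j]]
        T_ <- length(ids)
        if (T_ < 2L) next
        xin <- ids[-T_]; tgt <- ids[-1L]
        fw <- lm_forward(lm, xin)
        pos <- cbind(seq_len(T_ - 1L), tgt)
        ep_loss <- ep_loss - sum(fw$logp[pos])
        dlogits <- exp(fw$logp)
        dlogits[pos] <- dlogits[pos] - 1
        acc <- acc_grads(acc, lm_backward(lm, xin, fw, dlogits = dlogits))
        btok <- btok + T_ - 1L
        ep_tok <- ep_tok + T_ - 1L
      }
      if (btok > 0L) {
        grads <- lapply(acc, function(g) g / btok)
        st <- adamw_step(params, grads, opt, config$lr, config$weight_decay)
        params <- st$params; opt <- st$opt
      }
      i <- i + config$batch_size
    }
    train_loss <- ep_loss / ep_tok
    if (!is.finite(train_loss)) {
      stop("divergence error: non-finite training loss at epoch ", epoch)
    }
    lm$params <- params
    val_loss <- causal_loss(lm, val_ids)
    hist[[epoch]] <- c(epoch = epoch, train_loss = train_loss, val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, train_loss, val_loss))
    }
    val_hist <- c(val_hist, val_loss)
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = params, epoch = epoch)
    }
    if (stop_early(val_hist, config$patience)) break
  }
  lm$params <- best$params
  h <- do.call(rbind, hist)
  list(model = lm,
       history = tibble::tibble(epoch = h[, "epoch"],
                                train_loss = h[, "train_loss"],
                                val_loss = h[, "val_loss"]),
       best_epoch = best$epoch)
}

#' Save a model checkpoint
#'
#' Writes a self-describing directory: weights (`weights.json`), tokenizer
#' vocabulary (`tokenizer.json`) and a config manifest (`manifest.json`).
#'
#' @param lm a `tiny_lm`.
#' @param tokenizer the `word_tokenizer` used with the model.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(lm, tokenizer, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(lapply(lm$params, function(p) unclass(as.matrix(p))),
                       file.path(dir, "weights.json"), digits = NA)
  jsonlite::write_json(list(vocab = tokenizer$vocab),
                       file.path(dir, "tokenizer.json"))
  jsonlite::write_json(list(vocab_size = lm$vocab_size, dim = lm$dim,
                            hidden = lm$hidden, seed = lm$seed,
                            package_version = as.character(utils::packageVersion("gencoder"))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a model checkpoint
#' @param dir directory written by [save_checkpoint()].
#' @return List with elements `model` and `tokenizer`.
#' @export
load_checkpoint <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  w <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  lm <- tiny_lm(man$vocab_size, man$dim, man$hidden, man$seed)
  lm$params <- list(E = as.matrix(w$E), W1 = as.matrix(w$W1), b1 = as.numeric(w$b1),
                    W2 = as.matrix(w$W2), b2 = as.numeric(w$b2))
  vocab <- jsonlite::read_json(file.path(dir, "tokenizer.json"),
                               simplifyVector = TRUE)$vocab
  tok <- structure(list(vocab = vocab,
                        ids = stats::setNames(seq_along(vocab), vocab),
                        bos_id = 1L, eos_id = 2L, sep_id = 3L, unk_id = 4L),
                   class = "word_tokenizer")
  list(model = lm, tokenizer = tok)
}
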
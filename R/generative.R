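#' Decoding configuration
#'
#' Defaults follow the study settings: sampling from the `top_k = 10` highest
#' probability admissible tokens at each step, `k = 10` independently sampled
#' sequences per instance, and a softmax temperature of `0.01` when turning
#' sequence scores into a probability distribution over codes.
#'
#' @param k number of returned sequences per instance.
#' @param top_k per-step sampling pool size.
#' @param temperature softmax temperature over sequence scores (> 0).
#' @param seed optional RNG seed for sampling.
#' @param max_len maximum number of generated tokens (multi-cause decoding).
#' @return An object of class `decoding_config`.
#' @export
decoding_config <- function(k = 10, top_k = 10, temperature = 0.01,
                            seed = NULL, max_len = 64) {
  stopifnot(k >= 1, top_k >= 1, temperature > 0, max_len >= 1)
  structure(list(k = as.integer(k), top_k = as.integer(top_k),
                 temperature = temperature, seed = seed,
                 max_len = as.integer(max_len)),
            class = "decoding_config")
}

#' Mean token log-probability of a sequence
#'
#' The score used to re-rank sampled sequences: the sum of the per-token log
#' probabilities divided by the number of tokens, i.e. the length-normalized
#' joint log-probability.
#'
#' @param logprobs non-empty numeric vector of finite per-token log-probabilities.
#' @return The arithmetic mean.
#' @export
sequence_score <- function(logprobs) {
  if (length(logprobs) == 0) stop("argument error: empty log-probability list")
  if (any(!is.finite(logprobs))) stop("argument error: non-finite log-probability")
  mean(logprobs)
}

# One constrained sampling pass over the trie. The trie mask is applied to the
# full logit vector first, and the top-k pool is then taken among allowed
# tokens, so the pool is never empty and every finished sequence is a valid
# trie path. Per-token log-probabilities are the model's unconstrained
# log-softmax values, so the sequence score equals the chain-rule joint
# log-probability divided by length.
sample_one_path <- function(lm, trie, prompt_ids, top_k) {
  state <- lm_state_init(lm, prompt_ids)
  prefix <- integer(0)
  lps <- numeric(0)
  repeat {
    lp <- lm_state_logprobs(lm, state)
    allowed <- allowed_next(trie, prefix)
    la <- lp[allowed]
    pool <- allowed[order(la, decreasing = TRUE)][seq_len(min(top_k, length(allowed)))]
    lpp <- lp[pool]
    w <- exp(lpp - max(lpp))
    tok <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
    lps <- c(lps, lp[tok])
    prefix <- c(prefix, tok)
    if (tok == trie$eos_id) break
    state <- lm_state_step(lm, state, tok)
  }
  list(ids = prefix, logprobs = lps, score = sequence_score(lps),
       code = trie_resolve(trie, prefix))
}

#' Constrained sampling of scored sequences
#'
#' Draws `config$k` independent sequences from the model under the trie
#' constraint. At every step the admissible tokens are those allowed by the
#' trie; sampling is restricted to the `config$top_k` most probable admissible
#' tokens, renormalized. Sequences resolving to the same code are merged,
#' keeping the best (maximum) mean-log-probability score, so the result has
#' one scored sequence per distinct code, sorted by decreasing score.
#'
#' @param lm a `tiny_lm` (or any causal LM honouring the contract).
#' @param trie a `description_trie`.
#' @param prompt_ids integer vector of prompt token ids (non-empty).
#' @param config a [decoding_config()].
#' @return List of scored sequences; each has `ids`, `logprobs`, `score`,
#'   `code`.
#' @export
constrained_sample <- function(lm, trie, prompt_ids, config = decoding_config()) {
  stopifnot(length(prompt_ids) >= 1)
  if (length(trie$sequences) == 0) stop("empty trie")
  if (!is.null(config$seed)) set.seed(config$seed)
  draws <- lapply(seq_len(config$k), function(i) {
    sample_one_path(lm, trie, prompt_ids, config$top_k)
  })
  codes <- vapply(draws, `[[`, character(1), "code")
  scores <- vapply(draws, `[[`, numeric(1), "score")
  keep <- vapply(unique(codes), function(cd) {
    cand <- which(codes == cd)
    cand[which.max(scores[cand])]
  }, integer(1))
  out <- draws[keep]
  out[order(vapply(out, `[[`, numeric(1), "score"), decreasing = TRUE)]
}

#' Probability distribution over codes from scored sequences
#'
#' Applies a temperature-scaled softmax to the sequence scores of the returned
#' codes; all catalog codes outside the returned set receive probability zero.
#' Computed with max-subtraction for numerical stability. As the temperature
#' approaches zero the distribution converges to a point mass on the
#' best-scored code; codes with equal scores receive equal probability.
#'
#' @param scored list of scored sequences (one per distinct code), as returned
#'   by [constrained_sample()].
#' @param catalog a `code_catalog`.
#' @param temperature softmax temperature (> 0).
#' @return A `code_distribution`: named numeric vector over all catalog codes
#'   summing to 1, with at most `length(scored)` nonzero entries and
#'   provenance `"generative"`.
#' @export
code_distribution <- function(scored, catalog, temperature = 0.01) {
  if (temperature <= 0) stop("argument error: temperature must be positive")
  if (length(scored) == 0) stop("argument error: no scored sequences")
  codes <- vapply(scored, `[[`, character(1), "code")
  if (anyDuplicated(codes)) stop("scored sequences must have one entry per code")
  s <- vapply(scored, `[[`, numeric(1), "score") / temperature
  w <- exp(s - max(s))
  p <- w / sum(w)
  out <- stats::setNames(numeric(nrow(catalog$entries)), catalog$entries$code)
  out[codes] <- p
  structure(out, provenance = "generative", class = "code_distribution")
}

#' Predict the underlying cause of death by constrained generation
#'
#' Renders the record into a prompt, samples `config$k` constrained sequences,
#' re-ranks the distinct codes by mean token log-probability and converts the
#' scores into a probability distribution over the full code space. The top
#' code is the argmax of that distribution, which by construction equals the
#' best-scored sequence's code.
#'
#' @param lm a trained `tiny_lm`.
#' @param trie a `description_trie` (possibly restricted to a label subset).
#' @param record a `certificate`.
#' @param template a `prompt_template`.
#' @param tokenizer the model's `word_tokenizer`.
#' @param config a [decoding_config()].
#' @param catalog a `code_catalog`.
#' @return List with `code` (top prediction), `distribution`
#'   (a `code_distribution`), and `sequences` (scored sequences).
#' @export
predict_ucod <- function(lm, trie, record, template, tokenizer,
                         config = decoding_config(), catalog) {
  prompt <- render_prompt(record, template, "ucod")
  prompt_ids <- c(tokenizer$bos_id, encode(tokenizer, prompt))
  scored <- constrained_sample(lm, trie, prompt_ids, config)
  dist <- code_distribution(scored, catalog, config$temperature)
  list(code = scored[[1]]$code, distribution = dist, sequences = scored)
}

#' Predict multiple causes of death by constrained generation
#'
#' Generation alternates trie-constrained title segments with a free choice
#' between the delimiter token (`<sep>`, continue with another cause) and the
#' stop token (`<eos>`), available whenever a complete title has just been
#' generated. Returns the de-duplicated codes in generation order.
#'
#' @inheritParams predict_ucod
#' @return Character vector of predicted cause codes.
#' @export
predict_multiple_causes <- function(lm, trie, record, template, tokenizer,
                                    config = decoding_config(), catalog) {
  prompt <- render_prompt(record, template, "causes")
  ids <- c(tokenizer$bos_id, encode(tokenizer, prompt))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- lm_state_init(lm, ids)
  prefix <- integer(0)
  codes <- character(0)
  ngen <- 0L
  repeat {
    lp <- lm_state_logprobs(lm, state)
    allowed <- allowed_next(trie, prefix)
    terminal <- trie$eos_id %in% allowed
    cand <- if (terminal) c(allowed, tokenizer$sep_id) else allowed
    la <- lp[cand]
    pool <- cand[order(la, decreasing = TRUE)][seq_len(min(config$top_k, length(cand)))]
    lpp <- lp[pool]
    tok <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = exp(lpp - max(lpp)))
    ngen <- ngen + 1L
    if (tok == tokenizer$sep_id || tok == trie$eos_id) {
      codes <- c(codes, trie_resolve(trie, c(prefix, trie$eos_id)))
      if (tok == trie$eos_id) break
      prefix <- integer(0)
    } else {
      prefix <- c(prefix, tok)
    }
    state <- lm_state_step(lm, state, tok)
    if (ngen >= config$max_len) {
      warning("truncation: multi-cause generation hit max_len; partial set returned")
      break
    }
  }
  unique(codes)
}

#' Batch prediction of underlying causes
#'
#' @param lm,trie,template,tokenizer,config,catalog as in [predict_ucod()].
#' @param records list of `certificate` objects.
#' @return List with `codes` (character vector of top predictions) and
#'   `distributions` (numeric matrix, records x catalog codes).
#' @export
predict_ucod_all <- function(lm, trie, records, template, tokenizer,
                             config = decoding_config(), catalog) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL  # one stream for the whole batch
  dists <- matrix(0, length(records), nrow(catalog$entries),
                  dimnames = list(NULL, catalog$entries$code))
  codes <- character(length(records))
  for (i in seq_along(records)) {
    pr <- predict_ucod(lm, trie, records[[i]], template, tokenizer, cfg, catalog)
    codes[i] <- pr$code
    dists[i, ] <- as.numeric(pr$distribution)
  }
  list(codes = codes, distributions = dists)
}
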
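#' Calibrate a split conformal predictor
#'
#' Given the probability distributions produced by either coder on a held-out
#' calibration set (never seen during training) and the gold codes, computes
#' per-record conformity scores and the finite-sample-corrected quantile
#' threshold: the `ceiling((n + 1) (1 - alpha)) / n` empirical quantile of the
#' calibration scores. Prediction sets built with this threshold contain the
#' gold code with probability at least `1 - alpha` on exchangeable data.
#'
#' Score functions:
#' \describe{
#'   \item{lac}{`1 - p(gold)`; sets are `{c : 1 - p(c) <= q}` and may be empty.}
#'   \item{aps}{cumulative probability mass of the codes ranked above and
#'     including the gold code (descending probability, ties broken by column
#'     order); sets are the smallest probability-ordered prefix with
#'     cumulative mass `>= q`. Implemented without boundary randomization, so
#'     sets are deterministic at the price of slight over-coverage.}
#' }
#'
#' @param distributions numeric matrix, calibration records x codes, each row
#'   a normalized probability distribution (column names are codes).
#' @param gold character vector of gold codes (must be among the columns; a
#'   gold code outside the support gets the worst score).
#' @param alpha user-chosen error rate in (0, 1); coverage target is
#'   `1 - alpha`.
#' @param score `"lac"` or `"aps"` (default `"aps"`).
#' @return An object of class `conformal_model` with the threshold `q_hat`,
#'   the calibration size `n`, `alpha` and the score function id.
#' @export
conformal_calibrate <- function(distributions, gold, alpha = 0.1,
                                score = c("aps", "lac")) {
  score <- match.arg(score)
  if (!(alpha > 0 && alpha < 1)) stop("argument error: alpha must be in (0, 1)")
  distributions <- as.matrix(distributions)
  n <- nrow(distributions)
  stopifnot(n >= 1, length(gold) == n)
  check_rows_normalized(distributions)
  scores <- conformity_scores(distributions, gold, score)
  rank <- ceiling((n + 1) * (1 - alpha))
  q_hat <- if (rank > n) Inf else sort(scores)[rank]
  structure(list(alpha = alpha, score = score, q_hat = q_hat, n = n),
            class = "conformal_model")
}

check_rows_normalized <- function(m, tol = 1e-6) {
  s <- rowSums(m)
  if (any(abs(s - 1) > tol) || any(m < -tol)) {
    stop("validation error: rows must be normalized probability distributions")
  }
  invisible(TRUE)
}

conformity_scores <- function(distributions, gold, score) {
  codes <- colnames(distributions)
  gi <- match(gold, codes)
  if (anyNA(gi)) stop("gold code absent from distribution columns: ",
                      paste(gold[is.na(gi)], collapse = ", "))
  p_gold <- distributions[cbind(seq_along(gi), gi)]
  if (score == "lac") return(1 - p_gold)
  vapply(seq_len(nrow(distributions)), function(i) {
    p <- distributions[i, ]
    ord <- order(p, decreasing = TRUE)
    pos <- which(ord == gi[i])
    sum(p[ord[seq_len(pos)]])
  }, numeric(1))
}

#' @export
print.conformal_model <- function(x, ...) {
  cat(sprintf("<conformal_model> score=%s alpha=%.3f q_hat=%.4f n=%d\n",
              x$score, x$alpha, x$q_hat, x$n))
  invisible(x)
}

#' Prediction set for one distribution
#'
#' @param model a calibrated `conformal_model`.
#' @param distribution named numeric probability vector over codes.
#' @param force_nonempty if `TRUE`, an empty lac set is replaced by the argmax
#'   singleton.
#' @return Character vector: the set of codes.
#' @export
conformal_predict_set <- function(model, distribution, force_nonempty = FALSE) {
  p <- as.numeric(distribution)
  codes <- names(distribution)
  if (model$score == "lac") {
    set <- codes[1 - p <= model$q_hat]
    if (force_nonempty && length(set) == 0) set <- codes[which.max(p)]
    return(set)
  }
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= min(model$q_hat, cum[length(cum)]))[1]
  codes[ord[seq_len(k)]]
}

#' Prediction sets for a matrix of distributions
#'
#' @param model a `conformal_model`.
#' @param distributions matrix records x codes with code column names.
#' @param force_nonempty see [conformal_predict_set()].
#' @return List of character vectors.
#' @export
conformal_predict_sets <- function(model, distributions, force_nonempty = FALSE) {
  distributions <- as.matrix(distributions)
  codes <- colnames(distributions)
  lapply(seq_len(nrow(distributions)), function(i) {
    conformal_predict_set(model, stats::setNames(distributions[i, ], codes),
                          force_nonempty = force_nonempty)
  })
}

#' Coverage and set-size report
#'
#' Empirical coverage per ICD level -- the fraction of records whose gold
#' code, mapped to the level, is matched by some member of the prediction set
#' mapped to the same level -- plus the histogram of set sizes. Coverage can
#' only grow as the level coarsens (chapter >= block >= full-code).
#'
#' @param sets list of character vectors (prediction sets).
#' @param gold character vector of gold full codes.
#' @param catalog a `code_catalog`.
#' @param levels hierarchy levels to report.
#' @return List with `coverage` (tibble: level, coverage), `size_histogram`
#'   (table of set sizes) and `mean_size`.
#' @export
conformal_report <- function(sets, gold, catalog,
                             levels = c("chapter", "block", "full")) {
  stopifnot(length(sets) == length(gold))
  cov <- lapply(levels, function(lv) {
    g <- map_to_level(gold, lv, catalog)
    hit <- vapply(seq_along(sets), function(i) {
      length(sets[[i]]) > 0 && g[i] %in% map_to_level(sets[[i]], lv, catalog)
    }, logical(1))
    tibble::tibble(level = lv, coverage = mean(hit))
  })
  sizes <- vapply(sets, length, integer(1))
  list(coverage = do.call(rbind, cov),
       size_histogram = table(sizes),
       mean_size = mean(sizes))
}
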
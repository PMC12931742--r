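# Per-label precision/recall/F1. Labels = those present in the gold slice;
# a label that is never predicted gets precision 0 for averaging purposes.
per_label_prf <- function(pred, gold, labels = sort(unique(gold))) {
  tp <- fp <- fn <- stats::setNames(numeric(length(labels)), labels)
  for (l in labels) {
    tp[l] <- sum(pred == l & gold == l)
    fp[l] <- sum(pred == l & gold != l)
    fn[l] <- sum(pred != l & gold == l)
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = prec, recall = rec, f1 = f1)
}

macro_f1 <- function(pred, gold) {
  mean(per_label_prf(pred, gold)$f1)
}

#' Hierarchical classification metrics
#'
#' Computes accuracy and macro-averaged precision, recall and F1 at one or
#' more levels of the ICD hierarchy. Both predictions and gold codes are first
#' mapped to the level (full-code, block, or chapter); accuracy is the exact
#' match rate at that level, and macro averages are unweighted means of
#' per-label metrics over the labels present in the gold slice. Because the
#' level mappings are functions of the full code, accuracy at the chapter
#' level is always at least the block-level accuracy, which in turn bounds the
#' full-code accuracy.
#'
#' @param pred character vector of predicted full codes.
#' @param gold character vector of gold full codes, same length.
#' @param catalog a `code_catalog`.
#' @param levels subset of `c("chapter", "block", "full")`.
#' @return A tibble with one row per level: `level`, `n`, `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
hierarchical_metrics <- function(pred, gold, catalog,
                                 levels = c("chapter", "block", "full")) {
  stopifnot(length(pred) == length(gold))
  levels <- match.arg(levels, several.ok = TRUE)
  rows <- lapply(levels, function(lv) {
    p <- map_to_level(pred, lv, catalog)
    g <- map_to_level(gold, lv, catalog)
    m <- per_label_prf(p, g)
    tibble::tibble(level = lv, n = length(g), accuracy = mean(p == g),
                   macro_precision = mean(m$precision),
                   macro_recall = mean(m$recall),
                   macro_f1 = mean(m$f1))
  })
  do.call(rbind, rows)
}

#' Multi-label metrics for multiple-causes prediction
#'
#' Predicted and gold code sets are mapped to the requested hierarchy level
#' and de-duplicated; micro averages pool true/false positives and false
#' negatives over all labels, macro averages are per-label means over labels
#' occurring in the gold sets.
#'
#' @param pred_sets list of character vectors (predicted code sets).
#' @param gold_sets list of character vectors (gold code sets), same length.
#' @param catalog a `code_catalog`.
#' @param level one of `"chapter"`, `"block"`, `"full"`.
#' @return A tibble with columns `level`, `micro_precision`, `micro_recall`,
#'   `micro_f1`, `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
multilabel_metrics <- function(pred_sets, gold_sets, catalog,
                               level = c("full", "block", "chapter")) {
  level <- match.arg(level)
  stopifnot(length(pred_sets) == length(gold_sets))
  pm <- lapply(pred_sets, function(s) unique(map_to_level(s, level, catalog)))
  gm <- lapply(gold_sets, function(s) unique(map_to_level(s, level, catalog)))
  labels <- sort(unique(unlist(gm)))
  tp <- fp <- fn <- stats::setNames(numeric(length(labels)), labels)
  extra_fp <- 0
  for (i in seq_along(pm)) {
    p <- pm[[i]]; g <- gm[[i]]
    for (l in intersect(p, g)) tp[l] <- tp[l] + 1
    for (l in setdiff(g, p)) fn[l] <- fn[l] + 1
    for (l in setdiff(p, g)) {
      if (l %in% labels) fp[l] <- fp[l] + 1 else extra_fp <- extra_fp + 1
    }
  }
  TP <- sum(tp); FP <- sum(fp) + extra_fp; FN <- sum(fn)
  mip <- if (TP + FP > 0) TP / (TP + FP) else 0
  mir <- if (TP + FN > 0) TP / (TP + FN) else 0
  mif <- if (mip + mir > 0) 2 * mip * mir / (mip + mir) else 0
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tibble::tibble(level = level,
                 micro_precision = mip, micro_recall = mir, micro_f1 = mif,
                 macro_precision = mean(prec), macro_recall = mean(rec),
                 macro_f1 = mean(f1))
}

#' Subgroup evaluation report
#'
#' Evaluates full-code metrics within demographic subgroups: gender, or age
#' bins (default under-25, 25-50, 50-75, 75-100, above-100; bins are
#' left-closed and right-open at 25/50/75/100, so age 24 falls in under-25 and
#' age 25 in 25-50). Records missing the grouping field are excluded from the
#' groups and reported in the `excluded` attribute.
#'
#' @param pred,gold character vectors of predicted and gold full codes.
#' @param records list of `certificate` objects aligned with `pred`/`gold`.
#' @param catalog a `code_catalog`.
#' @param by `"gender"` or `"age"`.
#' @param age_breaks right-open bin edges for age grouping.
#' @return A tibble with one row per group (group, n, accuracy, macro metrics);
#'   attribute `excluded` counts records without the grouping information.
#' @export
subgroup_report <- function(pred, gold, records, catalog,
                            by = c("gender", "age"),
                            age_breaks = c(25, 50, 75, 100)) {
  by <- match.arg(by)
  if (by == "gender") {
    key <- vapply(records, function(r) r$gender, character(1))
    key[key == "unknown"] <- NA_character_
  } else {
    age <- vapply(records, function(r) as.numeric(r$age), numeric(1))
    lab <- c(paste0("under-", age_breaks[1]),
             paste(utils::head(age_breaks, -1), utils::tail(age_breaks, -1), sep = "-"),
             paste0("above-", age_breaks[length(age_breaks)]))
    key <- lab[findInterval(age, age_breaks) + 1L]
  }
  keep <- !is.na(key)
  excluded <- sum(!keep)
  groups <- unique(key[keep])
  rows <- lapply(groups, function(g) {
    sel <- keep & key == g
    m <- per_label_prf(pred[sel], gold[sel])
    tibble::tibble(group = g, n = sum(sel),
                   accuracy = mean(pred[sel] == gold[sel]),
                   macro_precision = mean(m$precision),
                   macro_recall = mean(m$recall), macro_f1 = mean(m$f1))
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Most-confused codes
#'
#' Ranks gold codes by absolute number of classification errors and reports,
#' for each, the most frequent wrong predictions. Ties are broken by
#' lexicographic code order for determinism.
#'
#' @param pred,gold character vectors of predicted and gold full codes.
#' @param n number of gold codes to report.
#' @return A tibble: `gold` code, total `errors`, and for each its confused
#'   predictions (`predicted`, `count`), ordered by decreasing error count.
#' @export
top_confusions <- function(pred, gold, n = 10) {
  stopifnot(n >= 1)
  err <- pred != gold
  if (!any(err)) {
    return(tibble::tibble(gold = character(0), errors = integer(0),
                          predicted = character(0), count = integer(0)))
  }
  eg <- gold[err]; ep <- pred[err]
  totals <- sort(table(eg), decreasing = TRUE)
  ord <- order(-as.integer(totals), names(totals))
  top <- names(totals)[ord][seq_len(min(n, length(totals)))]
  rows <- lapply(top, function(g) {
    tab <- sort(table(ep[eg == g]), decreasing = TRUE)
    o <- order(-as.integer(tab), names(tab))
    tibble::tibble(gold = g, errors = sum(eg == g),
                   predicted = names(tab)[o],
                   count = as.integer(tab)[o])
  })
  do.call(rbind, rows)
}
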
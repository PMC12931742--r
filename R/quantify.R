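#' Define a group of ICD codes for quantification
#'
#' A group is either an explicit set of full codes or a block range such as
#' `"I20-I25"` (ischemic heart diseases); a full code belongs to a block-range
#' group when its block falls inside the range (letter and number compared
#' together, e.g. `"I21.4"` is in `I20-I25`). A single block like `"U07"` is
#' the degenerate range `U07-U07`.
#'
#' @param name group label.
#' @param codes explicit character vector of member full codes, or `NULL`.
#' @param blocks block range string `"A00-A09"` / single block `"U07"`, or
#'   `NULL`.
#' @param catalog a `code_catalog` used to resolve membership.
#' @return An object of class `code_group` with the resolved member codes.
#' @export
code_group <- function(name, codes = NULL, blocks = NULL, catalog) {
  stopifnot(inherits(catalog, "code_catalog"))
  if (is.null(codes) && is.null(blocks)) {
    stop("configuration error: a group needs codes or a block range")
  }
  members <- character(0)
  if (!is.null(codes)) {
    unknown <- setdiff(codes, catalog$entries$code)
    if (length(unknown) > 0) {
      stop("group codes not in catalog: ", paste(unknown, collapse = ", "))
    }
    members <- codes
  }
  if (!is.null(blocks)) {
    parts <- strsplit(blocks, "-", fixed = TRUE)[[1]]
    lo <- parts[1]
    hi <- if (length(parts) > 1) parts[2] else parts[1]
    if (!grepl("^[A-Z][0-9]{2}$", lo) || !grepl("^[A-Z][0-9]{2}$", hi)) {
      stop("malformed block range: ", blocks)
    }
    blk <- catalog$entries$block
    members <- union(members, catalog$entries$code[blk >= lo & blk <= hi])
  }
  if (length(members) == 0) {
    stop("group resolves to no catalog code: ", name)
  }
  structure(list(name = name, members = sort(unique(members))),
            class = "code_group")
}

#' @export
print.code_group <- function(x, ...) {
  cat(sprintf("<code_group> %s: %d codes\n", x$name, length(x$members)))
  invisible(x)
}

#' Classify-and-Count prevalence estimate
#'
#' The fraction of records whose (argmax) predicted code falls in the group.
#'
#' @param predicted character vector of predicted codes (non-empty).
#' @param group a `code_group`.
#' @return Proportion in `[0, 1]`.
#' @export
cc_estimate <- function(predicted, group) {
  if (length(predicted) == 0) stop("argument error: empty collection")
  mean(predicted %in% group$members)
}

#' Probabilistic Classify-and-Count prevalence estimate
#'
#' Sums, over all records, the posterior probability mass the coder assigns to
#' the group's codes, divided by the number of records. When the
#' distributions equal the true class posteriors this is an unbiased
#' prevalence estimator; with degenerate one-hot distributions it equals the
#' Classify-and-Count estimate exactly.
#'
#' @param distributions numeric matrix, records x codes (columns named by
#'   code), each row a normalized distribution.
#' @param group a `code_group`.
#' @return Proportion in `[0, 1]`.
#' @export
pcc_estimate <- function(distributions, group) {
  distributions <- as.matrix(distributions)
  if (nrow(distributions) == 0) stop("argument error: empty collection")
  check_rows_normalized(distributions)
  cols <- intersect(colnames(distributions), group$members)
  sum(distributions[, cols, drop = FALSE]) / nrow(distributions)
}

#' Weekly surveillance series for a cause-of-death group
#'
#' For every week with at least one certificate, reports the manually-coded
#' proportion of deaths in the group, the Classify-and-Count and Probabilistic
#' Classify-and-Count estimates, and the decomposition of the argmax
#' classifications into true positives, false positives and false negatives
#' with respect to gold group membership. By construction
#' `manual = (TP + FN) / total` and `cc = (TP + FP) / total`. Records without
#' a week are excluded (their number is returned as an attribute).
#'
#' @param weeks integer vector of ISO weeks, one per record (`NA` allowed).
#' @param gold character vector of gold codes.
#' @param predicted character vector of argmax predictions.
#' @param distributions matrix records x codes.
#' @param group a `code_group`.
#' @return A tibble with columns `week`, `total`, `manual`, `cc`, `pcc`, `tp`,
#'   `fp`, `fn`; attribute `excluded` counts records without a week.
#' @export
weekly_series <- function(weeks, gold, predicted, distributions, group) {
  distributions <- as.matrix(distributions)
  n <- length(weeks)
  stopifnot(length(gold) == n, length(predicted) == n,
            nrow(distributions) == n)
  keep <- !is.na(weeks)
  excluded <- sum(!keep)
  gmem <- gold %in% group$members
  pmem <- predicted %in% group$members
  wk <- sort(unique(weeks[keep]))
  rows <- lapply(wk, function(w) {
    sel <- keep & weeks == w
    tot <- sum(sel)
    tp <- sum(sel & gmem & pmem)
    fp <- sum(sel & !gmem & pmem)
    fn <- sum(sel & gmem & !pmem)
    tibble::tibble(week = w, total = tot,
                   manual = sum(sel & gmem) / tot,
                   cc = cc_estimate(predicted[sel], group),
                   pcc = pcc_estimate(distributions[sel, , drop = FALSE], group),
                   tp = tp, fp = fp, fn = fn)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Read quantification groups from a YAML file
#'
#' The file maps group names either to a list of codes or to a block range
#' string.
#'
#' @param path YAML file.
#' @param catalog a `code_catalog`.
#' @return Named list of `code_group` objects.
#' @export
load_groups <- function(path, catalog) {
  x <- yaml::read_yaml(path)
  out <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    if (length(v) == 1 && grepl("^[A-Z][0-9]{2}(-[A-Z][0-9]{2})?$", v)) {
      code_group(nm, blocks = v, catalog = catalog)
    } else {
      code_group(nm, codes = unlist(v), catalog = catalog)
    }
  })
  stats::setNames(out, names(x))
}
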
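#' Construct an ICD-10 code catalog
#'
#' A catalog holds the label space of the coder: for every assignable code its
#' descriptive title and its chapter membership. Codes follow the usual ICD-10
#' shape (letter, two digits, optional decimal subdivision, e.g. `"C80.9"` or
#' `"I48"`); the *block* of a code is its first three characters and the
#' *chapter* is a top-level grouping recorded as a catalog column (Roman
#' numerals for the WHO chapters). Titles must be unique because constrained
#' decoding resolves a generated title back to exactly one code.
#'
#' @param code character vector of ICD-10 code strings.
#' @param title character vector of descriptive titles, same length as `code`.
#' @param chapter character vector of chapter identifiers, same length.
#' @param disambiguate_titles if `TRUE`, duplicated titles are suffixed with
#'   `" (CODE)"` instead of raising an error.
#' @return An object of class `code_catalog`: a data frame with columns
#'   `code`, `title`, `chapter`, `block`, plus lookup indexes.
#' @export
code_catalog <- function(code, title, chapter, disambiguate_titles = FALSE) {
  code <- as.character(code)
  title <- as.character(title)
  chapter <- as.character(chapter)
  n <- length(code)
  if (length(title) != n || length(chapter) != n) {
    stop("code, title and chapter must have the same length")
  }
  if (n == 0L) stop("catalog must contain at least one code")
  if (any(!nzchar(code)) || any(is.na(code))) stop("codes must be non-empty")
  if (any(!nzchar(title)) || any(is.na(title))) stop("titles must be non-empty")
  if (any(!nzchar(chapter)) || any(is.na(chapter))) stop("chapters must be non-empty")
  dup <- duplicated(code)
  if (any(dup)) {
    stop("catalog integrity: duplicate codes: ",
         paste(unique(code[dup]), collapse = ", "))
  }
  dupt <- duplicated(title)
  if (any(dupt)) {
    if (disambiguate_titles) {
      clash <- title %in% title[dupt]
      title[clash] <- paste0(title[clash], " (", code[clash], ")")
    } else {
      stop("catalog integrity: duplicate titles: ",
           paste(unique(title[dupt]), collapse = ", "))
    }
  }
  entries <- data.frame(
    code = code, title = title, chapter = chapter,
    block = vapply(code, block_of, character(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      entries = entries,
      by_code = stats::setNames(seq_len(n), code),
      by_title = stats::setNames(seq_len(n), title)
    ),
    class = "code_catalog"
  )
}

#' @export
print.code_catalog <- function(x, ...) {
  cts <- catalog_counts(x)
  cat(sprintf("<code_catalog> %d codes, %d blocks, %d chapters\n",
              cts["codes"], cts["blocks"], cts["chapters"]))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Number of distinct full-codes, blocks and chapters in a catalog
#'
#' @param catalog a `code_catalog`.
#' @return Named integer vector with elements `codes`, `blocks`, `chapters`.
#' @export
catalog_counts <- function(catalog) {
  stopifnot(inherits(catalog, "code_catalog"))
  c(codes = nrow(catalog$entries),
    blocks = length(unique(catalog$entries$block)),
    chapters = length(unique(catalog$entries$chapter)))
}

#' Load a code catalog from a TSV file
#'
#' The file must be UTF-8, tab separated, with a header naming at least the
#' columns `code`, `title` and `chapter`.
#'
#' @param path file path.
#' @param disambiguate_titles see [code_catalog()].
#' @return A `code_catalog`.
#' @export
load_catalog <- function(path, disambiguate_titles = FALSE) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           quote = "", fileEncoding = "UTF-8")
  need <- c("code", "title", "chapter")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("catalog format: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  blank <- !nzchar(tab$code) | !nzchar(tab$title) | !nzchar(tab$chapter)
  if (any(blank)) {
    stop("catalog format: blank required field in row(s): ",
         paste(which(blank), collapse = ", "))
  }
  code_catalog(tab$code, tab$title, tab$chapter,
               disambiguate_titles = disambiguate_titles)
}

#' Write a code catalog to a TSV file
#'
#' @param catalog a `code_catalog`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "code_catalog"))
  utils::write.table(catalog$entries[, c("code", "title", "chapter")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Block of an ICD-10 code
#'
#' The block is the first three characters of a code (letter plus two digits);
#' for a three-character code the block equals the code itself.
#'
#' @param code an ICD-10 code string.
#' @return The three-character block string.
#' @export
#' @examples
#' block_of("C80.9") # "C80"
#' block_of("I48")   # "I48"
block_of <- function(code) {
  if (length(code) != 1L || is.na(code) ||
      !grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", code)) {
    stop("malformed ICD code: ", paste(code, collapse = ", "))
  }
  substr(code, 1L, 3L)
}

#' Vectorised block mapping
#' @param codes character vector of ICD-10 codes.
#' @return Character vector of blocks.
#' @export
blocks_of <- function(codes) vapply(codes, block_of, character(1), USE.NAMES = FALSE)

#' Chapter of an ICD-10 code
#'
#' Chapter membership is data carried by the catalog, not hard-coded letter
#' ranges, so synthetic ontologies with arbitrary chapter layouts work the
#' same way as the WHO classification.
#'
#' @param code an ICD-10 code (full code or block) present in the catalog.
#' @param catalog a `code_catalog`.
#' @return The chapter identifier recorded for that code.
#' @export
chapter_of <- function(code, catalog) {
  stopifnot(inherits(catalog, "code_catalog"))
  idx <- catalog$by_code[code]
  if (is.na(idx)) {
    # fall back to block-level lookup: any code sharing the block
    blk <- block_of(code)
    hit <- which(catalog$entries$block == blk)
    if (length(hit) == 0) stop("unknown code: ", code)
    idx <- hit[1L]
  }
  catalog$entries$chapter[idx]
}

#' Vectorised chapter mapping
#' @param codes character vector of codes present in the catalog.
#' @param catalog a `code_catalog`.
#' @return Character vector of chapter identifiers.
#' @export
chapters_of <- function(codes, catalog) {
  vapply(codes, chapter_of, character(1), catalog = catalog, USE.NAMES = FALSE)
}

#' Map codes to a hierarchy level
#'
#' @param codes character vector of full codes.
#' @param level one of `"chapter"`, `"block"`, `"full"`.
#' @param catalog a `code_catalog` (needed for `"chapter"`).
#' @return Character vector of level-mapped labels.
#' @export
map_to_level <- function(codes, level = c("full", "block", "chapter"),
                         catalog = NULL) {
  level <- match.arg(level)
  switch(level,
    full = codes,
    block = blocks_of(codes),
    chapter = {
      if (is.null(catalog)) stop("chapter mapping requires a catalog")
      chapters_of(codes, catalog)
    })
}
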
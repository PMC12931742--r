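#' Build a token trie over the catalog's generation targets
#'
#' Constrained decoding guarantees that every generated sequence is a valid
#' code description by restricting, at every step, the admissible next tokens
#' to those that continue some catalog entry. The trie stores, for every
#' reachable token-id prefix, the set of allowed next token ids; terminal
#' paths carry the resolved code. Every target sequence is terminated by the
#' tokenizer's end-of-sequence token, so a title that is a strict prefix of
#' another is still unambiguous: at that node both `<eos>` and the
#' continuation tokens are allowed.
#'
#' @param catalog a `code_catalog`.
#' @param tokenizer a `word_tokenizer` (or any object supporting [encode()]).
#' @param target `"title"` (default; decoding generates the descriptive title,
#'   which also allows assigning codes never seen as classifier outputs) or
#'   `"code"` (generate the code string itself).
#' @return An object of class `description_trie`.
#' @export
build_trie <- function(catalog, tokenizer, target = c("title", "code")) {
  target <- match.arg(target)
  stopifnot(inherits(catalog, "code_catalog"))
  txt <- if (target == "title") catalog$entries$title else catalog$entries$code
  seqs <- lapply(txt, function(t) c(encode(tokenizer, t), tokenizer$eos_id))
  keys <- vapply(seqs, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) {
    d <- keys[duplicated(keys)][1]
    clash <- catalog$entries$code[keys == d]
    stop("trie ambiguity: entries tokenize identically: ",
         paste(clash, collapse = ", "))
  }
  nodes <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    prefix <- integer(0)
    for (tok in s) {
      key <- trie_key(prefix)
      node <- if (is.null(nodes[[key]])) list(next_ids = integer(0), code = NULL)
              else nodes[[key]]
      node$next_ids <- union(node$next_ids, tok)
      nodes[[key]] <- node
      prefix <- c(prefix, tok)
    }
    tkey <- trie_key(prefix)
    term <- if (is.null(nodes[[tkey]])) list(next_ids = integer(0), code = NULL)
            else nodes[[tkey]]
    term$code <- catalog$entries$code[i]
    nodes[[tkey]] <- term
  }
  structure(
    list(nodes = nodes,
         sequences = stats::setNames(seqs, catalog$entries$code),
         eos_id = tokenizer$eos_id,
         target = target),
    class = "description_trie"
  )
}

trie_key <- function(prefix) paste0("p", paste(prefix, collapse = ","))

#' Allowed next tokens after a prefix
#'
#' @param trie a `description_trie`.
#' @param prefix integer vector of token ids already generated (may be empty).
#' @return Integer vector of admissible next token ids; contains the
#'   end-of-sequence id iff the prefix completes some target.
#' @export
allowed_next <- function(trie, prefix = integer(0)) {
  node <- trie$nodes[[trie_key(prefix)]]
  if (is.null(node)) {
    stop("constraint violation: prefix is not a path in the trie (decoder bug)")
  }
  sort(node$next_ids)
}

#' Resolve a complete token sequence to its code
#'
#' @param trie a `description_trie`.
#' @param ids integer vector ending with the end-of-sequence token.
#' @return The catalog code whose target tokenizes to `ids`.
#' @export
trie_resolve <- function(trie, ids) {
  node <- trie$nodes[[trie_key(ids)]]
  if (is.null(node)) stop("resolution error: sequence is not a trie path")
  if (is.null(node$code)) stop("resolution error: sequence is incomplete")
  node$code
}

#' Codes reachable in a trie
#' @param trie a `description_trie`.
#' @return Character vector of codes with a terminal path.
#' @export
trie_codes <- function(trie) names(trie$sequences)

#' Restrict a trie to a subset of codes
#'
#' Decoding with the restricted trie can never produce an excluded code; this
#' is how evaluation against a reduced label set is performed without any
#' retraining.
#'
#' @param trie a `description_trie`.
#' @param codes character vector, subset of the trie's codes.
#' @return A new `description_trie` over only `codes`.
#' @export
restrict_trie <- function(trie, codes) {
  if (length(codes) == 0) stop("configuration error: empty allowed code set")
  unknown <- setdiff(codes, trie_codes(trie))
  if (length(unknown) > 0) {
    stop("allowed codes not in trie: ", paste(unknown, collapse = ", "))
  }
  seqs <- trie$sequences[codes]
  nodes <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    prefix <- integer(0)
    for (tok in s) {
      key <- trie_key(prefix)
      node <- if (is.null(nodes[[key]])) list(next_ids = integer(0), code = NULL)
              else nodes[[key]]
      node$next_ids <- union(node$next_ids, tok)
      nodes[[key]] <- node
      prefix <- c(prefix, tok)
    }
    tkey <- trie_key(prefix)
    term <- if (is.null(nodes[[tkey]])) list(next_ids = integer(0), code = NULL)
            else nodes[[tkey]]
    term$code <- names(seqs)[i]
    nodes[[tkey]] <- term
  }
  structure(
    list(nodes = nodes, sequences = seqs, eos_id = trie$eos_id,
         target = trie$target),
    class = "description_trie"
  )
}

#' Serialize a trie to JSON for inspection
#'
#' @param trie a `description_trie`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
trie_to_json <- function(trie, path = NULL) {
  obj <- list(
    format_version = 1L,
    target = trie$target,
    eos_id = trie$eos_id,
    sequences = lapply(trie$sequences, as.integer)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.description_trie <- function(x, ...) {
  cat(sprintf("<description_trie> %d codes, target = %s\n",
              length(x$sequences), x$target))
  invisible(x)
}
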
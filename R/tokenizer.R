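#' Build a word-level tokenizer from a text corpus
#'
#' The reference tokenizer is deliberately word-level: text is lower-cased and
#' split on whitespace, and each distinct word becomes one vocabulary entry.
#' This keeps the description trie and its brute-force oracles human-auditable.
#' The contract (deterministic `encode`/`decode`, reserved end-of-sequence id)
#' also admits sub-word tokenizers for larger models.
#'
#' Reserved tokens: `<bos>` (sequence start), `<eos>` (end of sequence, also
#' the stop token of multi-cause generation), `<sep>` (delimiter between
#' repeated prompts and between generated cause titles), `<unk>` (out of
#' vocabulary).
#'
#' @param texts character vector; the vocabulary is the set of words occurring
#'   in these texts.
#' @param extra character vector of additional words to include.
#' @return An object of class `word_tokenizer`.
#' @export
word_tokenizer <- function(texts, extra = character()) {
  words <- unique(c(unlist(lapply(texts, split_words), use.names = FALSE),
                    split_words(paste(extra, collapse = " "))))
  words <- setdiff(sort(words), c("<bos>", "<eos>", "<sep>", "<unk>"))
  vocab <- c("<bos>", "<eos>", "<sep>", "<unk>", words)
  structure(
    list(vocab = vocab,
         ids = stats::setNames(seq_along(vocab), vocab),
         bos_id = 1L, eos_id = 2L, sep_id = 3L, unk_id = 4L),
    class = "word_tokenizer"
  )
}

split_words <- function(text) {
  text <- tolower(text)
  out <- strsplit(trimws(text), "\\s+")[[1]]
  out[nzchar(out)]
}

#' Encode text into token ids
#' @param tokenizer a `word_tokenizer`.
#' @param text a single string.
#' @return Integer vector of token ids (out-of-vocabulary words map to `<unk>`).
#' @export
encode <- function(tokenizer, text) {
  w <- split_words(text)
  ids <- tokenizer$ids[w]
  ids[is.na(ids)] <- tokenizer$unk_id
  as.integer(unname(ids))
}

#' Decode token ids back into text
#' @param tokenizer a `word_tokenizer`.
#' @param ids integer vector of token ids.
#' @return A single string with tokens joined by spaces.
#' @export
decode <- function(tokenizer, ids) {
  if (any(ids < 1L | ids > length(tokenizer$vocab))) stop("token id out of range")
  paste(tokenizer$vocab[ids], collapse = " ")
}

#' @export
print.word_tokenizer <- function(x, ...) {
  cat(sprintf("<word_tokenizer> vocabulary size %d\n", length(x$vocab)))
  invisible(x)
}
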
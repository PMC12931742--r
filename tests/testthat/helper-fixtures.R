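# Shared fixtures, all built in code.

# Three-code toy catalog with a shared-prefix pair of titles.
toy_catalog <- function() {
  code_catalog(code = c("I21", "I64", "C80.9"),
               title = c("acute mi", "acute stroke", "metastatic carcinoma"),
               chapter = c("IX", "IX", "II"))
}

toy_tokenizer <- function(catalog = toy_catalog()) {
  word_tokenizer(catalog$entries$title)
}

# Brute-force oracle for allowed_next: scan all tokenized targets sharing the
# prefix and collect their next tokens. Independent of the trie structure.
oracle_allowed_next <- function(seqs, prefix) {
  nxt <- integer(0)
  np <- length(prefix)
  for (s in seqs) {
    if (length(s) > np && identical(s[seq_len(np)], as.integer(prefix))) {
      nxt <- c(nxt, s[np + 1L])
    }
  }
  sort(unique(nxt))
}

# All reachable proper prefixes (including the empty one) of a set of
# tokenized targets.
all_prefixes <- function(seqs) {
  seen <- new.env(parent = emptyenv())
  out <- list(integer(0))
  seen[["p"]] <- TRUE
  for (s in seqs) {
    for (l in seq_len(length(s) - 1L)) {
      key <- paste0("p", paste(s[seq_len(l)], collapse = ","))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- s[seq_len(l)]
      }
    }
  }
  out
}

# Heavy fixtures are trained once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The separable study corpus: 50 codes over 20 blocks and 5 chapters, 5,000
# certificates, Zipf-1 long tail, no text noise and no part-II auxiliary-cause
# distractors.
recovery_catalog <- function() {
  cached("recovery_catalog", make_ontology(5, 20, 50, seed = 42))
}

recovery_records <- function() {
  cached("recovery_records",
         sample_certificates(recovery_catalog(), 5000, zipf = 1, noise = 0,
                             multi_rate = 0, seed = 42))
}

# Full pipeline (pre-training + constrained decoding + fine-tuned classifier)
# on the separable corpus; used by the parameter-recovery and conformal
# acceptance checks.
recovery_pipeline <- function() {
  cached("recovery_pipeline", {
    ucod_pipeline(
      recovery_catalog(), recovery_records(),
      pre_config = train_config(lr = 1e-2, epochs_pretrain = 15, patience = 3,
                                seed = 42),
      ft_config = train_config(lr = 1e-2, epochs_finetune = 25, patience = 5,
                               seed = 42),
      dec = decoding_config(seed = 42),
      seed = 42
    )
  })
}
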
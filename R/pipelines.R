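#' Build a tokenizer covering a corpus and catalog
#'
#' The word-level vocabulary is collected from the rendered prompts of all
#' records, the catalog's titles (the generation targets) and the template's
#' instruction strings, so that encoding is stable across splits.
#'
#' @param records list of `certificate` objects.
#' @param catalog a `code_catalog`.
#' @param template a `prompt_template`.
#' @return A `word_tokenizer`.
#' @export
corpus_tokenizer <- function(records, catalog, template = default_template()) {
  prompts <- vapply(records, render_prompt, character(1),
                    template = template, task = "ucod")
  word_tokenizer(c(prompts, catalog$entries$title,
                   unname(template$instructions), template$output_prefix))
}

#' End-to-end underlying-cause coding experiment
#'
#' Convenience wrapper running the full study pipeline on a labeled corpus:
#' stratified 80/10/10 split, tokenizer and description-trie construction,
#' continual causal pre-training, constrained-decoding prediction on the test
#' split, optional fine-tuning of the discriminative echo-embedding
#' classifier, and hierarchical evaluation of both coders.
#'
#' @param catalog a `code_catalog`.
#' @param records labeled `certificate` list.
#' @param fractions split fractions (train, validation, test).
#' @param template a `prompt_template`.
#' @param pre_config [train_config()] for causal pre-training.
#' @param ft_config [train_config()] for classifier fine-tuning.
#' @param dec [decoding_config()] for constrained decoding.
#' @param dim,hidden backbone dimensions.
#' @param seed master seed (model init and split).
#' @param coders which coders to run.
#' @param verbose print training progress.
#' @return List with the fitted artifacts (`tokenizer`, `trie`, `model`,
#'   `classifier`), the `split`, per-coder test predictions/distributions and
#'   hierarchical metric tables.
#' @export
ucod_pipeline <- function(catalog, records, fractions = c(0.8, 0.1, 0.1),
                          template = default_template(),
                          pre_config = train_config(lr = 3e-3, epochs_pretrain = 5),
                          ft_config = train_config(lr = 3e-3, epochs_finetune = 20),
                          dec = decoding_config(),
                          dim = 24, hidden = 64, seed = 1L,
                          coders = c("generative", "discriminative"),
                          verbose = FALSE) {
  coders <- match.arg(coders, several.ok = TRUE)
  split <- stratified_split(records, fractions, seed = seed)
  tokenizer <- corpus_tokenizer(records, catalog, template)
  trie <- build_trie(catalog, tokenizer)
  lm <- tiny_lm(length(tokenizer$vocab), dim = dim, hidden = hidden, seed = seed)
  train_texts <- vapply(split$train, render_training_text, character(1),
                        template = template, task = "ucod", catalog = catalog)
  val_texts <- vapply(split$validation, render_training_text, character(1),
                      template = template, task = "ucod", catalog = catalog)
  pre <- train_causal(lm, train_texts, tokenizer, pre_config,
                      val_texts = val_texts, verbose = verbose)
  out <- list(tokenizer = tokenizer, trie = trie, model = pre$model,
              pretrain_history = pre$history, split = split,
              catalog = catalog, template = template)
  test_gold <- vapply(split$test, function(r) r$gold_ucod, character(1))
  out$test_gold <- test_gold
  if ("generative" %in% coders) {
    gen <- predict_ucod_all(pre$model, trie, split$test, template, tokenizer,
                            dec, catalog)
    out$generative <- c(gen, list(
      metrics = hierarchical_metrics(gen$codes, test_gold, catalog)))
  }
  if ("discriminative" %in% coders) {
    clf <- fine_tune_classifier(pre$model, split$train, template, tokenizer,
                                ft_config, val_records = split$validation,
                                verbose = verbose)
    dis <- classify_all(clf, split$test)
    out$classifier <- clf
    out$discriminative <- c(dis, list(
      metrics = hierarchical_metrics(dis$codes, test_gold, catalog)))
  }
  out
}
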
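# gencoder

Coding the underlying cause of death (UCOD) on free-text death certificates
with a *generative* language model. Instead of training a discriminative
classifier over thousands of ICD-10 codes, a causal language model is trained
with a plain next-token objective on prompts built from the certificate
fields, and at inference time **constrained decoding** over a trie of code
descriptions forces every generated output to be the title of a valid ICD-10
code. The k sampled sequences are re-ranked by their length-normalized log
probability, and a temperature-scaled softmax over those scores turns the
generations into a probability distribution over the whole code space — which
is what downstream public-health machinery needs: conformal prediction sets
with coverage guarantees for human-in-the-loop coding, and probabilistic
quantification of weekly cause-of-death prevalence.

The package is aimed at researchers in mortality surveillance and clinical
NLP who want to study this pipeline end to end without access to confidential
certificate registries: a synthetic-data module generates code ontologies and
certificate corpora with the long-tailed (Zipf-like) label distribution that
real mortality data exhibits, and a tiny self-contained causal language model
(pure R, hand-written backprop) makes every stage trainable on one CPU in
minutes.

## The method in brief

**Generative coder.** Each certificate is rendered into a textual prompt
(context preamble, Part I chain of events, optional Part II / clinical
bulletin / autopsy / coder notes, gender and age, task instruction, output
prefix). Continual pre-training minimizes cross-entropy over *all* tokens of
prompt + gold code title. At inference, decoding is restricted at every step
to the token set allowed by a prefix trie over the tokenized code titles;
sampling uses the top-k admissible tokens (k = 10). Each of the k returned
sequences gets the score

    s(y) = (1/T) * sum_t log p(y_t | y_<t, prompt)

and the distribution over codes is `softmax(s / tau)` with temperature
tau = 0.01, zero outside the returned codes. Restricting the trie to a code
subset restricts predictions to that subset with no retraining.

**Discriminative coder.** The same backbone is fine-tuned as a classifier
using *echo embeddings*: the prompt is fed twice, so second-copy tokens can
attend over the complete text despite unidirectional context, and the
second-copy hidden states are pooled with position-linear weights
`w_i = i / (T(T+1)/2)` before a linear softmax head over the label space.

**Conformal prediction.** Split conformal calibration (lac or aps scores) on
held-out distributions yields prediction sets with marginal coverage
`>= 1 - alpha` (default alpha = 0.1), evaluated per ICD level
(chapter / block / full-code) with set-size histograms.

**Quantification.** Weekly prevalence of a code group (e.g. blocks I20–I25)
is estimated by Classify-and-Count (fraction of argmax predictions in the
group) and Probabilistic Classify-and-Count (mean posterior group mass),
with a TP/FP/FN decomposition against manual coding.

## Worked example

Thirty synthetic codes, 3,000 certificates, full pipeline (split, causal
pre-training, constrained decoding, echo-embedding classifier) — about one
minute on one CPU:

```r
library(gencoder)

catalog <- make_ontology(n_chapters = 4, n_blocks = 12, n_codes = 30, seed = 1)
records <- sample_certificates(catalog, 3000, zipf = 1, noise = 0,
                               multi_rate = 0, seed = 1)

pipe <- ucod_pipeline(
  catalog, records,
  pre_config = train_config(lr = 1e-2, epochs_pretrain = 15, patience = 3, seed = 1),
  ft_config  = train_config(lr = 1e-2, epochs_finetune = 20, patience = 5, seed = 1),
  dec = decoding_config(k = 10, top_k = 10, temperature = 0.01, seed = 1),
  seed = 1
)
pipe$generative$metrics
#> # A tibble: 3 × 6
#>   level       n accuracy macro_precision macro_recall macro_f1
#> 1 chapter   290    0.983           0.939        0.925    0.930
#> 2 block     290    0.983           0.964        0.908    0.915
#> 3 full      290    0.983           0.905        0.933    0.914
```

Held-out full-code accuracy is 98.3% for the generative coder (the
discriminative coder reaches 100% on this corpus); accuracy can only grow as
codes are coarsened to blocks and chapters. A single prediction carries its
re-ranked code distribution:

```r
r <- pipe$split$test[[1]]
pred <- predict_ucod(pipe$model, pipe$trie, r, pipe$template, pipe$tokenizer,
                     decoding_config(seed = 2), catalog)
pred$code
#> [1] "A02.1"      # gold: A02.1
round(sort(pred$distribution[pred$distribution > 0], decreasing = TRUE), 4)
#> A02.1 A04.2 A02.0
#>     1     0     0
```

With temperature 0.01 the softmax over sequence scores is effectively a point
mass on the best-scored code; the other sampled codes keep vanishing mass.
Conformal sets on the classifier's distributions (alpha = 0.1, lac score,
calibrated on half of the 290 test records):

```r
dists <- classify_all(pipe$classifier, pipe$split$test)$distributions
gold <- pipe$test_gold
half <- seq_len(145)
cm <- conformal_calibrate(dists[half, ], gold[half], alpha = 0.1, score = "lac")
sets <- conformal_predict_sets(cm, dists[-half, ])
table(lengths(sets))
#>   0   1
#>  19 126
conformal_report(sets, gold[-half], catalog)$coverage
#>   level   coverage
#> 1 chapter    0.869
#> 2 block      0.869
#> 3 full       0.869
```

Most sets are singletons — the regime in which a human coder can cheaply
review suggestions. Empirical coverage on these 145 records is 0.869 against
the 0.9 target; at this sample size the binomial standard error is ±0.025,
and the test suite verifies the guarantee at n = 2,000 over 20 splits.

A command-line wrapper over the same functions is installed at
`system.file("cli", "gencoder", package = "gencoder")` with subcommands
`synth`, `pretrain`, `train-classifier`, `code`, `classify`, `conformal`,
`quantify` and `evaluate`; every run writes a reproducibility manifest.

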
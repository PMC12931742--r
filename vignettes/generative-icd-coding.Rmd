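---
title: "Generative ICD-10 coding of death certificates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative ICD-10 coding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `gencoder`, the assumptions
behind them, the parameters that matter, and the design decisions that were
genuinely open — in the spirit of a methods section rather than a function
reference.

## Problem setting

A death certificate carries a causal chain of free-text statements (Part I,
up to four fields, ordered from the immediate cause down to the underlying
one), optional contributing conditions (Part II), sometimes a clinical
bulletin or autopsy report, coder annotations, and structured covariates
(gender, age, week of death). National statistics offices assign to each
certificate a single ICD-10 code for the underlying cause of death (UCOD),
and often a set of codes for all mentioned causes. The ICD-10 label space is
hierarchical: full codes (e.g. `C80.9`) nest in blocks (first three
characters, `C80`) which nest in chapters (Roman numerals, e.g. `II` for
neoplasms). Real registries exhibit an extremely imbalanced, long-tailed
label distribution over thousands of codes.

## The generative coder

### Training objective

Certificates are rendered into textual prompts by a deterministic template:
preamble, each present field under a natural-language label, the covariates,
a task instruction and an output prefix. Absent optional sections are
omitted; unknown gender or age is rendered as an explicit "unknown" phrase,
because certificates genuinely lacking the information exist and the model
should learn that state rather than conflate it with omission. Training
texts append the gold code's descriptive *title* and an end-of-sequence
marker, and the cross-entropy loss is applied to **all** tokens of the
instance — prompt included — not only to the expected output. Monitoring is
on validation loss with early stopping.

### Constrained decoding

The label space enters only at inference. A prefix trie is built over the
tokenized code titles; every root-to-terminal path is exactly one title plus
an explicit end-of-sequence token. At each generation step the admissible
tokens are the trie's continuations of the current prefix; the sampling pool
is the `top_k` admissible tokens by model probability, renormalized. Two
consequences follow by construction:

* every completed sequence resolves to exactly one catalog code — validity is
  100% even for an untrained model;
* a title that is a strict prefix of another remains decodable, because
  stopping requires explicitly emitting the end-of-sequence token.

The *masking-first* ordering (apply the trie mask to the full logit vector,
then take the top-k among admissible tokens) was an open choice; the
alternative — intersecting an unconstrained top-k with the mask — can yield
an empty pool. Masking-first guarantees progress and is what the validity
property requires.

Generating *titles* rather than code strings is the default because it keeps
the approach open-vocabulary: a code never seen as a training label can still
be assigned when decoding is restricted to a label set that includes it. A
`code` target mode exists as an option.

### Scores and the code distribution

Each of the `k` independently sampled sequences is scored by its mean token
log-probability (the length-normalized joint log-probability; per-token
values are the model's unconstrained log-softmax entries, so the score equals
the chain-rule value and is checked against it in the tests). Sequences
resolving to the same code are merged keeping the best score — re-ranking is
over *codes*, so one score per code; max preserves the ranking semantics
(summing would conflate sampling multiplicity with model confidence).
The distribution over codes is a temperature-scaled softmax of the scores,
zero outside the returned codes; it therefore has support at most `k`. With
the default temperature 0.01 it is near-degenerate on the best code — the
point is not calibration of the top-1 mass but a usable ranking for
conformal sets and quantification. The softmax is computed with
max-subtraction; at equal scores it is exactly uniform, and as the
temperature goes to zero it converges to a point mass on the best-scored
code.

### Multiple causes

The same trained model predicts all causes of a certificate: generation
alternates trie-constrained title segments with a free choice, available only
when a complete title has just been generated, between a delimiter token
(continue) and the stop token. The delimiter/stop decision points are the
only unconstrained steps, so every emitted segment is still a valid title.
The output is the de-duplicated code set in generation order; gold causes are
rendered in certificate field order (a canonical-sort option exists).

## The discriminative coder

The alternative is a standard classification head on the same backbone. To
compensate for unidirectional attention, the prompt is repeated twice around
a separator ("echo" embeddings): tokens of the second copy see the entire
first copy, emulating bidirectional context. Only second-copy hidden states
are pooled, with 1-based position-linear weights

\[ w_i = \frac{i}{\sum_{j=1}^{T} j} = \frac{2i}{T(T+1)}, \]

which sum to one and grow strictly, weighting the end of the prompt more.
A fully-connected layer projects the pooled embedding to the label space;
backbone and head are trained jointly with categorical cross-entropy,
monitoring validation macro-F1 (full-code) with early stopping and returning
the best checkpoint. The label space is the set of codes observed in
training (the split guarantees every code appears there). No L2
normalization is applied to the pooled embedding before the head — the
reference procedure does not state one, and the flag is recorded here. If
the doubled prompt ever exceeded a context budget, the *first* copy would be
truncated from its start: the pooling only reads second-copy states, so
those inputs are preserved.

Unlike the generative distribution (support at most `k`), the classifier's
distribution has full support — a behavioural difference that propagates
into conformal set shapes.

## The reference language model

No deep-learning framework is assumed: `tiny_lm()` is a small autoregressive
model in base R with hand-written backpropagation and AdamW. At position
`t` the prediction input is the pair (mean of embeddings of tokens `1..t`,
embedding of token `t`) — a global bag-of-context channel plus a local
bigram channel — through one `tanh` layer, with a linear LM head. The model
is causal by construction, its log-probability vectors normalize, and
initialization, data order and sampling are all seeded. The same hidden
states serve as the contextual token embeddings pooled by the echo
classifier. Gradients are verified against central finite differences in the
test suite.

The tokenizer is word-level (lower-cased whitespace splitting) with reserved
`<bos>`, `<eos>`, `<sep>`, `<unk>` tokens. This keeps the trie and its
brute-force oracles auditable by eye; the contracts admit sub-word
tokenizers for larger models. Whether sub-word merges could make two
distinct titles tokenize identically is left as data-dependent: identical
tokenizations are a hard error at trie construction, with an optional
" (CODE)" disambiguation suffix at catalog load.

### Training hyperparameters

`train_config()` defaults encode the study settings: effective batch size 32
(realized by gradient accumulation), AdamW with a constant learning rate of
2e-5 and no warm-up, at most 5 pre-training epochs (validation loss), at most
20 fine-tuning epochs (validation macro-F1), patience 2. The 2e-5 rate is
appropriate for fine-tuning billion-parameter backbones; the tiny reference
model trains *from scratch*, so the desk-scale experiments in the tests and
the acceptance script pass `lr = 1e-2` — a standard Adam-family rate for a
small randomly-initialized network — together with somewhat longer schedules
(up to 15 pre-training epochs with patience 3, up to 25 fine-tuning epochs
with patience 5), reflecting that an epoch over a few thousand short
sequences contains only ~100 gradient steps. Gradient clipping and warm-up
are not used; weight decay defaults to AdamW's 0.01. All of these live in
the config object and the checkpoint manifest rather than being silently
fixed.

## Conformal prediction

Split conformal calibration turns any of the coders' distributions into
prediction sets with a distribution-free marginal guarantee: with
calibration scores \(s_1,\dots,s_n\) and the threshold \(\hat q\) set to the
\(\lceil (n+1)(1-\alpha)\rceil / n\) empirical quantile (the finite-sample
correction is what yields the guarantee; if the rank exceeds \(n\), the
threshold is infinite), sets contain the gold code with probability at least
\(1-\alpha\) under exchangeability. Two score functions are provided:

* **lac** — `1 - p(gold)`; test sets are `{c : 1 - p(c) <= q}`. Sets may be
  empty; they are reported as such (a `force_nonempty` flag adds the argmax),
  and deterministic lac attains essentially exact coverage,
  \(1-\alpha \le \mathrm{cov} \le 1-\alpha + 1/(n+1)\) up to score ties.
* **aps** — the cumulative probability mass down to and including the gold
  code; test sets are the smallest probability-ordered prefix reaching
  \(\hat q\), ties broken by code order. Implemented *without* boundary
  randomization so sets are reproducible; the price is over-coverage that
  grows with the model's confidence (the last included class contributes its
  whole mass). For this reason the coverage-band checks in the test suite
  use lac, while aps remains the default for producing adaptive sets.

Coverage is reported per ICD level by mapping both gold and set members to
the level; coarsening can only turn misses into hits, so chapter coverage ≥
block coverage ≥ full-code coverage. With a well-trained classifier at
\(\alpha = 0.1\) the modal set size is 1 — the regime useful for coder
review queues.

## Quantification

For a code group (explicit set or block range such as `I20-I25`; a full code
belongs to a range through its block), weekly prevalence is estimated two
ways: **CC** counts argmax classifications in the group; **PCC** averages
the posterior group mass. PCC equals CC exactly under one-hot distributions,
is additive over disjoint groups, and is unbiased when the distributions are
the true posteriors — under a misspecified or overconfident classifier CC
inherits the classifier's bias while PCC softens it, which is why PCC's
weekly error is lower in the simulation with oracle posteriors (a noisy-label
channel over a seasonally varying prevalence). Generative distributions
(support ≤ k) are used as-is for PCC; the truncation is a documented
estimator property rather than being corrected. Weeks follow ISO-8601
numbering; weeks with no certificates are omitted from the series, and the
TP/FP/FN decomposition satisfies `manual = (TP+FN)/total` and
`cc = (TP+FP)/total` by construction.

## Evaluation conventions

Hierarchical metrics map predictions and gold to the level *before* scoring;
accuracy is therefore monotone along the hierarchy. Macro averages run over
the labels present in the gold slice (not the full catalog) — evaluation
slices such as per-chapter subsets would otherwise be dominated by
structurally absent labels — and a label never predicted contributes
precision 0. Multi-label metrics de-duplicate level-mapped sets and report
both micro (pooled TP/FP/FN) and macro averages. Age subgroups default to
under-25, 25-50, 50-75, 75-100, above-100 with left-closed, right-open
boundaries (age 25 falls in 25-50); records missing the grouping field are
excluded and counted. Confusion rankings break ties lexicographically for
determinism.

## The synthetic-data generator

`make_ontology()` and `sample_certificates()` emulate the *structure* of
mortality-registry data, not its language:

* a three-level ontology (chapters ⊃ blocks ⊃ full codes) with exact
  requested counts, up to the scale of the real label space (21 chapters,
  1,131 blocks, 3,644 codes);
* titles that pair an adjective with a per-code unique noun built from
  clinical morphemes. The unique content word mirrors how real code titles
  are mostly identifiable by a distinctive term, and it is what makes the
  noise-free corpus a *separable* task — the text determines the code — so
  that parameter-recovery runs have a known ceiling;
* a Zipf-ranked label distribution (`zipf = 1` by default; exponent 0 gives
  uniform labels) reproducing the long tail;
* covariates (gender, age centred on old age, ISO week) and optional
  auxiliary causes whose titles appear in Part II.

The generator does **not** emulate Portuguese clinical language, negation,
misspellings, inter-coder disagreement, or the correlation structure between
covariates and causes. Passing tests on synthetic corpora therefore
demonstrate the *mechanics* of the pipeline (validity, coverage, estimator
behaviour, trainability), not clinical-grade accuracy on real certificates.

Two generator choices deserve emphasis. First, the separable
parameter-recovery corpus is drawn with `multi_rate = 0`: auxiliary-cause
titles in Part II are indistinguishable from the Part-I title for a
bag-of-context backbone, so they would turn label recovery into an
order-discrimination task the reference model is intentionally too simple to
solve; the multi-cause experiments use their own corpora with
`multi_rate > 0` and the multi-cause target. Second, label noise defaults to
0 and exists only for robustness experiments — baselines need the known
ceiling.

`stratified_split()` allocates each code's instances as close to 80/10/10 as
integers allow, rounding in favour of training then validation, which yields
8/1/1 for a ten-instance code and guarantees every code at least one
training instance (single-instance codes go entirely to training). The
splits are disjoint and exhaustive.

## Problem sizes and numerical choices

The test suite and acceptance script use: a 200-code catalog for the
validity and trie-oracle checks (1,000 generations; every reachable prefix);
a 50-code, 5,000-record separable corpus for parameter recovery (held-out
accuracy ≥ 95% for both coders); 4,000 fresh records with 20 random
2,000/2,000 calibration/test splits for the coverage band; and 50 weeks ×
400 records with an exact noisy-channel posterior for quantification. These
sizes keep any single run in the minutes range on one CPU while leaving the
statistical checks well-powered.

Numerical details: log-softmax and score-softmax use max-subtraction;
distribution validation tolerates 1e-6 row-sum error; the conformal quantile
is the exact order statistic, not an interpolated quantile; equal conformity
scores share the fate of the threshold score deterministically. Degenerate
inputs are defined rather than accidental: a single-code trie decodes to
that code with probability 1; a one-token second copy pools to that token's
hidden state; `pooling_weights(1)` is 1; an empty allowed-code set,
non-positive temperature, or α outside (0,1) are argument errors.

## Limitations

The reference model is a deliberately small stand-in: it establishes the
contracts (causality, normalization, hidden states) and the end-to-end
behaviour of the method at desk scale, but its bag-of-context architecture
cannot use word order, so tasks that hinge on field position (e.g. UCOD
selection among several mentioned causes) are outside its reach — swapping
in a stronger causal LM behind the same contract is the intended path.
Conformal guarantees are marginal, not class-conditional; aps sets are
deterministic and over-cover; quantification implements CC and PCC only (no
adjusted or distribution-matching quantifiers). ICD-11, code-set versioning
and WHO licensing are out of scope.
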
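Package: gencoder
Title: Generative ICD-10 Coding of Death Certificates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns ICD-10 codes to free-text death certificates with a small
    causal language model. Inference uses constrained decoding over a trie of
    code descriptions, so every generated output is a valid code, and converts
    re-ranked sampled sequences into a probability distribution over the code
    space. A discriminative alternative fine-tunes the same backbone with echo
    embeddings (position-weighted pooling over a repeated prompt) and a linear
    classification head. On top of either coder the package provides split
    conformal prediction sets with marginal coverage guarantees, prevalence
    estimation for public-health surveillance by Classify-and-Count and
    Probabilistic Classify-and-Count, hierarchical (chapter/block/full-code)
    and multi-label evaluation, and a synthetic death-certificate generator
    with a long-tailed label distribution so the whole pipeline can be
    exercised without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
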
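# Vocabulary for synthetic code titles built from clinical-flavoured
# morphemes: each code receives a unique noun (simple stem+suffix forms first,
# then compound stem-o-stem forms), qualified by an adjective. The unique noun
# makes every code identifiable from a single content word, which is what
# real code titles mostly look like and what makes the noise-free corpus a
# separable learning task. 200 simple + 3,800 compound nouns cover ontologies
# at the scale of the full ICD-10 mortality label set.
synthetic_title_vocab <- function() {
  adjectives <- c(
    "acute", "chronic", "severe", "mild", "recurrent", "progressive",
    "congenital", "idiopathic", "secondary", "primary", "malignant", "benign",
    "diffuse", "focal", "bilateral", "unilateral", "obstructive",
    "hemorrhagic", "ischemic", "septic", "viral", "bacterial", "toxic",
    "degenerative", "metastatic", "unspecified", "complicated", "fulminant",
    "latent", "refractory", "subacute", "terminal", "advanced", "generalized",
    "localized", "persistent", "transient", "atypical", "familial", "senile")
  stems <- c("cardi", "nephr", "hepat", "pneum", "neur", "gastr", "derm",
             "oste", "arthr", "angi", "myel", "encephal", "col", "enter",
             "phleb", "bronch", "laryng", "rhin", "splen", "ophthalm")
  suffixes <- c("itis", "osis", "opathy", "algia", "emia", "oma", "ectasia",
                "osclerosis", "odynia", "orrhage")
  simple <- as.vector(outer(stems, suffixes, paste0))
  pairs <- expand.grid(a = stems, b = stems, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  compound <- as.vector(outer(paste0(pairs$a, "o", pairs$b),
                              suffixes, paste0))
  list(adjectives = adjectives, nouns = c(simple, compound))
}

synthetic_fillers <- function() {
  c("cardiorespiratory arrest", "multiorgan failure", "terminal event",
    "respiratory insufficiency", "circulatory collapse")
}

synthetic_noise_words <- function() {
  c("patient", "history", "longstanding", "reported", "probable", "suspected",
    "known", "recent", "prior", "documented")
}

#' Generate a synthetic code ontology
#'
#' Builds a catalog with the three-level structure of ICD-10: `n_chapters`
#' chapters (Roman numerals), `n_blocks` blocks (letter plus two digits,
#' distributed as evenly as possible across chapters) and `n_codes` full codes
#' (distributed as evenly as possible across blocks; a block holding a single
#' code uses the bare three-character form, otherwise decimal subdivisions).
#' Titles pair an adjective with a per-code unique noun from a built-in
#' clinical-flavoured vocabulary, so every code has a distinctive content word.
#'
#' @param n_chapters,n_blocks,n_codes requested counts
#'   (`n_chapters <= n_blocks <= n_codes`).
#' @param seed RNG seed (title assignment).
#' @return A `code_catalog` whose [catalog_counts()] equal the requested sizes.
#' @export
make_ontology <- function(n_chapters = 2, n_blocks = 4, n_codes = 8, seed = 1L) {
  stopifnot(n_chapters >= 1, n_blocks >= n_chapters, n_codes >= n_blocks)
  if (n_blocks > 2600) stop("generation error: at most 2600 blocks supported")
  voc <- synthetic_title_vocab()
  if (n_codes > length(voc$nouns)) {
    stop("generation error: title vocabulary exhausted (max ",
         length(voc$nouns), " codes)")
  }
  set.seed(seed)
  noun <- sample(voc$nouns, n_codes)
  adj <- sample(voc$adjectives, n_codes, replace = TRUE)
  titles <- paste(adj, noun)

  blocks <- vapply(seq_len(n_blocks) - 1L, function(b) {
    sprintf("%s%02d", LETTERS[b %/% 100 + 1L], b %% 100)
  }, character(1))
  # blocks per chapter, then codes per block, spreading remainders forward
  even_split <- function(total, bins) {
    base <- total %/% bins
    cnt <- rep(base, bins)
    if (total %% bins > 0) cnt[seq_len(total %% bins)] <- base + 1L
    cnt
  }
  bpc <- even_split(n_blocks, n_chapters)
  chap_of_block <- rep(as.character(utils::as.roman(seq_len(n_chapters))), bpc)
  cpb <- even_split(n_codes, n_blocks)
  codes <- unlist(lapply(seq_len(n_blocks), function(b) {
    if (cpb[b] == 1L) blocks[b]
    else paste0(blocks[b], ".", seq_len(cpb[b]) - 1L)
  }))
  chapters <- rep(chap_of_block, cpb)
  code_catalog(codes, titles, chapters)
}

#' Sample synthetic death certificates
#'
#' Gold underlying causes are drawn from a Zipf-ranked distribution over the
#' catalog (`p(rank r) proportional to r^-zipf`; exponent 0 gives a uniform
#' label distribution, exponent around 1 the long-tailed shape typical of
#' mortality data). Part I text is built from the gold code's title plus
#' generic filler phrases; with probability `noise` uninformative noise words
#' are added, so with `noise = 0` and the injective built-in templates the
#' text determines the code exactly (a separable task). With probability
#' `multi_rate` the record carries auxiliary causes (their titles appear in
#' Part II) and `gold_causes` lists the underlying plus auxiliary codes.
#' `label_noise` replaces the gold code (label only, not the text) with a
#' random one, for robustness experiments.
#'
#' @param catalog a `code_catalog`.
#' @param n number of records.
#' @param zipf Zipf exponent of the label distribution (default 1).
#' @param noise probability of injecting noise words into Part I.
#' @param multi_rate probability of auxiliary causes.
#' @param weeks number of ISO weeks spanned.
#' @param week_start first week number (later-period corpora for surveillance
#'   experiments are produced by shifting this).
#' @param label_noise probability of replacing the gold label by a random code.
#' @param seed RNG seed.
#' @return List of `certificate` objects.
#' @export
sample_certificates <- function(catalog, n, zipf = 1, noise = 0.05,
                                multi_rate = 0.3, weeks = 26L,
                                week_start = 1L, label_noise = 0, seed = 1L) {
  stopifnot(inherits(catalog, "code_catalog"), n >= 1)
  set.seed(seed)
  K <- nrow(catalog$entries)
  prob <- seq_len(K)^(-zipf)
  prob <- prob / sum(prob)
  gi <- sample.int(K, n, replace = TRUE, prob = prob)
  fillers <- synthetic_fillers()
  noisew <- synthetic_noise_words()
  lapply(seq_len(n), function(i) {
    g <- gi[i]
    title <- catalog$entries$title[g]
    p1 <- title
    if (stats::runif(1) < noise) {
      p1 <- paste(sample(noisew, 1), p1)
    }
    part1 <- if (stats::runif(1) < 0.5) c(sample(fillers, 1), p1) else p1
    aux <- integer(0)
    part2 <- NULL
    if (stats::runif(1) < multi_rate) {
      n_aux <- min(3L, 1L + stats::rpois(1, 0.7))
      aux <- setdiff(sample.int(K, n_aux, replace = TRUE, prob = prob), g)
      if (length(aux) > 0) {
        part2 <- paste(catalog$entries$title[aux], collapse = " ; ")
      }
    }
    gender <- if (stats::runif(1) < 0.01) "unknown" else
      sample(c("male", "female"), 1)
    age <- if (stats::runif(1) < 0.01) NA else
      min(110, max(0, round(stats::rnorm(1, 80, 12))))
    gold <- catalog$entries$code[g]
    if (label_noise > 0 && stats::runif(1) < label_noise) {
      gold <- catalog$entries$code[sample.int(K, 1)]
    }
    certificate(
      part1 = part1, part2 = part2, gender = gender, age = age,
      week = week_start + sample.int(weeks, 1) - 1L,
      gold_ucod = gold,
      gold_causes = c(gold, catalog$entries$code[aux]),
      id = sprintf("r%06d", i)
    )
  })
}

#' Stratified train/validation/test split
#'
#' Splits records per gold code as close to the requested fractions as integer
#' counts allow, guaranteeing that every code appears at least once in the
#' training split: a code with 10 instances is split 8/1/1, a code with a
#' single instance goes entirely to training. Integer rounding favours the
#' training split, then validation. The three splits are disjoint and
#' exhaustive.
#'
#' @param records list of `certificate` objects with gold labels.
#' @param fractions numeric length-3 vector summing to 1
#'   (train, validation, test).
#' @param seed RNG seed (assignment within each code).
#' @return List with elements `train`, `validation`, `test`.
#' @export
stratified_split <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  set.seed(seed)
  golds <- vapply(records, function(r) r$gold_ucod, character(1))
  if (anyNA(golds)) stop("all records need a gold_ucod for stratified splitting")
  idx_tr <- idx_va <- idx_te <- integer(0)
  for (cd in unique(golds)) {
    ii <- which(golds == cd)
    ii <- ii[sample.int(length(ii))]
    nc <- length(ii)
    n_tr <- max(1L, round(fractions[1] * nc))
    rem <- nc - n_tr
    n_va <- if (fractions[2] + fractions[3] > 0) {
      ceiling(rem * fractions[2] / (fractions[2] + fractions[3]))
    } else 0L
    idx_tr <- c(idx_tr, ii[seq_len(n_tr)])
    if (rem > 0) {
      idx_va <- c(idx_va, ii[n_tr + seq_len(n_va)])
      if (rem - n_va > 0) idx_te <- c(idx_te, ii[(n_tr + n_va) + seq_len(rem - n_va)])
    }
  }
  list(train = records[sort(idx_tr)],
       validation = records[sort(idx_va)],
       test = records[sort(idx_te)])
}
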
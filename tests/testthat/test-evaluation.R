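# Independent per-label oracle: table-based confusion counts, written
# differently from the package implementation.
oracle_prf <- function(pred, gold) {
  labels <- sort(unique(gold))
  prec <- rec <- f1 <- numeric(length(labels))
  for (i in seq_along(labels)) {
    l <- labels[i]
    tp <- sum(pred == l & gold == l)
    prec[i] <- if (sum(pred == l) > 0) tp / sum(pred == l) else 0
    rec[i] <- if (sum(gold == l) > 0) tp / sum(gold == l) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

random_slice <- function(cat, n, err = 0.4, seed = 1) {
  set.seed(seed)
  codes <- cat$entries$code
  gold <- sample(codes, n, replace = TRUE, prob = seq_along(codes)^-1)
  pred <- gold
  flip <- sample(n, round(err * n))
  pred[flip] <- sample(codes, length(flip), replace = TRUE)
  list(pred = pred, gold = gold)
}

test_that("hierarchy mapping scores levels independently", {
  cat <- toy_catalog()
  m <- hierarchical_metrics("C80.9", "C80.1", cat)
  acc <- stats::setNames(m$accuracy, m$level)
  expect_equal(unname(acc["full"]), 0)
  expect_equal(unname(acc["block"]), 1)
  expect_equal(unname(acc["chapter"]), 1)
  perfect <- hierarchical_metrics(c("I21", "I64"), c("I21", "I64"), cat)
  expect_true(all(perfect$accuracy == 1) && all(perfect$macro_f1 == 1))
})

test_that("macro metrics match the per-label oracle on random slices", {
  cat <- make_ontology(4, 15, 60, seed = 3)
  for (seed in 1:3) {
    sl <- random_slice(cat, 500, seed = seed)
    for (lv in c("full", "block", "chapter")) {
      m <- hierarchical_metrics(sl$pred, sl$gold, cat, levels = lv)
      o <- oracle_prf(map_to_level(sl$pred, lv, cat),
                      map_to_level(sl$gold, lv, cat))
      expect_equal(m$macro_precision, o$precision, tolerance = 1e-12)
      expect_equal(m$macro_recall, o$recall, tolerance = 1e-12)
      expect_equal(m$macro_f1, o$f1, tolerance = 1e-12)
    }
  }
})

test_that("accuracy is monotone in the hierarchy and invariant to duplication", {
  cat <- make_ontology(4, 15, 60, seed = 3)
  sl <- random_slice(cat, 400, seed = 9)
  m <- hierarchical_metrics(sl$pred, sl$gold, cat)
  acc <- stats::setNames(m$accuracy, m$level)
  expect_true(acc["chapter"] >= acc["block"] && acc["block"] >= acc["full"])
  dup <- hierarchical_metrics(rep(sl$pred, 2), rep(sl$gold, 2), cat)
  expect_equal(dup$accuracy, m$accuracy)
  expect_equal(dup$macro_f1, m$macro_f1)
})

test_that("multi-label metrics match the pooled-count oracle", {
  cat <- make_ontology(3, 10, 30, seed = 4)
  set.seed(4)
  codes <- cat$entries$code
  gold_sets <- replicate(120, sample(codes, sample(1:4, 1)), simplify = FALSE)
  pred_sets <- lapply(gold_sets, function(g) {
    keep <- g[stats::runif(length(g)) < 0.8]
    unique(c(keep, sample(codes, stats::rbinom(1, 2, 0.3))))
  })
  m <- multilabel_metrics(pred_sets, gold_sets, cat, level = "full")
  # pooled oracle
  TP <- FP <- FN <- 0
  for (i in seq_along(gold_sets)) {
    TP <- TP + length(intersect(pred_sets[[i]], gold_sets[[i]]))
    FP <- FP + length(setdiff(pred_sets[[i]], gold_sets[[i]]))
    FN <- FN + length(setdiff(gold_sets[[i]], pred_sets[[i]]))
  }
  expect_equal(m$micro_precision, TP / (TP + FP), tolerance = 1e-12)
  expect_equal(m$micro_recall, TP / (TP + FN), tolerance = 1e-12)
  # perfect prediction degenerate case
  p <- multilabel_metrics(gold_sets, gold_sets, cat)
  expect_equal(p$micro_f1, 1)
  expect_equal(p$macro_f1, 1)
  # strict supersets: recall one, precision below one
  sup <- lapply(gold_sets, function(g) unique(c(g, codes[1:2])))
  s <- multilabel_metrics(sup, gold_sets, cat)
  expect_equal(s$micro_recall, 1)
  expect_lt(s$micro_precision, 1)
})

test_that("subgroup report bins ages left-closed and excludes missing fields", {
  cat <- toy_catalog()
  mk <- function(age, gender = "male") {
    certificate("x", gender = gender, age = age, gold_ucod = "I21")
  }
  recs <- list(mk(24), mk(25), mk(99), mk(100), mk(NA), mk(50, "unknown"))
  pred <- rep("I21", 6)
  gold <- rep("I21", 6)
  rep_age <- subgroup_report(pred, gold, recs, cat, by = "age")
  expect_setequal(rep_age$group,
                  c("under-25", "25-50", "50-75", "75-100", "above-100"))
  expect_equal(attr(rep_age, "excluded"), 1)   # the record with unknown age
  expect_equal(rep_age$n[rep_age$group == "25-50"], 1)   # age 25 only
  expect_equal(rep_age$n[rep_age$group == "50-75"], 1)   # age 50 is left-closed
  expect_equal(rep_age$n[rep_age$group == "above-100"], 1)  # age 100
  rep_g <- subgroup_report(pred, gold, recs, cat, by = "gender")
  expect_equal(rep_g$group, "male")
  expect_equal(attr(rep_g, "excluded"), 1)
})

test_that("per-group accuracy recombines to the overall count-weighted mean", {
  cat <- make_ontology(3, 10, 30, seed = 6)
  sl <- random_slice(cat, 300, seed = 6)
  set.seed(6)
  recs <- lapply(seq_along(sl$gold), function(i) {
    certificate("x", gender = sample(c("male", "female"), 1),
                age = sample(20:100, 1), gold_ucod = sl$gold[i])
  })
  rep_g <- subgroup_report(sl$pred, sl$gold, recs, cat, by = "gender")
  overall <- sum(rep_g$accuracy * rep_g$n) / sum(rep_g$n)
  expect_equal(overall, mean(sl$pred == sl$gold), tolerance = 1e-12)
})

test_that("top confusions tally errors with deterministic ordering", {
  expect_equal(nrow(top_confusions(c("A01", "B02"), c("A01", "B02"))), 0)
  one <- top_confusions(rep("B02", 5), rep("A01", 5), n = 3)
  expect_equal(one$gold, "A01")
  expect_equal(one$errors, 5)
  expect_equal(one$predicted, "B02")
  expect_equal(one$count, 5L)
  # row totals equal per-code error counts from a direct tally
  cat <- make_ontology(3, 10, 30, seed = 8)
  sl <- random_slice(cat, 500, err = 0.5, seed = 8)
  tc <- top_confusions(sl$pred, sl$gold, n = 5)
  for (g in unique(tc$gold)) {
    expect_equal(tc$errors[tc$gold == g][1],
                 sum(sl$gold == g & sl$pred != sl$gold))
    expect_equal(sum(tc$count[tc$gold == g]),
                 sum(sl$gold == g & sl$pred != sl$gold))
  }
})
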
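test_that("confusion tallies hand-checked cases with ties going positive", {
  cm <- confusion(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(unclass(cm)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  # tie at threshold is predicted positive
  cm2 <- confusion(c(0.5, 0.5), c(1, 0), threshold = 0.5)
  expect_equal(cm2$TP, 1L)
  expect_equal(cm2$FP, 1L)
  # threshold 0 predicts everything positive
  cm3 <- confusion(c(0.1, 0.9), c(0, 1), threshold = 0)
  expect_equal(cm3$TN, 0L)
  expect_error(confusion(numeric(0), integer(0)), "empty")
})

test_that("metrics match the closed forms on a hand tally", {
  cm <- structure(list(TP = 50L, TN = 30L, FP = 10L, FN = 10L),
                  class = "confusion_matrix")
  m <- metrics_from_cm(cm)
  expect_equal(unname(m["acc"]), 0.8)
  expect_equal(unname(m["sen"]), 50 / 60, tolerance = 1e-12)
  expect_equal(unname(m["spe"]), 0.75)
  expect_equal(unname(m["f1"]), 100 / 120, tolerance = 1e-12)
  perfect <- structure(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L),
                       class = "confusion_matrix")
  expect_true(all(metrics_from_cm(perfect) == 1))
})

test_that("zero-denominator metrics are NaN with a warning, never silent 0", {
  cm <- structure(list(TP = 0L, TN = 4L, FP = 0L, FN = 0L),
                  class = "confusion_matrix")
  expect_warning(m <- metrics_from_cm(cm), "sensitivity")
  expect_true(is.nan(m[["sen"]]))
  expect_equal(m[["acc"]], 1)
})

test_that("AUC matches exhaustive pair counting and handles ties", {
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.4)
  y <- c(0, 0, 1, 1, 1, 0)
  # all-pairs oracle
  pos <- s[y == 1]; neg <- s[y == 0]
  pairs <- expand.grid(p = pos, n = neg)
  oracle <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  expect_equal(auc(s, y), oracle, tolerance = 1e-12)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(c(.1, .2), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  s <- runif(60)
  y <- rbinom(60, 1, s)
  if (length(unique(y)) == 2) {
    a0 <- auc(s, y)
    expect_equal(auc(plogis(5 * s - 2), y), a0, tolerance = 1e-12)
    expect_equal(auc(s^3, y), a0, tolerance = 1e-12)
  }
})

test_that("accuracy is the prevalence-weighted mix of sen and spe", {
  set.seed(32)
  s <- runif(400)
  y <- rbinom(400, 1, 0.4)
  cm <- confusion(s, y)
  m <- metrics_from_cm(cm)
  prev <- mean(y)
  expect_equal(unname(m["acc"]),
               unname(prev * m["sen"] + (1 - prev) * m["spe"]),
               tolerance = 1e-12)
})

test_that("bootstrap CI is seeded, contains the point estimate, and shrinks with n", {
  set.seed(33)
  gen <- function(n) {
    y <- rbinom(n, 1, 0.5)
    s <- plogis(rnorm(n, mean = ifelse(y == 1, 1, -1)))
    list(s = s, y = y)
  }
  d <- gen(250)
  ci1 <- bootstrap_ci(d$s, d$y, "auc", replicates = 300, seed = 1)
  ci2 <- bootstrap_ci(d$s, d$y, "auc", replicates = 300, seed = 1)
  expect_identical(ci1, ci2)
  pt <- auc(d$s, d$y)
  expect_lte(ci1$lo, pt)
  expect_gte(ci1$hi, pt)
  d2 <- gen(4000)
  ci_big <- bootstrap_ci(d2$s, d2$y, "auc", replicates = 300, seed = 1)
  expect_lt(ci_big$hi - ci_big$lo, ci1$hi - ci1$lo)
  # perfect classifier: zero-variance accuracy CI collapses
  yperf <- rep(c(0, 1), 20)
  sperf <- ifelse(yperf == 1, 0.99, 0.01)
  cip <- bootstrap_ci(sperf, yperf, "acc", replicates = 100, seed = 2)
  expect_equal(cip$lo, 1)
  expect_equal(cip$hi, 1)
})

test_that("evaluate produces a full, self-consistent, reproducible report", {
  set.seed(34)
  cfg <- glnet_config(input_dim = 6, embed_dim = 8, ssm_state_dim = 3, seed = 2)
  m <- init_model(cfg)
  n <- 80
  ds <- structure(list(x = matrix(rnorm(n * 6), n), columns = paste0("c", 1:6),
                       y = rbinom(n, 1, 0.5), standardized = TRUE),
                  class = "encoded_dataset")
  r1 <- evaluate(m, ds, replicates = 200, seed = 7)
  r2 <- evaluate(m, ds, replicates = 200, seed = 7)
  r1$scores <- r2$scores <- NULL
  expect_identical(r1, r2)
  r <- evaluate(m, ds, replicates = 200, seed = 7)
  expect_named(r$metrics, c("auc", "acc", "sen", "spe", "f1"))
  # self-consistency: report metrics equal metrics recomputed from scores
  expect_equal(r$metrics$auc$point, auc(r$scores, r$labels))
  mm <- suppressWarnings(metrics_from_cm(confusion(r$scores, r$labels, r$threshold)))
  expect_equal(r$metrics$acc$point, unname(mm["acc"]))
  expect_equal(r$metrics$f1$point, unname(mm["f1"]))
  for (v in r$metrics) expect_true(v$lo <= v$point && v$point <= v$hi)
  # an untrained model is near chance on random labels
  expect_lt(abs(r$metrics$auc$point - 0.5), 0.2)
  f <- tempfile(fileext = ".json")
  report_to_json(r, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$metrics$auc$percent$point, 100 * r$metrics$auc$point,
               tolerance = 1e-9)
})
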
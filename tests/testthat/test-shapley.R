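# Toy models used throughout: closures mapping a row matrix to predictions.
lin_model <- function(beta) function(X) as.numeric(as.matrix(X) %*% beta)
prod_model <- function(X) as.matrix(X)[, 1] * as.matrix(X)[, 2]

test_that("value function hits its endpoints and ignores S for constant models", {
  set.seed(41)
  bg <- matrix(rnorm(20 * 3), 20)
  x <- rnorm(3)
  f <- lin_model(c(1, -2, 0.5))
  expect_equal(value_function(f, x, 1:3, bg), f(matrix(x, 1)))
  expect_equal(value_function(f, x, integer(0), bg), mean(f(bg)))
  const <- function(X) rep(0.7, nrow(as.matrix(X)))
  expect_equal(value_function(const, x, c(1, 3), bg), 0.7)
  expect_error(value_function(f, x, 1, bg[0, , drop = FALSE]), "background")
})

test_that("exact Shapley satisfies additivity, the hand-enumerated product case, and dummy", {
  # additive model, zero background: phi = beta * x
  f <- lin_model(c(1, 1))
  bg <- matrix(0, 1, 2)
  x <- c(3, 5)
  vf <- function(S) value_function(f, x, S, bg)
  phi <- exact_shapley(vf, 2)
  expect_equal(as.numeric(phi), c(3, 5), tolerance = 1e-12)
  # f = x1*x2 at (1,1), zero background: enumerating the 4 subsets gives (1/2, 1/2)
  vf2 <- function(S) value_function(prod_model, c(1, 1), S, matrix(0, 1, 2))
  phi2 <- exact_shapley(vf2, 2)
  expect_equal(as.numeric(phi2), c(0.5, 0.5), tolerance = 1e-12)
  # dummy: unused third feature gets exactly zero
  f3 <- function(X) as.matrix(X)[, 1] + 2 * as.matrix(X)[, 2]
  set.seed(42)
  bg3 <- matrix(rnorm(30), 10, 3)
  vf3 <- function(S) value_function(f3, c(1, 2, 9), S, bg3)
  phi3 <- exact_shapley(vf3, 3)
  expect_equal(as.numeric(phi3[3]), 0, tolerance = 1e-12)
  expect_error(exact_shapley(vf3, 20), "limit")
})

test_that("exact Shapley satisfies efficiency and symmetry", {
  set.seed(43)
  d <- 6
  W <- rnorm(d)
  f <- function(X) plogis(as.matrix(X) %*% W + 0.3 *
                            as.matrix(X)[, 1] * as.matrix(X)[, 2])
  bg <- matrix(rnorm(15 * d), 15)
  x <- rnorm(d)
  vf <- function(S) value_function(f, x, S, bg)
  phi <- exact_shapley(vf, d)
  expect_equal(sum(phi) + attr(phi, "base_value"), f(matrix(x, 1)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # symmetry: exchangeable features get equal credit
  fsym <- function(X) (as.matrix(X)[, 1] + as.matrix(X)[, 2])^2
  xs <- c(1.2, 1.2, -0.4)
  bgs <- matrix(rep(c(0.5, 0.5, 0), each = 8), 8)
  vfs <- function(S) value_function(fsym, xs, S, bgs)
  ps <- exact_shapley(vfs, 3)
  expect_equal(ps[1], ps[2], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("sampled Shapley is seeded, exact for additive models, and near exact otherwise", {
  set.seed(44)
  d <- 8
  W <- rnorm(d)
  f <- function(X) plogis(as.matrix(X) %*% W +
                            0.5 * as.matrix(X)[, 1] * as.matrix(X)[, 3])
  bg <- matrix(rnorm(10 * d), 10)
  x <- rnorm(d)
  vf <- function(S) value_function(f, x, S, bg)
  s1 <- sampled_shapley(vf, d, M = 50, seed = 9)
  s2 <- sampled_shapley(vf, d, M = 50, seed = 9)
  expect_identical(s1, s2)
  ex <- exact_shapley(vf, d)
  se <- attr(s1, "se")
  expect_true(all(abs(s1 - ex) <= 3 * pmax(se, 1e-9) + 1e-9))
  # additive model: every permutation gives the same marginal, so M=1 is exact
  fa <- lin_model(W)
  vfa <- function(S) value_function(fa, x, S, bg)
  sa <- sampled_shapley(vfa, d, M = 1, seed = 1)
  exa <- exact_shapley(vfa, d)
  expect_equal(as.numeric(sa), as.numeric(exa), tolerance = 1e-10)
})

test_that("the permutation estimator is unbiased across seeds", {
  set.seed(45)
  d <- 6
  f <- function(X) {
    X <- as.matrix(X)
    plogis(X[, 1] - X[, 2] + 0.8 * X[, 3] * X[, 4] + 0.2 * X[, 5])
  }
  bg <- matrix(rnorm(8 * d), 8)
  x <- rnorm(d)
  vf <- function(S) value_function(f, x, S, bg)
  ex <- exact_shapley(vf, d)
  ests <- t(vapply(1:50, function(s) as.numeric(sampled_shapley(vf, d, M = 8,
                                                                seed = s)),
                   numeric(d)))
  pooled_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests) - as.numeric(ex)) <=
                    3 * pmax(pooled_se, 1e-9)))
})

test_that("attribute_dataset: exact mode satisfies per-row efficiency; batched sampling matches the generic path", {
  set.seed(46)
  d <- 5
  W <- rnorm(d)
  f <- function(X) plogis(as.matrix(X) %*% W)
  rows <- matrix(rnorm(6 * d), 6)
  bg <- matrix(rnorm(12 * d), 12)
  res <- attribute_dataset(f, rows, bg, seed = 2)
  expect_identical(res$estimator, "exact")
  fx <- f(rows)
  for (r in 1:6) {
    expect_equal(sum(res$phi[r, ]) + res$base_value, fx[r], tolerance = 1e-6)
  }
  # force the batched permutation path and compare with sampled_shapley
  res_p <- attribute_dataset(f, rows[1, , drop = FALSE], bg, M = 40,
                             exact_limit = 2, seed = 3)
  expect_identical(res_p$estimator, "permutation")
  vf <- function(S) value_function(f, rows[1, ], S, bg)
  ref <- sampled_shapley(vf, d, M = 200, seed = 11)
  expect_true(all(abs(res_p$phi[1, ] - as.numeric(ref)) <=
                    3 * sqrt(res_p$se[1, ]^2 + attr(ref, "se")^2) + 1e-8))
  # sampled mode keeps telescoping efficiency per row
  expect_equal(sum(res_p$phi[1, ]) + res_p$base_value, unname(fx[1]),
               tolerance = 1e-8)
  # a constant column is a dummy feature
  rows2 <- rows; rows2[, 4] <- 0
  bg2 <- bg; bg2[, 4] <- 0
  res2 <- attribute_dataset(f, rows2, bg2, seed = 4)
  expect_equal(max(abs(res2$phi[, 4])), 0, tolerance = 1e-12)
})

test_that("global summary ranks by mean |phi| invariant to row order", {
  set.seed(47)
  phi <- cbind(a = rnorm(30, 0, 2), b = rnorm(30, 0, 0.5), c = rnorm(30, 0, 0.1))
  vals <- matrix(rnorm(90), 30)
  res <- structure(list(phi = phi, se = NULL, base_value = 0.5, values = vals,
                        columns = colnames(phi), estimator = "exact",
                        config = list()), class = "attribution_result")
  gs <- global_summary(res)
  expect_identical(gs$ranking$column[1], "a")
  perm <- sample(30)
  res2 <- res; res2$phi <- phi[perm, ]; res2$values <- vals[perm, ]
  expect_identical(global_summary(res2)$ranking$column, gs$ranking$column)
  expect_equal(nrow(gs$beeswarm), 90)
  res0 <- res; res0$phi[] <- 0
  expect_warning(g0 <- global_summary(res0), "zero")
  expect_equal(nrow(g0$ranking), 0)
})

test_that("subgroup attribution filters rows and reduces to the global summary", {
  set.seed(48)
  n <- 80
  phi <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  vals <- matrix(rnorm(2 * n), n)
  res <- structure(list(phi = phi, se = NULL, base_value = 0.4, values = vals,
                        columns = colnames(phi), estimator = "exact",
                        config = list()), class = "attribution_result")
  rec <- data.frame(Gender = rep(c("Female", "Male"), each = n / 2))
  ss <- subgroup_attribution(res, rec, "Gender=Female")
  expect_equal(ss$n, n / 2)
  # no-op filter equals global
  rec_all <- data.frame(Group = rep("All", n))
  ss_all <- subgroup_attribution(res, rec_all, "Group=All")
  expect_equal(ss_all$ranking, global_summary(res)$ranking)
  expect_error(subgroup_attribution(res, rec, "Gender=Other"), "empty subgroup")
  expect_error(subgroup_attribution(res, rec, "Nope=1"), "unknown factor")
  expect_warning(subgroup_attribution(res, rec, "Gender=Female", min_size = 60),
                 "only")
})
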
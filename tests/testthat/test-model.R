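test_that("initialization is seed-deterministic and guarded", {
  cfg <- glnet_config(input_dim = 10, embed_dim = 16, ssm_state_dim = 4, seed = 0)
  a <- init_model(cfg)
  b <- init_model(cfg)
  expect_identical(a$params, b$params)
  expect_error(glnet_config(input_dim = 10, embed_dim = 126), "divisible by 4")
  expect_error(glnet_config(input_dim = 10, conv_kernel = 4), "odd")
})

test_that("parameter count matches the layer-by-layer closed form", {
  d_in <- 10L; E <- 16L; N <- 4L; K <- 3L
  cfg <- glnet_config(d_in, E, N, K, seed = 1)
  m <- init_model(cfg)
  dims_in <- c(E, 2L * E, 4L * E, 2L * E)
  dims_out <- c(2L * E, 4L * E, 2L * E, E)
  per_block <- function(i, o) {
    (N + 1 + 1 + N + N + N + N + 1) +   # ssm: A, wd, bd, wB, bB, wC, bC, D
      (K + 1) +                         # conv
      (i * o + o) +                     # fc
      (2 * o)                           # bn gamma/beta
  }
  expected <- (d_in * E + E) +
    sum(mapply(per_block, dims_in, dims_out)) +
    (E * 2 + 2)
  expect_equal(sum(vapply(m$params, length, integer(1))), expected)
})

test_that("scan of all-zero input with zero skip is zero, and L=1 matches the closed form", {
  set.seed(2)
  p <- random_ssm_params(4)
  p0 <- p; p0$D <- 0
  expect_equal(ssm_scan(rep(0, 7), p0), rep(0, 7))
  # single step: y1 = C1 . (Delta1 B1 x1) + D x1
  x1 <- 0.7
  d1 <- log1p(exp(p$wd * x1 + p$bd))
  y1 <- sum((p$wC * x1 + p$bC) * (d1 * (p$wB * x1 + p$bB) * x1)) + p$D * x1
  expect_equal(ssm_scan(x1, p), y1, tolerance = 1e-12)
})

test_that("sequential scan equals the brute-force unrolled oracle", {
  set.seed(4)
  for (i in 1:25) {
    p <- random_ssm_params(sample(2:6, 1))
    L <- sample(2:32, 1)
    x <- rnorm(L)
    expect_equal(ssm_scan(x, p), ssm_unrolled_oracle(x, p), tolerance = 1e-5)
  }
})

test_that("scan states stay bounded over 10,000 steps with A < 0", {
  set.seed(5)
  p <- random_ssm_params(4)
  y <- ssm_scan(rnorm(10000), p)
  expect_true(all(is.finite(y)))
  expect_lt(max(abs(y)), 1e3)
})

test_that("scan rejects empty sequences and non-negative A", {
  p <- random_ssm_params(3)
  expect_error(ssm_scan(numeric(0), p), "empty")
  p$A[1] <- 0.5
  expect_error(ssm_scan(1:3, p), "negative")
})

test_that("block shape algebra: up doubles, down halves, chain returns to E", {
  cfg <- glnet_config(input_dim = 6, embed_dim = 16, ssm_state_dim = 3, seed = 7)
  m <- init_model(cfg)
  v <- rnorm(16)
  o1 <- glb_forward(v, m, 1)
  expect_length(o1, 32)
  o2 <- glb_forward(o1, m, 2)
  expect_length(o2, 64)
  o3 <- glb_forward(o2, m, 3)
  expect_length(o3, 32)
  o4 <- glb_forward(o3 + o1, m, 4)
  expect_length(o4, 16)
  expect_error(glb_forward(rnorm(5), m, 1), "contract error")
})

test_that("eval-mode forward is deterministic and batch-size invariant", {
  cfg <- glnet_config(input_dim = 9, embed_dim = 12, ssm_state_dim = 4, seed = 3)
  m <- init_model(cfg)
  X <- matrix(rnorm(7 * 9), 7)
  l1 <- glnet_forward(X, m)
  expect_identical(dim(l1), c(7L, 2L))
  expect_identical(l1, glnet_forward(X, m))
  # single-row forward equals the batched row
  for (i in c(1, 4, 7)) {
    expect_equal(as.numeric(glnet_forward(X[i, ], m)), as.numeric(l1[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("the residual path carries gradient: probing it changes the logits", {
  cfg <- glnet_config(input_dim = 5, embed_dim = 8, ssm_state_dim = 3, seed = 9)
  m <- init_model(cfg)
  x <- rnorm(5)
  X1 <- as.numeric(x %*% m$params[["embed.W"]] + m$params[["embed.b"]])
  g1 <- glb_forward(X1, m, 1)
  g2 <- glb_forward(g1, m, 2)
  g3 <- glb_forward(g2, m, 3)
  base <- glb_forward(g3 + g1, m, 4)
  eps <- 1e-4
  bumped <- glb_forward(g3 + g1 + eps, m, 4)   # finite-difference along the skip
  expect_gt(max(abs(bumped - base)), 0)
  # and removing the residual changes the output
  no_res <- glb_forward(g3, m, 4)
  expect_gt(max(abs(no_res - base)), 1e-8)
})

test_that("the model is sequence-order aware: permuting columns changes outputs", {
  cfg <- glnet_config(input_dim = 8, embed_dim = 8, ssm_state_dim = 3, seed = 1)
  m <- init_model(cfg)
  x <- rnorm(8)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_gt(max(abs(glnet_forward(x, m) - glnet_forward(x[perm], m))), 1e-8)
})

test_that("probabilities are a softmax of the logits", {
  cfg <- glnet_config(input_dim = 4, embed_dim = 8, ssm_state_dim = 2, seed = 0)
  m <- init_model(cfg)
  X <- matrix(rnorm(6 * 4), 6)
  p <- predict_proba(X, m)
  expect_true(all(p >= 0 & p <= 1))
  lg <- glnet_forward(X, m)
  expect_equal(p, exp(lg[, 2]) / (exp(lg[, 1]) + exp(lg[, 2])), tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- glnet_config(input_dim = 5, embed_dim = 8, ssm_state_dim = 3, seed = 6)
  m <- init_model(cfg)
  f <- tempfile(fileext = ".json")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, m$params)
  expect_equal(back$running, m$running)
  X <- matrix(rnorm(3 * 5), 3)
  expect_identical(glnet_forward(X, back), glnet_forward(X, m))
})
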
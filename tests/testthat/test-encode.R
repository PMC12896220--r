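test_that("one-hot encoding matches the closed-form layout", {
  sch <- factor_schema(list(
    list(name = "age", kind = "numeric", levels = character(0)),
    list(name = "city", kind = "categorical", levels = c("A", "B", "C"))))
  ds <- encode_dataset(data.frame(age = 21, city = "B"), sch, label = 1L)
  expect_identical(as.numeric(ds$x), c(21, 0, 1, 0))
  expect_identical(ds$columns, c("age", "city=A", "city=B", "city=C"))
})

test_that("encoded column count equals the schema closed form", {
  sch <- factor_schema(list(
    list(name = "n1", kind = "numeric", levels = character(0)),
    list(name = "n2", kind = "numeric", levels = character(0)),
    list(name = "b", kind = "binary", levels = c("No", "Yes")),
    list(name = "c4", kind = "categorical", levels = paste0("L", 1:4)),
    list(name = "c5", kind = "categorical", levels = paste0("M", 1:5))))
  expect_length(schema_columns(sch), 2 + 1 + 4 + 5)
  # property: random schemas
  set.seed(7)
  for (i in 1:10) {
    s <- random_schema()
    expected <- sum(vapply(s$factors, function(f) {
      if (f$kind == "categorical") length(f$levels) else 1L
    }, integer(1)))
    expect_length(schema_columns(s), expected)
    df <- random_records(s, 20)
    ds <- encode_dataset(df, s)
    expect_equal(ncol(ds$x), expected)
  }
})

test_that("categorical encoding is invertible via argmax and binary via round", {
  set.seed(3)
  for (i in 1:5) {
    s <- random_schema()
    df <- random_records(s, 30)
    ds <- encode_dataset(df, s)
    back <- decode_dataset(ds)
    for (f in s$factors) {
      if (f$kind %in% c("categorical", "binary")) {
        expect_identical(as.character(back[[f$name]]),
                         as.character(df[[f$name]]))
      } else {
        expect_equal(back[[f$name]], as.numeric(df[[f$name]]))
      }
    }
    # exactly one indicator per categorical factor per row
    j <- 1L
    for (f in s$factors) {
      w <- if (f$kind == "categorical") length(f$levels) else 1L
      if (f$kind == "categorical") {
        expect_true(all(rowSums(ds$x[, j:(j + w - 1L), drop = FALSE]) == 1))
      }
      j <- j + w
    }
  }
})

test_that("encoding errors name the offending factor", {
  sch <- factor_schema(list(
    list(name = "city", kind = "categorical", levels = c("A", "B"))))
  expect_error(encode_dataset(data.frame(city = "Z"), sch), "city")
})

test_that("split uses floor arithmetic on the training pool", {
  # 27,898 rows at 80:20 -> 22,318 pool / 5,580 test
  n <- 27898L
  y <- rep(c(0L, 1L), length.out = n)
  ds <- structure(list(x = matrix(0, n, 1), columns = "x", y = y,
                       standardized = FALSE), class = "encoded_dataset")
  sp <- split_dataset(ds, 0.2, 0.15, seed = 1)
  expect_equal(length(sp$train) + length(sp$validation), 22318L)
  expect_equal(length(sp$test), 5580L)
  expect_equal(length(sp$validation), floor(22318 * 0.15))
})

test_that("split is a seed-reproducible stratified partition", {
  set.seed(9)
  n <- 1500L
  y <- rbinom(n, 1, 0.6)
  ds <- structure(list(x = matrix(rnorm(n), n, 1), columns = "x", y = y,
                       standardized = FALSE), class = "encoded_dataset")
  a <- split_dataset(ds, 0.2, 0.15, seed = 4)
  b <- split_dataset(ds, 0.2, 0.15, seed = 4)
  expect_identical(a, b)
  all_idx <- sort(c(a$train, a$validation, a$test))
  expect_identical(all_idx, seq_len(n))
  expect_length(intersect(a$train, a$test), 0L)
  expect_length(intersect(a$validation, a$test), 0L)
  # prevalence within 2 points of parent in each partition
  prev <- mean(y)
  for (part in list(a$train, a$validation, a$test)) {
    expect_lt(abs(mean(y[part]) - prev), 0.02)
  }
  c_ <- split_dataset(ds, 0.2, 0.15, seed = 5)
  expect_false(identical(a$test, c_$test))
})

test_that("tiny balanced split forces one of each class into test", {
  ds <- structure(list(x = matrix(0, 10, 1), columns = "x",
                       y = rep(c(0L, 1L), 5), standardized = FALSE),
                  class = "encoded_dataset")
  sp <- split_dataset(ds, 0.2, 0.2, seed = 2)
  expect_equal(sum(ds$y[sp$test]), 1L)
  expect_length(sp$test, 2L)
})

test_that("standardizer is fit on train only and round-trips", {
  set.seed(11)
  x <- matrix(rnorm(200 * 3, mean = 5, sd = 2), 200)
  x[, 3] <- 7                                  # constant column
  ds <- structure(list(x = x, columns = paste0("c", 1:3), y = rbinom(200, 1, .5),
                       standardized = FALSE), class = "encoded_dataset")
  tr <- 1:120
  std <- fit_standardizer(ds, tr)
  expect_equal(unname(std$mean[3]), 7)
  expect_equal(unname(std$sd[3]), 1e-8)        # floored
  expect_equal(unname(std$mean[1]), mean(x[tr, 1]))
  expect_equal(unname(std$sd[2]), sd(x[tr, 2]))
  z <- apply_standardizer(ds, std)
  expect_true(z$standardized)
  expect_lt(max(abs(colMeans(z$x[tr, 1:2]))), 1e-6)
  expect_equal(apply(z$x[tr, 1:2], 2, sd), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-6)
  back <- apply_standardizer(z, std, invert = TRUE)
  expect_lt(max(abs(back$x - x)), 1e-9)
  # leakage: perturbing non-train rows leaves parameters bit-identical
  ds2 <- ds
  ds2$x[150:200, ] <- ds2$x[150:200, ] + 100
  expect_identical(fit_standardizer(ds2, tr), std)
})

test_that("split and standardizer JSON sidecars round-trip", {
  ds <- structure(list(x = matrix(rnorm(50), 50, 1), columns = "x",
                       y = rep(c(0L, 1L), 25), standardized = FALSE),
                  class = "encoded_dataset")
  sp <- split_dataset(ds, 0.2, 0.2, seed = 3)
  f <- tempfile(fileext = ".json")
  split_to_json(sp, f)
  expect_identical(split_from_json(f), sp)
  std <- fit_standardizer(ds, sp$train)
  f2 <- tempfile(fileext = ".json")
  standardizer_to_json(std, f2)
  back <- standardizer_from_json(f2)
  expect_equal(back$mean, std$mean)
  expect_equal(back$sd, std$sd)
})
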
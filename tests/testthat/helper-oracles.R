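# Independent brute-force oracle for the selective scan: the unrolled sum
#   y_t = sum_{k<=t} C_t (prod_{j=k+1..t} Abar_j) Bbar_k x_k + D x_t
# computed directly, with no shared code with the sequential recurrence.
ssm_unrolled_oracle <- function(x, p) {
  L <- length(x)
  N <- length(p$A)
  y <- numeric(L)
  softplus <- function(z) log1p(exp(z))
  for (t in seq_len(L)) {
    acc <- rep(0, N)
    for (k in seq_len(t)) {
      dk <- softplus(p$wd * x[k] + p$bd)
      term <- dk * (p$wB * x[k] + p$bB) * x[k]
      if (t > k) {
        for (j in (k + 1):t) {
          dj <- softplus(p$wd * x[j] + p$bd)
          term <- term * exp(dj * p$A)
        }
      }
      acc <- acc + term
    }
    Ct <- p$wC * x[t] + p$bC
    y[t] <- sum(Ct * acc) + p$D * x[t]
  }
  y
}

random_ssm_params <- function(N = 4L) {
  list(A = -runif(N, 0.5, N), wd = rnorm(1, 0, 0.5), bd = rnorm(1, -2, 1),
       wB = rnorm(N), bB = rnorm(N), wC = rnorm(N), bC = rnorm(N),
       D = rnorm(1))
}

# Small random schema generator for encoding property tests.
random_schema <- function(max_factors = 6L) {
  n_f <- sample(2:max_factors, 1)
  kinds <- sample(c("numeric", "ordinal", "categorical", "binary"), n_f,
                  replace = TRUE)
  factor_schema(lapply(seq_len(n_f), function(i) {
    k <- kinds[i]
    lv <- switch(k,
                 categorical = paste0("L", seq_len(sample(2:5, 1))),
                 binary = c("No", "Yes"),
                 character(0))
    list(name = paste0("F", i), kind = k, levels = lv)
  }))
}

random_records <- function(schema, n) {
  cols <- lapply(schema$factors, function(f) {
    switch(f$kind,
           numeric = round(rnorm(n), 4),
           ordinal = sample(1:5, n, replace = TRUE),
           sample(f$levels, n, replace = TRUE))
  })
  names(cols) <- vapply(schema$factors, function(f) f$name, character(1))
  as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

write_records_csv <- function(df, label = NULL, path = tempfile(fileext = ".csv")) {
  if (!is.null(label)) df$Depression <- label
  write.csv(df, path, row.names = FALSE)
  path
}

# Tiny standardized fixture dataset + split used by several training tests.
tiny_training_fixture <- function(n = 240, p_sep = TRUE, seed = 5) {
  set.seed(seed)
  x <- matrix(rnorm(n * 8), n)
  y <- if (p_sep) as.integer(x[, 1] + 0.8 * x[, 2] > 0) else rbinom(n, 1, 0.5)
  ds <- structure(list(x = x, columns = paste0("x", 1:8), y = y,
                       schema = NULL, standardized = TRUE),
                  class = "encoded_dataset")
  sp <- structure(list(train = 1:(n * 0.7),
                       validation = (n * 0.7 + 1):(n * 0.85),
                       test = (n * 0.85 + 1):n, seed = seed),
                  class = "split_result")
  list(ds = ds, sp = sp)
}
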
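#' Encode raw records into the numeric design matrix
#'
#' Numeric and ordinal factors are copied as single columns; binary factors
#' map to 0/1 (second schema level -> 1); every categorical factor is split
#' into one indicator column per level, with no reference level dropped, so
#' that each level can later receive its own attribution. Exactly one
#' indicator per categorical factor is 1 in every row. Column order is a
#' pure function of the schema.
#'
#' @param records a `student_records` object from [load_records()], or a
#'   raw data.frame (then `label` must be supplied).
#' @param schema the [factor_schema()] the records conform to.
#' @param label optional integer 0/1 vector when `records` is a data.frame.
#' @return An object of class `encoded_dataset`: `x` (n x p matrix),
#'   `columns`, `y` (0/1 integer or NULL), `schema`, `standardized` flag.
#' @export
encode_dataset <- function(records, schema, label = NULL) {
  if (inherits(records, "student_records")) {
    df <- records$data
    label <- records$label
  } else {
    df <- as.data.frame(records)
  }
  want <- schema_names(schema)
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    stop("encoding error: records lack factor(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  cols <- schema_columns(schema)
  x <- matrix(0, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  j <- 1L
  for (f in schema$factors) {
    v <- df[[f$name]]
    if (f$kind %in% c("numeric", "ordinal")) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) {
        stop("encoding error: non-numeric value in factor '", f$name,
             "' at row ", which(is.na(vn))[1])
      }
      x[, j] <- vn
      j <- j + 1L
    } else if (f$kind == "binary") {
      m <- match(as.character(v), f$levels)
      if (anyNA(m)) {
        stop("encoding error: value not in levels of '", f$name,
             "' at row ", which(is.na(m))[1])
      }
      x[, j] <- m - 1L
      j <- j + 1L
    } else {
      m <- match(as.character(v), f$levels)
      if (anyNA(m)) {
        stop("encoding error: value not in levels of '", f$name,
             "' at row ", which(is.na(m))[1])
      }
      x[cbind(seq_len(n), j + m - 1L)] <- 1
      j <- j + length(f$levels)
    }
  }
  structure(list(x = x, columns = cols,
                 y = if (!is.null(label)) as.integer(label) else NULL,
                 schema = schema, schema_id = schema_id(schema),
                 standardized = FALSE),
            class = "encoded_dataset")
}

#' Recover raw categorical levels from an encoded matrix
#'
#' Inverse of the one-hot expansion: for each categorical factor the level
#' with the largest indicator is returned. Used for round-trip checks and
#' for subgroup filtering on raw values.
#'
#' @param dataset an `encoded_dataset`.
#' @return data.frame of raw factor values in schema order.
#' @export
decode_dataset <- function(dataset) {
  schema <- dataset$schema
  out <- list()
  j <- 1L
  for (f in schema$factors) {
    if (f$kind %in% c("numeric", "ordinal")) {
      out[[f$name]] <- dataset$x[, j]
      j <- j + 1L
    } else if (f$kind == "binary") {
      out[[f$name]] <- f$levels[round(dataset$x[, j]) + 1L]
      j <- j + 1L
    } else {
      block <- dataset$x[, j:(j + length(f$levels) - 1L), drop = FALSE]
      out[[f$name]] <- f$levels[max.col(block, ties.method = "first")]
      j <- j + length(f$levels)
    }
  }
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("<encoded_dataset> ", nrow(x$x), " x ", ncol(x$x),
      if (isTRUE(x$standardized)) " (standardized)" else " (raw scale)",
      if (!is.null(x$y)) paste0(" | prevalence ", round(mean(x$y), 3)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Stratified train/validation/test partition
#'
#' The training pool receives `floor(n * (1 - test_fraction))` rows and the
#' test set the remainder (so an 80:20 split of 27,898 rows gives a
#' 22,318-row pool and 5,580 test rows); the validation set then takes
#' `floor(pool * val_fraction_of_train)` rows out of the pool. Assignment
#' is stratified by label with largest-remainder apportionment across
#' strata, and is deterministic given `seed`. A stratum with fewer than two
#' members is assigned wholly to train with a warning.
#'
#' @param dataset an `encoded_dataset` with labels.
#' @param test_fraction fraction held out for testing (default 0.2).
#' @param val_fraction_of_train fraction of the training pool used for
#'   validation (default 0.15).
#' @param seed integer seed.
#' @return An object of class `split_result` with integer index vectors
#'   `train`, `validation`, `test` and the `seed`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.2,
                          val_fraction_of_train = 0.15, seed = 0L) {
  y <- dataset$y
  if (is.null(y)) stop("split_dataset: dataset has no labels")
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction_of_train > 0, val_fraction_of_train < 1)
  n <- length(y)
  pool_n <- floor(n * (1 - test_fraction))
  test_n <- n - pool_n
  val_n <- floor(pool_n * val_fraction_of_train)

  strata <- split(seq_len(n), y)
  small <- vapply(strata, function(ix) length(ix) < 2L, logical(1))
  forced_train <- unlist(strata[small], use.names = FALSE)
  if (length(forced_train)) {
    warning("split_dataset: stratum with < 2 members assigned wholly to train")
    strata <- strata[!small]
  }

  # largest-remainder apportionment of the test quota across strata
  apportion <- function(sizes, total) {
    raw <- sizes * total / sum(sizes)
    base <- floor(raw)
    rem <- total - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    as.integer(base)
  }

  sizes <- vapply(strata, length, integer(1))
  test_q <- apportion(sizes, test_n)
  test_idx <- integer(0); pool_idx <- forced_train
  with_seed(derive_seed(seed, "split"), {
    for (k in seq_along(strata)) {
      ix <- sample(strata[[k]])
      test_idx <- c(test_idx, ix[seq_len(test_q[k])])
      pool_idx <- c(pool_idx, ix[setdiff(seq_along(ix), seq_len(test_q[k]))])
    }
    pool_strata <- split(pool_idx, y[pool_idx])
    val_q <- apportion(vapply(pool_strata, length, integer(1)), val_n)
    val_idx <- integer(0); train_idx <- integer(0)
    for (k in seq_along(pool_strata)) {
      ix <- sample(pool_strata[[k]])
      val_idx <- c(val_idx, ix[seq_len(val_q[k])])
      train_idx <- c(train_idx, ix[setdiff(seq_along(ix), seq_len(val_q[k]))])
    }
  })
  structure(list(train = sort(train_idx), validation = sort(val_idx),
                 test = sort(test_idx), seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> train", length(x$train), "| validation",
      length(x$validation), "| test", length(x$test), "| seed", x$seed, "\n")
  invisible(x)
}

#' Save / load a split as a JSON sidecar
#' @param split a `split_result`; @param path file path.
#' @return the path (save) or a `split_result` (load).
#' @export
split_to_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname split_to_json
#' @export
split_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.integer(raw$train),
                 validation = as.integer(raw$validation),
                 test = as.integer(raw$test),
                 seed = as.integer(raw$seed[1])),
            class = "split_result")
}

#' Fit column-wise standardization on the training partition only
#'
#' Means and standard deviations are computed over training rows alone so
#' no information from validation or test rows can leak into the
#' transformation. Standard deviations of (near-)constant columns are
#' floored at `sd_floor`.
#'
#' @param dataset an `encoded_dataset` (raw scale).
#' @param train_idx integer indices of the training rows.
#' @param sd_floor lower bound applied to column standard deviations.
#' @return An object of class `standardizer` with `mean`, `sd`, `columns`,
#'   `fitted_on`.
#' @export
fit_standardizer <- function(dataset, train_idx, sd_floor = 1e-8) {
  stopifnot(length(train_idx) > 0L)
  xt <- dataset$x[train_idx, , drop = FALSE]
  mu <- setNames(colMeans(xt), dataset$columns)
  s <- setNames(apply(xt, 2L, sd), dataset$columns)
  s[!is.finite(s) | s < sd_floor] <- sd_floor
  structure(list(mean = mu, sd = s, columns = dataset$columns,
                 fitted_on = "train"),
            class = "standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param dataset an `encoded_dataset` whose columns match the params.
#' @param params a `standardizer` from [fit_standardizer()].
#' @param invert if `TRUE`, undo the transformation.
#' @return The transformed `encoded_dataset` with its `standardized` flag set.
#' @export
apply_standardizer <- function(dataset, params, invert = FALSE) {
  if (!identical(dataset$columns, params$columns)) {
    stop("contract error: column sets of dataset and standardizer differ")
  }
  if (invert) {
    dataset$x <- sweep(sweep(dataset$x, 2L, params$sd, "*"), 2L, params$mean, "+")
    dataset$standardized <- FALSE
  } else {
    dataset$x <- sweep(sweep(dataset$x, 2L, params$mean, "-"), 2L, params$sd, "/")
    dataset$standardized <- TRUE
  }
  dataset
}

#' @rdname fit_standardizer
#' @param path file path for the JSON sidecar.
#' @export
standardizer_to_json <- function(params, path) {
  jsonlite::write_json(list(mean = unname(params$mean), sd = unname(params$sd),
                            columns = params$columns, fitted_on = params$fitted_on),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname fit_standardizer
#' @export
standardizer_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = setNames(raw$mean, raw$columns),
                 sd = setNames(raw$sd, raw$columns),
                 columns = raw$columns, fitted_on = raw$fitted_on[1]),
            class = "standardizer")
}
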
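#' Interventional coalition value function
#'
#' `f(S)` is the model's expected class-1 probability when the columns in
#' `S` are fixed to the instance's values and all other columns are
#' replaced by background-sample values, averaged over the background
#' rows. `f(full set)` is the model probability at the instance;
#' `f(empty set)` is the mean probability over the background.
#'
#' @param model a `glnet_model`, or any function mapping a numeric matrix
#'   of rows to a numeric vector of predictions.
#' @param x numeric vector: the instance being explained.
#' @param S integer vector of column indices held at the instance's values
#'   (possibly empty).
#' @param background numeric matrix of reference rows (same width as `x`).
#' @return The scalar coalition value.
#' @export
value_function <- function(model, x, S, background) {
  predict_fn <- model_predict_fn(model)
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("value_function: empty background")
  hybrid <- background
  if (length(S) > 0L) {
    hybrid[, S] <- matrix(x[S], nrow(background), length(S), byrow = TRUE)
  }
  mean(predict_fn(hybrid))
}

model_predict_fn <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "glnet_fit")) model <- model$model
  if (inherits(model, "glnet_model")) {
    return(function(X) predict_proba(X, model))
  }
  stop("value_function: model must be a glnet_model or a prediction function")
}

#' Exact Shapley values by subset enumeration
#'
#' Computes `phi_i = sum over S not containing i of
#' |S|! (d-|S|-1)! / d! * (f(S u {i}) - f(S))` by enumerating all `2^d`
#' coalitions. Intended as the small-d oracle; beyond `limit` columns use
#' [sampled_shapley()].
#'
#' @param value_fn function taking an integer vector of column indices and
#'   returning the coalition value (see [value_function()]).
#' @param d number of columns.
#' @param limit refuse enumeration beyond this many columns (default 15).
#' @return Numeric vector `phi` of length `d` with attribute
#'   `base_value = f(empty set)`.
#' @export
exact_shapley <- function(value_fn, d, limit = 15L) {
  if (d > limit) {
    stop("exact_shapley: d = ", d, " exceeds the enumeration limit (", limit,
         "); use sampled_shapley()")
  }
  n_mask <- bitwShiftL(1L, d)
  bits <- bitwShiftL(1L, 0:(d - 1L))
  vs <- numeric(n_mask)
  size <- integer(n_mask)
  for (m in 0:(n_mask - 1L)) {
    S <- which(bitwAnd(m, bits) > 0L)
    vs[m + 1L] <- value_fn(S)
    size[m + 1L] <- length(S)
  }
  # weight by coalition size: |S|! (d-|S|-1)! / d!
  wt <- exp(lfactorial(0:(d - 1L)) + lfactorial(d - 1L - (0:(d - 1L))) -
              lfactorial(d))
  phi <- numeric(d)
  for (i in seq_len(d)) {
    bi <- bits[i]
    without <- which(bitwAnd(0:(n_mask - 1L), bi) == 0L)   # 1-based masks+1
    masks0 <- without - 1L
    phi[i] <- sum(wt[size[without] + 1L] *
                    (vs[bitwOr(masks0, bi) + 1L] - vs[without]))
  }
  attr(phi, "base_value") <- vs[1L]
  phi
}

#' Permutation-sampling Shapley estimate
#'
#' Averages marginal contributions `f(pred u {i}) - f(pred)` over `M`
#' uniformly random feature orderings; an unbiased estimator of the exact
#' Shapley value, with Monte-Carlo standard errors.
#'
#' @param value_fn coalition value function as in [exact_shapley()].
#' @param d number of columns.
#' @param M number of permutations (default 200).
#' @param seed integer seed.
#' @return Numeric `phi` of length `d` with attributes `se` (Monte-Carlo
#'   standard errors), `base_value`, and `M`.
#' @export
sampled_shapley <- function(value_fn, d, M = 200L, seed = 0L) {
  stopifnot(M >= 1L)
  contrib <- matrix(NA_real_, M, d)
  v_empty <- value_fn(integer(0))
  with_seed(derive_seed(seed, "shapley"), {
    for (m in seq_len(M)) {
      perm <- sample.int(d)
      v_prev <- v_empty
      for (j in seq_len(d)) {
        v_cur <- value_fn(perm[seq_len(j)])
        contrib[m, perm[j]] <- v_cur - v_prev
        v_prev <- v_cur
      }
    }
  })
  phi <- colMeans(contrib)
  se <- if (M > 1L) apply(contrib, 2L, sd) / sqrt(M) else rep(NA_real_, d)
  attr(phi, "se") <- se
  attr(phi, "base_value") <- v_empty
  attr(phi, "M") <- M
  phi
}

#' Shapley attributions for a set of rows
#'
#' Per-row, per-encoded-column Shapley values of the class-1 probability,
#' against a background reference set. Uses exact enumeration when the
#' column count is at most `exact_limit`, and batched permutation sampling
#' otherwise. Positive values push the prediction toward the depressed
#' class.
#'
#' @param model a `glnet_model`, `glnet_fit`, or prediction function.
#' @param rows numeric matrix of (standardized) rows to explain.
#' @param background numeric matrix of (standardized) reference rows,
#'   conventionally sampled from the training partition.
#' @param M permutations per row in sampled mode (default 200).
#' @param exact_limit maximum column count for exact enumeration.
#' @param seed integer seed.
#' @param background_origin where the background rows came from; passing
#'   `"test"` triggers a leakage warning.
#' @param columns optional encoded-column names.
#' @return An object of class `attribution_result`: `phi` (n x d), `se`
#'   (n x d or NULL), `base_value`, `values` (the explained rows),
#'   `columns`, `estimator`, `config`.
#' @export
attribute_dataset <- function(model, rows, background, M = 200L,
                              exact_limit = 15L, seed = 0L,
                              background_origin = c("train", "other", "test"),
                              columns = NULL) {
  background_origin <- match.arg(background_origin)
  if (background_origin == "test") {
    warning("attribute_dataset: background drawn from test rows leaks ",
            "evaluation data into the explanation reference")
  }
  rows <- as.matrix(rows)
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("attribute_dataset: empty background")
  d <- ncol(rows)
  predict_fn <- model_predict_fn(model)
  columns <- columns %||% colnames(rows) %||% paste0("x", seq_len(d))
  n <- nrow(rows)
  phi <- matrix(0, n, d, dimnames = list(NULL, columns))
  base_value <- mean(predict_fn(background))

  if (d <= exact_limit) {
    estimator <- "exact"
    se <- NULL
    for (r in seq_len(n)) {
      x <- rows[r, ]
      vf <- function(S) value_function(predict_fn, x, S, background)
      phi[r, ] <- as.numeric(exact_shapley(vf, d, limit = exact_limit))
    }
  } else {
    estimator <- "permutation"
    se <- matrix(0, n, d, dimnames = list(NULL, columns))
    B <- nrow(background)
    v_full_all <- predict_fn(rows)
    # chunk whole permutations so each model call sees a large batch
    perms_per_chunk <- max(1L, as.integer(floor(8192 / ((d - 1L) * B))))
    for (r in seq_len(n)) {
      contrib <- matrix(NA_real_, M, d)
      x <- rows[r, ]
      with_seed(derive_seed(seed, paste0("attr", r)), {
        perms <- replicate(M, sample.int(d))          # d x M
      })
      for (c0 in seq(1L, M, by = perms_per_chunk)) {
        mm <- c0:min(c0 + perms_per_chunk - 1L, M)
        big <- matrix(0, length(mm) * (d - 1L) * B, d)
        ptr <- 0L
        for (m in mm) {
          hybrid <- background
          for (j in seq_len(d - 1L)) {
            hybrid[, perms[j, m]] <- x[perms[j, m]]
            big[ptr + seq_len(B), ] <- hybrid
            ptr <- ptr + B
          }
        }
        pv <- predict_fn(big)
        vmat <- matrix(colMeans(matrix(pv, B)), nrow = d - 1L)  # (d-1) x |mm|
        for (kk in seq_along(mm)) {
          m <- mm[kk]
          v_seq <- c(base_value, vmat[, kk], v_full_all[r])
          contrib[m, perms[, m]] <- diff(v_seq)
        }
      }
      phi[r, ] <- colMeans(contrib)
      se[r, ] <- apply(contrib, 2L, sd) / sqrt(M)
    }
  }
  structure(list(phi = phi, se = se, base_value = base_value,
                 values = rows, columns = columns, estimator = estimator,
                 config = list(M = as.integer(M), B = nrow(background),
                               seed = as.integer(seed))),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result>", nrow(x$phi), "rows x", ncol(x$phi),
      "columns | estimator:", x$estimator,
      "| base value:", signif(x$base_value, 4), "\n")
  invisible(x)
}

#' Global factor-importance summary
#'
#' Ranks encoded columns by mean absolute Shapley value and exports the
#' (sample, column, phi, value) triples behind a beeswarm-style summary
#' plot. Positive phi pushes the prediction toward the depressed class.
#'
#' @param result an [attribute_dataset()] result.
#' @param schema optional [factor_schema()] used to annotate each encoded
#'   column with its parent factor.
#' @return An object of class `attribution_summary`: `ranking` (data.frame
#'   with `column`, `factor`, `mean_abs_phi`, `mean_phi`, `phi_value_cor`)
#'   and `beeswarm` (long data.frame).
#' @export
global_summary <- function(result, schema = NULL) {
  phi <- result$phi
  if (all(phi == 0)) {
    warning("global_summary: all attributions are zero")
    ranking <- data.frame(column = character(0), factor = character(0),
                          mean_abs_phi = numeric(0), mean_phi = numeric(0),
                          phi_value_cor = numeric(0),
                          phi_value_slope = numeric(0))
    return(structure(list(ranking = ranking,
                          beeswarm = data.frame(sample = integer(0),
                                                column = character(0),
                                                phi = numeric(0),
                                                value = numeric(0))),
                     class = "attribution_summary"))
  }
  parent <- if (!is.null(schema)) {
    schema_column_factors(schema)[match(result$columns, schema_columns(schema))]
  } else result$columns
  assoc <- vapply(seq_len(ncol(phi)), function(j) {
    v <- result$values[, j]
    if (sd(v) == 0 || sd(phi[, j]) == 0) return(NA_real_)
    cor(phi[, j], v)
  }, numeric(1))
  # regression slope of phi on the column value: a signed association that,
  # unlike the correlation, carries the magnitude of the dependence
  slope <- vapply(seq_len(ncol(phi)), function(j) {
    v <- result$values[, j]
    if (sd(v) == 0) return(NA_real_)
    cov(phi[, j], v) / var(v)
  }, numeric(1))
  ranking <- data.frame(column = result$columns, factor = parent,
                        mean_abs_phi = colMeans(abs(phi)),
                        mean_phi = colMeans(phi),
                        phi_value_cor = assoc,
                        phi_value_slope = slope,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_phi), ]
  rownames(ranking) <- NULL
  n <- nrow(phi)
  beeswarm <- data.frame(sample = rep(seq_len(n), ncol(phi)),
                         column = rep(result$columns, each = n),
                         phi = as.numeric(phi),
                         value = as.numeric(result$values),
                         stringsAsFactors = FALSE)
  structure(list(ranking = ranking, beeswarm = beeswarm),
            class = "attribution_summary")
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat("<attribution_summary> top factors by mean |phi|:\n")
  print(head(x$ranking, 10L))
  invisible(x)
}

parse_filter <- function(filter) {
  if (is.character(filter) && length(filter) == 1L && grepl("=", filter)) {
    kv <- strsplit(filter, "=", fixed = TRUE)[[1]]
    return(setNames(paste(kv[-1], collapse = "="), kv[1]))
  }
  if (!is.null(names(filter))) return(unlist(filter))
  stop("subgroup filter must be 'Factor=value' or a named value")
}

#' Subgroup attribution summary
#'
#' Restricts an attribution result to the rows matching a raw-factor
#' filter (e.g. `"Gender=Female"`) and summarizes per-column importance and
#' the signed association between each column's value and its Shapley
#' value within the subgroup — the quantity behind statements like "the
#' higher the CGPA, the higher the predicted risk" for that subgroup.
#'
#' @param result an [attribute_dataset()] result.
#' @param records data.frame of raw factor values aligned row-for-row with
#'   the attributed rows (e.g. from [decode_dataset()]).
#' @param filter `"Factor=value"` string or named vector.
#' @param schema optional schema for parent-factor annotation.
#' @param min_size warn when the subgroup is smaller than this (default 30).
#' @return An object of class `subgroup_summary`: `filter`, `n`, `ranking`
#'   as in [global_summary()].
#' @export
subgroup_attribution <- function(result, records, filter, schema = NULL,
                                 min_size = 30L) {
  flt <- parse_filter(filter)
  fac <- names(flt)
  if (!fac %in% names(records)) {
    stop("subgroup_attribution: unknown factor '", fac, "'; valid names: ",
         paste(names(records), collapse = ", "))
  }
  stopifnot(nrow(records) == nrow(result$phi))
  keep <- as.character(records[[fac]]) == flt[[1]]
  if (!any(keep)) stop("subgroup_attribution: empty subgroup for ", fac,
                       "=", flt[[1]])
  if (sum(keep) < min_size) {
    warning("subgroup_attribution: subgroup has only ", sum(keep),
            " rows (< ", min_size, ")")
  }
  sub <- result
  sub$phi <- result$phi[keep, , drop = FALSE]
  sub$se <- if (!is.null(result$se)) result$se[keep, , drop = FALSE] else NULL
  sub$values <- result$values[keep, , drop = FALSE]
  gs <- suppressWarnings(global_summary(sub, schema))
  structure(list(filter = paste0(fac, "=", flt[[1]]), n = sum(keep),
                 ranking = gs$ranking, beeswarm = gs$beeswarm),
            class = "subgroup_summary")
}

#' @export
print.subgroup_summary <- function(x, ...) {
  cat("<subgroup_summary>", x$filter, "| n =", x$n, "\n")
  print(head(x$ranking, 10L))
  invisible(x)
}

#' Export an attribution result to CSV + JSON metadata
#'
#' @param result an `attribution_result`.
#' @param csv_path wide CSV of per-row attributions.
#' @param json_path JSON metadata (base value, estimator, config).
#' @return `csv_path`, invisibly.
#' @export
attribution_to_files <- function(result, csv_path, json_path = NULL) {
  df <- as.data.frame(result$phi)
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(base_value = result$base_value,
                              estimator = result$estimator,
                              config = result$config,
                              columns = result$columns),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
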
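#' Declare a factor schema for raw survey records
#'
#' A factor schema is an ordered list of raw factors, each with a kind
#' (`numeric`, `ordinal`, `categorical`, `binary`) and, for categorical and
#' binary kinds, an ordered level vocabulary. The schema fully determines
#' the encoded design-matrix layout: ordering of factors and of levels is
#' part of the schema and is serialized with it.
#'
#' @param factors a list of factor descriptors, each a list with elements
#'   `name` (character), `kind` (one of `"numeric"`, `"ordinal"`,
#'   `"categorical"`, `"binary"`), and `levels` (character vector; required
#'   for categorical/binary, must be empty otherwise).
#' @return An object of class `factor_schema`.
#' @export
factor_schema <- function(factors) {
  stopifnot(is.list(factors), length(factors) > 0L)
  kinds <- c("numeric", "ordinal", "categorical", "binary")
  nm <- vapply(factors, function(f) f$name, character(1))
  if (anyDuplicated(nm)) stop("schema error: duplicate factor names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  factors <- lapply(factors, function(f) {
    if (!f$kind %in% kinds) {
      stop("schema error: unknown kind '", f$kind, "' for factor '", f$name, "'")
    }
    f$levels <- as.character(f$levels %||% character(0))
    if (f$kind == "categorical" && length(unique(f$levels)) < 2L) {
      stop("schema error: categorical factor '", f$name, "' needs >= 2 levels")
    }
    if (f$kind == "binary" && length(f$levels) != 2L) {
      stop("schema error: binary factor '", f$name, "' needs exactly 2 levels")
    }
    if (f$kind %in% c("numeric", "ordinal") && length(f$levels) > 0L) {
      stop("schema error: ", f$kind, " factor '", f$name, "' must not have levels")
    }
    f[c("name", "kind", "levels")]
  })
  structure(list(factors = factors), class = "factor_schema")
}

schema_names <- function(schema) {
  vapply(schema$factors, function(f) f$name, character(1))
}

#' Encoded-column layout implied by a schema
#'
#' Categorical factors expand to one indicator column per level (no
#' reference level is dropped, so per-level attributions are possible);
#' numeric, ordinal and binary factors occupy a single column. Indicator
#' columns are named `"factor=level"`.
#'
#' @param schema a [factor_schema()].
#' @return Character vector of encoded column names, in schema order.
#' @export
schema_columns <- function(schema) {
  unlist(lapply(schema$factors, function(f) {
    if (f$kind == "categorical") paste0(f$name, "=", f$levels) else f$name
  }), use.names = FALSE)
}

# Map each encoded column back to its parent raw factor.
schema_column_factors <- function(schema) {
  unlist(lapply(schema$factors, function(f) {
    rep(f$name, if (f$kind == "categorical") length(f$levels) else 1L)
  }), use.names = FALSE)
}

# A short content hash so downstream artifacts can record which schema
# produced them.
schema_id <- function(schema) {
  txt <- paste(vapply(schema$factors, function(f) {
    paste(f$name, f$kind, paste(f$levels, collapse = "|"), sep = ";")
  }, character(1)), collapse = "\n")
  substr(sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997 + 1)) %% 4294967296), 1, 8)
}

#' @export
print.factor_schema <- function(x, ...) {
  cat("<factor_schema> ", length(x$factors), " factors, ",
      length(schema_columns(x)), " encoded columns\n", sep = "")
  for (f in x$factors) {
    cat("  ", format(f$name, width = 28), f$kind,
        if (length(f$levels)) paste0(" [", paste(f$levels, collapse = ", "), "]") else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize / restore a schema as JSON
#'
#' @param schema a [factor_schema()].
#' @param path file path.
#' @return `schema_to_json` returns `path` invisibly; `schema_from_json`
#'   returns a `factor_schema`.
#' @export
schema_to_json <- function(schema, path) {
  jsonlite::write_json(lapply(schema$factors, function(f) {
    list(name = f$name, kind = f$kind, levels = as.list(f$levels))
  }), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname schema_to_json
#' @export
schema_from_json <- function(path) {
  raw <- jsonlite::read_json(path)
  factor_schema(lapply(raw, function(f) {
    list(name = f$name, kind = f$kind, levels = unlist(f$levels))
  }))
}

#' Infer a factor schema from a CSV file
#'
#' Numeric columns become `numeric` factors, text columns become
#' `categorical` with observed levels sorted lexicographically (C locale).
#' Overrides win on conflict and are the way to mark survey scales as
#' `ordinal` or two-level text columns as `binary`.
#'
#' @param path CSV file with a header row.
#' @param overrides optional named list: `name -> kind` (character) or
#'   `name -> list(kind=, levels=)` for full control.
#' @param label_col name of the label column to exclude from the schema
#'   (default `"Depression"`); pass `NULL` if the file has no label.
#' @param max_levels guard against ID-like columns: a text column with more
#'   distinct values than this and no override is a schema error.
#' @return A [factor_schema()].
#' @export
infer_schema <- function(path, overrides = list(), label_col = "Depression",
                         max_levels = 100L) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("input error: empty file: ", path)
  cols <- setdiff(names(df), label_col)
  factors <- lapply(cols, function(cn) {
    ov <- overrides[[cn]]
    if (is.list(ov) && !is.null(ov$kind) && !is.null(ov$levels)) {
      return(list(name = cn, kind = ov$kind, levels = ov$levels))
    }
    kind_ov <- if (is.character(ov)) ov else if (is.list(ov)) ov$kind else NULL
    v <- df[[cn]]
    if (is.numeric(v)) {
      kind <- kind_ov %||% "numeric"
      list(name = cn, kind = kind, levels = character(0))
    } else {
      lv <- sort(unique(as.character(v[!is.na(v) & nzchar(v)])), method = "radix")
      kind <- kind_ov %||% "categorical"
      if (kind %in% c("numeric", "ordinal")) {
        return(list(name = cn, kind = kind, levels = character(0)))
      }
      if (length(lv) > max_levels) {
        stop("schema error: column '", cn, "' has ", length(lv),
             " distinct values (> max_levels = ", max_levels,
             "); looks like an identifier — supply an override to keep it")
      }
      list(name = cn, kind = kind, levels = lv)
    }
  })
  factor_schema(factors)
}

#' Load raw student records from CSV, dropping incomplete rows
#'
#' Rows with any missing or unparseable field (including the label) are
#' dropped listwise; no imputation is attempted. The number of dropped rows
#' is reported in the return value and via a message.
#'
#' @param path CSV file (RFC-4180, UTF-8, header row).
#' @param schema a [factor_schema()] describing the expected factors.
#' @param label_col label column name; values must code depressed as 1 and
#'   non-depressed as 0 (or "Yes"/"No").
#' @return A list of class `student_records`: `data` (data.frame of raw
#'   factor values, schema column order), `label` (integer 0/1),
#'   `n_dropped` (rows removed).
#' @export
load_records <- function(path, schema, label_col = "Depression") {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  if (nrow(df) == 0L) stop("input error: empty file: ", path)
  want <- schema_names(schema)
  missing_cols <- setdiff(c(want, label_col), names(df))
  if (length(missing_cols)) {
    stop("schema error: columns absent from file: ",
         paste(missing_cols, collapse = ", "))
  }
  lab_raw <- df[[label_col]]
  lab <- if (is.numeric(lab_raw)) as.integer(lab_raw) else {
    ifelse(lab_raw %in% c("Yes", "yes", "1"), 1L,
           ifelse(lab_raw %in% c("No", "no", "0"), 0L, NA_integer_))
  }
  lab[!lab %in% c(0L, 1L)] <- NA_integer_

  keep <- !is.na(lab)
  for (f in schema$factors) {
    v <- df[[f$name]]
    ok <- !is.na(v)
    if (f$kind %in% c("numeric", "ordinal")) {
      vn <- suppressWarnings(as.numeric(v))
      ok <- ok & !is.na(vn)
      df[[f$name]] <- vn
    } else {
      ok <- ok & as.character(v) %in% f$levels
    }
    keep <- keep & ok
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("load_records: dropped ", n_dropped, " incomplete record(s)")
  }
  out <- df[keep, want, drop = FALSE]
  rownames(out) <- NULL
  structure(list(data = out, label = lab[keep], n_dropped = n_dropped),
            class = "student_records")
}

#' @export
print.student_records <- function(x, ...) {
  cat("<student_records> n =", nrow(x$data), "| dropped =", x$n_dropped,
      "| prevalence =", round(mean(x$label), 3), "\n")
  invisible(x)
}
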
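#' Synthetic student-survey specification
#'
#' A generative model for survey-like records: factor marginals, a
#' logistic ground truth with known main-effect coefficients and planted
#' interactions, and a target label prevalence hit by auto-calibrating the
#' intercept. Effect terms act on internally standardized factor values
#' (`(value - center) / scale` for numeric/ordinal factors, 0/1 level
#' indicators otherwise) so coefficient magnitudes are comparable across
#' factors.
#'
#' @param schema a [factor_schema()].
#' @param main_effects list of terms: `list(factor=, beta=, level=NULL,
#'   center=0, scale=1)`.
#' @param interactions list of pairs: `list(factor1=, level1=NULL,
#'   center1=, scale1=, factor2=, level2=NULL, center2=, scale2=, beta=)`.
#' @param marginals named list of per-factor sampling settings: numeric
#'   `list(mean, sd, min, max)` (truncated normal); ordinal `list(min,
#'   max)` (discrete uniform); categorical/binary `list(probs)` (level
#'   probabilities, default uniform).
#' @param target_prevalence desired positive-label fraction in (0, 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(schema, main_effects = list(),
                           interactions = list(), marginals = list(),
                           target_prevalence = 0.59) {
  stopifnot(inherits(schema, "factor_schema"),
            target_prevalence > 0, target_prevalence < 1)
  nm <- schema_names(schema)
  check_term <- function(fac, lev) {
    if (!fac %in% nm) stop("synthetic_spec: unknown factor '", fac, "'")
    f <- schema$factors[[match(fac, nm)]]
    if (!is.null(lev) && !lev %in% f$levels) {
      stop("synthetic_spec: factor '", fac, "' has no level '", lev, "'")
    }
  }
  main_effects <- lapply(main_effects, function(t) {
    t$level <- t$level %||% NULL
    t$center <- t$center %||% 0
    t$scale <- t$scale %||% 1
    check_term(t$factor, t$level)
    t
  })
  for (it in interactions) {
    check_term(it$factor1, it$level1 %||% NULL)
    check_term(it$factor2, it$level2 %||% NULL)
  }
  structure(list(schema = schema, main_effects = main_effects,
                 interactions = interactions, marginals = marginals,
                 target_prevalence = target_prevalence),
            class = "synthetic_spec")
}

#' Default synthetic specification for student-depression surveys
#'
#' Sixteen factors mirroring a student mental-health survey (demographics,
#' academic indicators, lifestyle, and additional history items), with
#' ~59% label prevalence. Main-effect signs and descending magnitudes
#' encode the canonical risk ordering: suicidal ideation, academic
#' pressure, financial stress, work/study hours, family history and short
#' sleep raise risk; older age, healthy diet and study satisfaction lower
#' it. Two subgroup interactions are planted: CGPA raises risk for female
#' students only, and an unhealthy diet raises risk for doctoral students
#' specifically.
#'
#' @return A [synthetic_spec()].
#' @export
default_sdd_like_spec <- function() {
  schema <- factor_schema(list(
    list(name = "Age", kind = "numeric", levels = character(0)),
    list(name = "Gender", kind = "binary", levels = c("Female", "Male")),
    list(name = "City", kind = "categorical",
         levels = c("CityA", "CityB", "CityC")),
    list(name = "CGPA", kind = "numeric", levels = character(0)),
    list(name = "Study Satisfaction", kind = "ordinal", levels = character(0)),
    list(name = "Academic Pressure", kind = "ordinal", levels = character(0)),
    list(name = "Sleep Duration", kind = "categorical",
         levels = c("5-6 hours", "7-8 hours", "Less than 5 hours",
                    "More than 8 hours")),
    list(name = "Dietary Habits", kind = "categorical",
         levels = c("Healthy", "Moderate", "Unhealthy")),
    list(name = "Work/Study Hours", kind = "numeric", levels = character(0)),
    list(name = "Job Satisfaction", kind = "ordinal", levels = character(0)),
    list(name = "Work Pressure", kind = "ordinal", levels = character(0)),
    list(name = "Profession", kind = "categorical",
         levels = c("Other", "Student", "Working Professional")),
    list(name = "Degree", kind = "categorical",
         levels = c("BSc", "Class 12", "MSc", "PhD")),
    list(name = "Suicidal Thoughts", kind = "binary", levels = c("No", "Yes")),
    list(name = "Family History of Mental Illness", kind = "binary",
         levels = c("No", "Yes")),
    list(name = "Financial Stress", kind = "ordinal", levels = character(0))
  ))
  ord_c <- 3; ord_s <- sqrt(2)     # mean/sd of a discrete uniform on 1..5
  # Indicator main effects are standardized (center = level probability,
  # scale = its sd) so that |beta| is the effect size on a unit-sd term for
  # every factor and the coefficient ordering is the importance ordering.
  main <- list(
    list(factor = "Suicidal Thoughts", level = "Yes", beta = 2.0,
         center = 0.5, scale = 0.5),
    list(factor = "Academic Pressure", beta = 1.4, center = ord_c, scale = ord_s),
    list(factor = "Financial Stress", beta = 1.1, center = ord_c, scale = ord_s),
    list(factor = "Work/Study Hours", beta = 0.9, center = 6, scale = 3),
    list(factor = "Family History of Mental Illness", level = "Yes", beta = 0.7,
         center = 0.5, scale = 0.5),
    list(factor = "Sleep Duration", level = "Less than 5 hours", beta = 0.6,
         center = 0.25, scale = sqrt(0.25 * 0.75)),
    list(factor = "Age", beta = -0.5, center = 26, scale = 5),
    list(factor = "Dietary Habits", level = "Healthy", beta = -0.45,
         center = 1 / 3, scale = sqrt(2) / 3),
    list(factor = "Study Satisfaction", beta = -0.4, center = ord_c, scale = ord_s)
  )
  inter <- list(
    list(factor1 = "CGPA", center1 = 7.5, scale1 = 1.5,
         factor2 = "Gender", level2 = "Female", beta = 0.8),
    list(factor1 = "Dietary Habits", level1 = "Unhealthy",
         factor2 = "Degree", level2 = "PhD", beta = 1.0)
  )
  marg <- list(
    "Age" = list(mean = 26, sd = 5, min = 18, max = 40),
    "CGPA" = list(mean = 7.5, sd = 1.5, min = 5, max = 10),
    "Work/Study Hours" = list(mean = 6, sd = 3, min = 0, max = 12),
    "Study Satisfaction" = list(min = 1, max = 5),
    "Academic Pressure" = list(min = 1, max = 5),
    "Job Satisfaction" = list(min = 1, max = 5),
    "Work Pressure" = list(min = 1, max = 5),
    "Financial Stress" = list(min = 1, max = 5)
  )
  synthetic_spec(schema, main, inter, marg, target_prevalence = 0.59)
}

# Transformed value of one effect term given raw records. Level terms are
# 0/1 indicators; both kinds are shifted/scaled by (center, scale), so a
# main-effect indicator can be standardized (center = p, scale = sd) to make
# its coefficient magnitude comparable with scaled numeric terms, while
# interaction indicators keep the raw 0/1 coding (center 0, scale 1) so the
# partner effect is confined to the indicated subgroup.
term_value <- function(df, fac, level, center, scale) {
  v <- df[[fac]]
  raw <- if (!is.null(level)) as.numeric(as.character(v) == level) else as.numeric(v)
  (raw - (center %||% 0)) / (scale %||% 1)
}

linear_predictor <- function(spec, df) {
  lp <- numeric(nrow(df))
  for (t in spec$main_effects) {
    lp <- lp + t$beta * term_value(df, t$factor, t$level, t$center, t$scale)
  }
  for (it in spec$interactions) {
    v1 <- term_value(df, it$factor1, it$level1 %||% NULL,
                     it$center1 %||% 0, it$scale1 %||% 1)
    v2 <- term_value(df, it$factor2, it$level2 %||% NULL,
                     it$center2 %||% 0, it$scale2 %||% 1)
    lp <- lp + it$beta * v1 * v2
  }
  lp
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate synthetic survey records from a specification
#'
#' Factor values are drawn from the per-kind marginals, the intercept is
#' calibrated by root-finding so the expected prevalence matches the
#' specification target on the drawn covariates, and labels are Bernoulli
#' draws from the logistic model. Fully reproducible under `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return An object of class `synthetic_data`: `data` (data.frame of raw
#'   factors plus a `Depression` 0/1 column) and `truth` (intercept,
#'   per-record linear predictor and probability, and the spec).
#' @export
generate <- function(spec, n, seed = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1L)
  df <- NULL
  lab <- NULL
  with_seed(derive_seed(seed, "generate"), {
    cols <- list()
    for (f in spec$schema$factors) {
      m <- spec$marginals[[f$name]]
      cols[[f$name]] <- switch(
        f$kind,
        numeric = {
          m <- m %||% list(mean = 0, sd = 1, min = -3, max = 3)
          round(rtruncnorm1(n, m$mean, m$sd, m$min, m$max), 6)
        },
        ordinal = {
          m <- m %||% list(min = 1, max = 5)
          sample(seq(m$min, m$max), n, replace = TRUE)
        },
        {
          probs <- m$probs %||% rep(1 / length(f$levels), length(f$levels))
          sample(f$levels, n, replace = TRUE, prob = probs)
        })
    }
    df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- schema_names(spec$schema)
    lp <- linear_predictor(spec, df)
    fobj <- function(c0) mean(sigmoid(lp + c0)) - spec$target_prevalence
    if (fobj(-30) > 0 || fobj(30) < 0) {
      stop("calibration error: target prevalence ", spec$target_prevalence,
           " unreachable with the given coefficients")
    }
    c0 <- uniroot(fobj, c(-30, 30), tol = 1e-10)$root
    prob <- sigmoid(lp + c0)
    lab <- rbinom(n, 1L, prob)
    df$Depression <- lab
    attr(df, "truth") <- list(intercept = c0, linear_predictor = lp,
                               prob = prob)
  })
  truth <- attr(df, "truth")
  attr(df, "truth") <- NULL
  truth$spec <- spec
  structure(list(data = df, truth = truth), class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat("<synthetic_data> n =", nrow(x$data),
      "| prevalence =", round(mean(x$data$Depression), 3),
      "| intercept =", signif(x$truth$intercept, 4), "\n")
  invisible(x)
}

#' Write synthetic records (and the truth sidecar) to disk
#'
#' The CSV is in the same dialect [load_records()] reads; the truth
#' sidecar is test-only metadata and is never read by the pipeline.
#'
#' @param sim a `synthetic_data` object.
#' @param csv_path output CSV path.
#' @param truth_path optional JSON sidecar path.
#' @return `csv_path`, invisibly.
#' @export
synthetic_to_csv <- function(sim, csv_path, truth_path = NULL) {
  write.csv(sim$data, csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    sp <- sim$truth$spec
    jsonlite::write_json(
      list(intercept = sim$truth$intercept,
           target_prevalence = sp$target_prevalence,
           main_effects = sp$main_effects,
           interactions = sp$interactions,
           linear_predictor = sim$truth$linear_predictor),
      truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv_path)
}

#' Ground-truth prediction function on encoded rows
#'
#' Returns the logistic ground-truth probability as a function of a
#' raw-scale encoded matrix (columns as in [schema_columns()]); used as an
#' oracle model in attribution-recovery checks.
#'
#' @param spec a [synthetic_spec()].
#' @param intercept intercept to use (default 0; ranking-invariant).
#' @return Function mapping an encoded matrix to probabilities.
#' @export
spec_predict_fn <- function(spec, intercept = 0) {
  cols <- schema_columns(spec$schema)
  nm <- schema_names(spec$schema)
  enc_term <- function(X, fac, level, center, scale) {
    f <- spec$schema$factors[[match(fac, nm)]]
    raw <- if (!is.null(level)) {
      if (f$kind == "categorical") {
        X[, match(paste0(fac, "=", level), cols)]
      } else {                     # binary: second level encodes as 1
        v <- X[, match(fac, cols)]
        if (level == f$levels[2]) v else 1 - v
      }
    } else {
      X[, match(fac, cols)]
    }
    (raw - (center %||% 0)) / (scale %||% 1)
  }
  function(X) {
    X <- as.matrix(X)
    lp <- rep(intercept, nrow(X))
    for (t in spec$main_effects) {
      lp <- lp + t$beta * enc_term(X, t$factor, t$level, t$center, t$scale)
    }
    for (it in spec$interactions) {
      lp <- lp + it$beta *
        enc_term(X, it$factor1, it$level1 %||% NULL, it$center1 %||% 0,
                 it$scale1 %||% 1) *
        enc_term(X, it$factor2, it$level2 %||% NULL, it$center2 %||% 0,
                 it$scale2 %||% 1)
    }
    sigmoid(lp)
  }
}

#' Planted-importance recovery score
#'
#' Fraction of the `k` largest-|beta| ground-truth factors that appear in
#' the top `k` of the mean-|phi| ranking (encoded columns are aggregated
#' back to their parent factors by their maximum mean |phi|).
#'
#' @param attribution an [attribute_dataset()] result computed on data
#'   generated from `spec`.
#' @param spec the [synthetic_spec()] that generated the data.
#' @param k number of top factors compared.
#' @return A fraction in [0, 1].
#' @export
importance_recovery_score <- function(attribution, spec, k) {
  betas <- vapply(spec$main_effects, function(t) abs(t$beta), numeric(1))
  facs <- vapply(spec$main_effects, function(t) t$factor, character(1))
  truth_rank <- unique(facs[order(-betas)])
  if (k > length(schema_names(spec$schema))) {
    stop("importance_recovery_score: k exceeds the factor count")
  }
  top_truth <- head(truth_rank, k)
  cols <- schema_columns(spec$schema)
  parent <- schema_column_factors(spec$schema)[match(attribution$columns, cols)]
  mphi <- colMeans(abs(attribution$phi))
  fac_phi <- tapply(mphi, parent, max)
  top_hat <- names(sort(fac_phi, decreasing = TRUE))[seq_len(k)]
  length(intersect(top_truth, top_hat)) / k
}
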
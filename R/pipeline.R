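#' Run configuration for the end-to-end pipeline
#'
#' One global seed governs every stage (each stage derives its own stream
#' from it), and a serialized copy of the configuration is written to the
#' output directory before any computation, so a run directory is fully
#' reproducible from its config alone.
#'
#' @param input_csv path to the raw records CSV.
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed.
#' @param label_col label column name.
#' @param schema_overrides overrides passed to [infer_schema()].
#' @param model named list of [glnet_config()] arguments (minus
#'   `input_dim`, which is taken from the encoded data).
#' @param train named list of [train_config()] arguments.
#' @param attribution named list: `n_explain` (rows explained, drawn from
#'   the test partition), `M` (permutations per row), `background`
#'   (training rows in the reference set), `exact_limit`.
#' @param test_fraction,val_fraction_of_train split ratios.
#' @param threshold decision threshold.
#' @param bootstrap_replicates bootstrap replicates for the metric CIs.
#' @param subgroups character vector of `"Factor=value"` filters to
#'   summarize after attribution.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_csv, out_dir, seed = 0L,
                       label_col = "Depression",
                       schema_overrides = list(),
                       model = list(), train = list(),
                       attribution = list(),
                       test_fraction = 0.2, val_fraction_of_train = 0.15,
                       threshold = 0.5, bootstrap_replicates = 1000L,
                       subgroups = character(0)) {
  att <- list(n_explain = 200L, M = 20L, background = 100L, exact_limit = 15L)
  att[names(attribution)] <- attribution
  structure(list(input_csv = input_csv, out_dir = out_dir,
                 seed = as.integer(seed), label_col = label_col,
                 schema_overrides = schema_overrides,
                 model = model, train = train, attribution = att,
                 test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 threshold = threshold,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 subgroups = subgroups),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path configuration file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
run_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("config error: reading YAML requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw)
}

#' Serialize a synthetic specification to / from JSON
#'
#' @param spec a [synthetic_spec()]; @param path file path.
#' @return `path` (write) or a `synthetic_spec` (read).
#' @export
spec_to_json <- function(spec, path) {
  jsonlite::write_json(
    list(schema = lapply(spec$schema$factors, function(f) {
           list(name = f$name, kind = f$kind, levels = as.list(f$levels))
         }),
         main_effects = spec$main_effects,
         interactions = spec$interactions,
         marginals = spec$marginals,
         target_prevalence = spec$target_prevalence),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  if (!file.exists(path)) stop("config error: spec file not found: ", path)
  raw <- jsonlite::read_json(path)
  schema <- factor_schema(lapply(raw$schema, function(f) {
    list(name = f$name, kind = f$kind, levels = unlist(f$levels))
  }))
  synthetic_spec(schema,
                 main_effects = raw$main_effects %||% list(),
                 interactions = raw$interactions %||% list(),
                 marginals = raw$marginals %||% list(),
                 target_prevalence = raw$target_prevalence %||% 0.59)
}

#' Simulate records to disk (CLI backend)
#'
#' @param spec `"default"` or a path to a [spec_to_json()] file.
#' @param n number of records.
#' @param seed integer seed.
#' @param out output prefix; writes `<out>.csv` and `<out>_truth.json`.
#' @return Named character vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(spec = "default", n, seed = 0L, out) {
  sp <- if (identical(spec, "default")) default_sdd_like_spec()
        else spec_from_json(spec)
  sim <- generate(sp, n, seed)
  csv <- paste0(out, ".csv")
  truth <- paste0(out, "_truth.json")
  synthetic_to_csv(sim, csv, truth)
  invisible(c(csv = csv, truth = truth))
}

write_manifest <- function(out_dir, files) {
  paths <- file.path(out_dir, files)
  ok <- file.exists(paths)
  hashes <- rep(NA_character_, length(files))
  hashes[ok] <- unname(tools::md5sum(paths[ok]))
  jsonlite::write_json(setNames(as.list(hashes), files),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(hashes)
}

#' Run the full pipeline: encode, split, standardize, train, evaluate,
#' attribute, summarize
#'
#' Every artifact (schema, split, standardizer, checkpoint, metrics
#' report, attributions, global and subgroup summaries) is written to the
#' output directory, and a manifest lists each artifact with a content
#' hash. Reruns with the same configuration are byte-identical.
#'
#' @param config a [run_config()] (or a path readable by
#'   [run_config_from_file()]).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
pipeline_run_all <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- run_config_from_file(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say <- function(...) if (verbose) message(...)

  say("encode: inferring schema and encoding records")
  schema <- infer_schema(config$input_csv, config$schema_overrides,
                         label_col = config$label_col)
  schema_to_json(schema, file.path(out, "schema.json"))
  rec <- load_records(config$input_csv, schema, label_col = config$label_col)
  ds <- encode_dataset(rec, schema)

  say("split: stratified partition")
  split <- split_dataset(ds, config$test_fraction,
                         config$val_fraction_of_train, seed = config$seed)
  split_to_json(split, file.path(out, "split.json"))

  std <- fit_standardizer(ds, split$train)
  standardizer_to_json(std, file.path(out, "standardizer.json"))
  dss <- apply_standardizer(ds, std)

  say("train: optimizing the network")
  tr_args <- config$train
  tr_args$seed <- tr_args$seed %||% config$seed
  tcfg <- do.call(train_config, tr_args)
  m_args <- config$model
  m_args$input_dim <- ncol(dss$x)
  m_args$seed <- m_args$seed %||% config$seed
  mcfg <- do.call(glnet_config, m_args)
  fit <- train_model(dss, split, mcfg, tcfg, verbose = verbose)
  save_checkpoint(fit$model, file.path(out, "checkpoint.json"))
  write.csv(fit$history, file.path(out, "history.csv"), row.names = FALSE)

  say("evaluate: metrics with bootstrap CIs")
  report <- evaluate(fit, dss, split$test, threshold = config$threshold,
                     replicates = config$bootstrap_replicates,
                     seed = config$seed)
  report_to_json(report, file.path(out, "metrics.json"))

  say("explain: Shapley attribution")
  acfg <- config$attribution
  n_exp <- min(acfg$n_explain, length(split$test))
  n_bg <- min(acfg$background, length(split$train))
  with_seed(derive_seed(config$seed, "explain-rows"), {
    exp_idx <- sort(sample(split$test, n_exp))
    bg_idx <- sort(sample(split$train, n_bg))
  })
  att <- attribute_dataset(fit$model, dss$x[exp_idx, , drop = FALSE],
                           dss$x[bg_idx, , drop = FALSE],
                           M = acfg$M, exact_limit = acfg$exact_limit,
                           seed = config$seed, background_origin = "train")
  attribution_to_files(att, file.path(out, "attributions.csv"),
                       file.path(out, "attribution_meta.json"))
  explained_raw <- rec$data[exp_idx, , drop = FALSE]
  write.csv(explained_raw, file.path(out, "explained_records.csv"),
            row.names = FALSE)
  gs <- global_summary(att, schema)
  write.csv(gs$ranking, file.path(out, "global_summary.csv"),
            row.names = FALSE)
  write.table(gs$beeswarm, file.path(out, "beeswarm.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  sub_files <- character(0)
  for (flt in config$subgroups) {
    ss <- subgroup_attribution(att, explained_raw, flt, schema)
    fn <- paste0("subgroup_", gsub("[^A-Za-z0-9]+", "_", flt), ".csv")
    write.csv(ss$ranking, file.path(out, fn), row.names = FALSE)
    sub_files <- c(sub_files, fn)
  }

  files <- c("run_config.json", "schema.json", "split.json",
             "standardizer.json", "checkpoint.json", "history.csv",
             "metrics.json", "attributions.csv", "attribution_meta.json",
             "explained_records.csv", "global_summary.csv", "beeswarm.tsv",
             sub_files)
  write_manifest(out, files)
  say("done: ", length(files), " artifacts in ", out)
  invisible(list(schema = schema, split = split, standardizer = std,
                 fit = fit, report = report, attribution = att,
                 summary = gs, out_dir = out, files = files))
}

#' Subgroup summary over a completed run directory (CLI backend)
#'
#' @param run_dir a directory produced by [pipeline_run_all()].
#' @param filter `"Factor=value"` on raw factor values.
#' @param min_size minimum subgroup size before a warning.
#' @return The `subgroup_summary`, invisibly; writes
#'   `subgroup_<filter>.csv` into the run directory.
#' @export
pipeline_subgroup <- function(run_dir, filter, min_size = 30L) {
  need <- file.path(run_dir, c("schema.json", "attributions.csv",
                               "explained_records.csv",
                               "attribution_meta.json"))
  if (!all(file.exists(need))) {
    stop("run directory is incomplete: missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "))
  }
  schema <- schema_from_json(need[1])
  phi <- as.matrix(read.csv(need[2], check.names = FALSE))
  records <- read.csv(need[3], check.names = FALSE,
                      stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(need[4], simplifyVector = TRUE)
  values <- encode_dataset(records, schema)$x
  att <- structure(list(phi = phi, se = NULL,
                        base_value = meta$base_value, values = values,
                        columns = colnames(phi), estimator = meta$estimator,
                        config = as.list(meta$config)),
                   class = "attribution_result")
  ss <- subgroup_attribution(att, records, filter, schema,
                             min_size = min_size)
  fn <- file.path(run_dir,
                  paste0("subgroup_", gsub("[^A-Za-z0-9]+", "_", ss$filter),
                         ".csv"))
  write.csv(ss$ranking, fn, row.names = FALSE)
  invisible(ss)
}
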
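# Config-driven orchestration: describe -> calibrate -> evaluate per
# trait x scenario, with per-run artifacts (tidy per-fold CSVs, JSON
# summaries, a frozen copy of the resolved configuration) so every reported
# number is recomputable from the CSVs alone.

#' Run a configured experiment
#'
#' Executes the full pipeline for every trait x scenario combination in the
#' config: the season-comparison description once, then a nested-CV
#' evaluation per combination. A failure in one combination is caught, logged
#' and surfaced in the returned `failures` element without aborting the
#' others. Re-running with an identical config and seed reproduces the
#' artifacts byte for byte.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{data}{either a list `list(spectra =, traits =)` of in-memory
#'       objects, a list `list(spectra_path =, traits_path =, metadata_path =)`
#'       of CSV paths, or a [synthetic_config()] to simulate from.}
#'     \item{traits}{named list; each entry may set `model`, `aggregation`,
#'       `scenarios` (character vector), `calibration`, `noc_grid`, `c_grid`,
#'       `test_season`, `train_seasons` for that trait. An empty list uses
#'       the defaults (PLSR, genotype aggregation, random scenario,
#'       single-CV calibration).}
#'     \item{k_folds, reps, inner_folds, seed}{engine defaults, optional.}
#'     \item{describe}{logical, run [season_summary()] (default `TRUE`).}
#'     \item{out_dir}{optional output directory for artifacts.}
#'   }
#' @return list with `evaluations` (named list of `evaluation_result`),
#'   `description` (a `season_summary` or `NULL`), `failures` (named list of
#'   error messages) and `config` (the resolved configuration).
#' @export
run_experiment <- function(config) {
  seed <- config$seed %||% 1
  if (inherits(config$data, "synthetic_config")) {
    sim <- generate_dataset(config$data, seed = seed)
    ds <- sim$spectra; tt <- sim$traits
  } else if (!is.null(config$data$spectra_path)) {
    loaded <- load_dataset(config$data$spectra_path, config$data$traits_path,
                           config$data$metadata_path)
    ds <- loaded$spectra; tt <- loaded$traits
  } else {
    ds <- config$data$spectra; tt <- config$data$traits
    if (!inherits(ds, "spectral_dataset") || !inherits(tt, "trait_table")) {
      stop("config$data must supply spectra/traits objects, CSV paths, or a ",
           "synthetic_config")
    }
  }
  unknown <- setdiff(names(config$traits), names(tt$values))
  if (length(unknown)) {
    stop("config names unknown trait(s): ", paste(unknown, collapse = ", "))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  description <- NULL
  if (isTRUE(config$describe %||% TRUE)) {
    description <- season_summary(ds, tt, seed = seed)
    if (!is.null(out_dir)) write_season_summary(description, out_dir)
  }

  evaluations <- list()
  failures <- list()
  for (trait in names(config$traits)) {
    tc <- config$traits[[trait]]
    for (scen in tc$scenarios %||% "random") {
      key <- paste(trait, scen, sep = ".")
      res <- tryCatch(
        run_nested_cv(ds, tt, trait,
                      model = tc$model %||% "plsr",
                      aggregation = tc$aggregation %||% "genotype",
                      scenario = scen,
                      k_folds = config$k_folds %||% 5,
                      reps = config$reps %||% 20,
                      calibration = tc$calibration %||% "single_cv",
                      noc_grid = tc$noc_grid %||% 1:40,
                      c_grid = tc$c_grid %||% 10^seq(-3, 3, length.out = 9),
                      inner_folds = config$inner_folds %||% 3,
                      train_seasons = tc$train_seasons,
                      test_season = tc$test_season,
                      seed = seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
        next
      }
      evaluations[[key]] <- res
      if (!is.null(out_dir)) {
        write_evaluation(res,
                         csv_path = file.path(out_dir, paste0(key, "_folds.csv")),
                         json_path = file.path(out_dir, paste0(key, "_summary.json")))
      }
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(resolve_config_echo(config),
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  if (length(failures)) {
    message("experiment finished with ", length(failures), " failure(s): ",
            paste(names(failures), collapse = ", "))
  }
  list(evaluations = evaluations, description = description,
       failures = failures, config = config)
}

# a JSON-safe echo of the configuration (in-memory datasets summarised)
resolve_config_echo <- function(config) {
  echo <- config
  if (!inherits(config$data, "synthetic_config") &&
      is.null(config$data$spectra_path)) {
    echo$data <- list(in_memory = TRUE,
                      n_samples = nrow(config$data$spectra$reflectance),
                      n_wavelengths = length(config$data$spectra$wavelengths))
  } else if (inherits(config$data, "synthetic_config")) {
    echo$data <- unclass(config$data)
    echo$data$wavelengths <- range(config$data$wavelengths)
  }
  echo
}

#' Summarise a set of evaluation results
#'
#' One row per trait x scenario x model x aggregation with the median and
#' IQR of every metric; optionally a paired Wilcoxon signed-rank comparison
#' of the primary metric between two scenarios of the same trait (paired over
#' repetition means).
#'
#' @param results list of `evaluation_result` objects (e.g.
#'   `run_experiment(...)$evaluations`).
#' @param compare optional character vector of two scenario names to compare
#'   per trait with a paired Wilcoxon test.
#' @return data.frame report; when `compare` is given, the comparison table
#'   is attached as attribute `"comparisons"`.
#' @export
summarize_experiment <- function(results, compare = NULL) {
  if (!length(results)) stop("need at least one evaluation result")
  report <- do.call(rbind, lapply(results, function(res) {
    s <- res$summaries
    data.frame(trait = res$config$trait, scenario = res$config$scenario,
               model = res$config$model, aggregation = res$config$aggregation,
               metric = s$metric, median = s$median, iqr = s$iqr,
               n_folds = s$n_folds)
  }))
  rownames(report) <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2)
    traits <- unique(vapply(results, function(r) r$config$trait, character(1)))
    comps <- list()
    for (tr in traits) {
      pick <- function(scen) {
        hit <- Filter(function(r) r$config$trait == tr &&
                        r$config$scenario == scen, results)
        if (length(hit)) hit[[1]] else NULL
      }
      a <- pick(compare[1]); b <- pick(compare[2])
      if (is.null(a) || is.null(b)) next
      # pair over repetition means of the primary metric
      pa <- tapply(a$per_fold[[a$primary_metric]], a$per_fold$repetition,
                   mean, na.rm = TRUE)
      pb <- tapply(b$per_fold[[b$primary_metric]], b$per_fold$repetition,
                   mean, na.rm = TRUE)
      m <- min(length(pa), length(pb))
      pval <- stats::wilcox.test(pa[seq_len(m)], pb[seq_len(m)],
                                 paired = TRUE, exact = FALSE)$p.value
      comps[[tr]] <- data.frame(trait = tr, scenarioA = compare[1],
                                scenarioB = compare[2], p_value = pval,
                                stars = p_stars(pval))
    }
    attr(report, "comparisons") <- do.call(rbind, comps)
  }
  report
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}
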
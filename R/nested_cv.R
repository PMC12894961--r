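#' Run a nested cross-validation experiment for one trait
#'
#' The complete evaluation engine: aggregates the data, applies the trait's
#' wavelength window and optional per-season centring/scaling, drops rows
#' with a missing trait value (pairwise; spectra rows are never dropped
#' globally), builds the scenario's outer fold plan, audits it for leakage,
#' and then, for every outer fold, selects the model hyperparameter on the
#' calibration rows only (inner loop), refits on the full calibration set and
#' scores the validation set. Inner folds honour genotype exclusivity
#' whenever the outer scenario groups by genotype; the whole-season transfer
#' scenario uses random inner splits within the multi-season calibration set.
#'
#' Reported metrics: coefficient of determination and RMSE% for the
#' within-distribution scenarios (`random`, `unseen_genotype`); squared
#' Pearson correlation for the season-transfer scenarios, where trait
#' magnitudes shift between seasons and only the trend is assessed. All three
#' are recorded per fold when computable; `summaries` holds the median and
#' IQR of each across folds.
#'
#' @param ds a [spectral_dataset()].
#' @param tt a [trait_table()] aligned to `ds`.
#' @param trait trait name in `tt`.
#' @param model `"plsr"` or `"svr"`.
#' @param aggregation `"raw"`, `"plot"` or `"genotype"` (applied before fold
#'   construction).
#' @param scenario outer-loop scenario, see [build_fold_plan()].
#' @param k_folds,reps outer-loop design (default 20 repetitions of 5-fold).
#' @param calibration inner-loop strategy for PLSR: `"single_cv"`,
#'   `"repeated_cv"` or `"press"`.
#' @param noc_grid candidate NoC grid (PLSR).
#' @param c_grid candidate cost grid (SVR).
#' @param inner_folds,inner_reps inner-loop CV design (defaults: 3 folds;
#'   10 repetitions when `calibration = "repeated_cv"`).
#' @param press_subsamples,press_fraction PRESS inner-loop design.
#' @param train_seasons,test_season season scenario arguments, see
#'   [build_fold_plan()].
#' @param window wavelength window override; default: the trait's registry
#'   entry (full grid if none).
#' @param scale_by_season override for per-season trait centring/scaling;
#'   default: the trait's registry entry.
#' @param seed master seed.
#' @return an object of class `evaluation_result` with `per_fold`
#'   (data.frame: repetition, fold, n_val, hyperparameter, r2, rmse_pct,
#'   sq_pearson), `summaries`, and a `config` echo.
#' @export
run_nested_cv <- function(ds, tt, trait,
                          model = c("plsr", "svr"),
                          aggregation = c("raw", "plot", "genotype"),
                          scenario = c("random", "unseen_genotype",
                                       "unseen_season",
                                       "unseen_genotype_unseen_season"),
                          k_folds = 5, reps = 20,
                          calibration = c("single_cv", "repeated_cv", "press"),
                          noc_grid = 1:40,
                          c_grid = 10^seq(-3, 3, length.out = 9),
                          inner_folds = 3, inner_reps = 10,
                          press_subsamples = 100, press_fraction = 0.8,
                          train_seasons = NULL, test_season = NULL,
                          window = NULL, scale_by_season = NULL,
                          seed = 1) {
  model <- match.arg(model)
  aggregation <- match.arg(aggregation)
  scenario <- match.arg(scenario)
  calibration <- match.arg(calibration)
  if (!trait %in% names(tt$values)) stop("unknown trait '", trait, "'")

  agg <- aggregate_samples(ds, tt, aggregation)
  ds_a <- agg$spectra
  tt_a <- agg$traits

  reg <- tt_a$registry[[trait]] %||% list()
  window <- window %||% reg$window
  if (!is.null(window)) ds_a <- restrict_wavelengths(ds_a, window[1], window[2])
  scale_by_season <- scale_by_season %||% isTRUE(reg$scale_by_season)
  scale_params <- NULL
  if (scale_by_season) {
    cs <- center_scale_by_season(tt_a, trait)
    tt_a <- cs$table
    scale_params <- cs$params
  }

  keep <- which(!is.na(tt_a$values[[trait]]))
  if (length(keep) < 3) stop("fewer than 3 non-missing values of '", trait, "'")
  X <- ds_a$reflectance[keep, , drop = FALSE]
  y <- tt_a$values[[trait]][keep]
  meta <- ds_a$samples[keep, , drop = FALSE]

  plan <- build_fold_plan(meta, scenario, k_folds = k_folds, reps = reps,
                          train_seasons = train_seasons,
                          test_season = test_season, seed = seed)
  audit_fold_plan(plan, meta)

  inner_groups_for <- function(cal_idx) {
    if (plan$grouping == "genotype_id") meta$genotype_id[cal_idx] else NULL
  }

  rows <- list()
  counter <- 0L
  for (r in seq_along(plan$repetitions)) {
    for (f in seq_along(plan$repetitions[[r]])) {
      counter <- counter + 1L
      cal <- plan$repetitions[[r]][[f]]$calibration
      val <- plan$repetitions[[r]][[f]]$validation
      Xc <- X[cal, , drop = FALSE]; yc <- y[cal]
      Xv <- X[val, , drop = FALSE]; yv <- y[val]
      inner_seed <- child_seed(seed, 100000L + counter)
      groups <- inner_groups_for(cal)

      if (model == "plsr") {
        sel <- switch(calibration,
          single_cv = select_noc_single_cv(Xc, yc, noc_grid,
                                           k_folds = inner_folds,
                                           seed = inner_seed, groups = groups),
          repeated_cv = select_noc_repeated_cv(Xc, yc, noc_grid,
                                               reps = inner_reps,
                                               k_folds = inner_folds,
                                               seed = inner_seed,
                                               groups = groups),
          press = select_noc_press(Xc, yc, noc_grid,
                                   n_subsamples = press_subsamples,
                                   train_fraction = press_fraction,
                                   seed = inner_seed, groups = groups))
        hyper <- sel$consensus
        fit <- fit_plsr(Xc, yc, max_noc = min(hyper,
                                              min(nrow(Xc) - 1, ncol(Xc))))
        pred <- predict(fit, Xv, ncomp = fit$ncomp)
      } else {
        sel <- select_svr_c(Xc, yc, c_grid, k_folds = inner_folds,
                            seed = inner_seed, groups = groups)
        hyper <- sel$consensus
        fit <- fit_linear_svr(Xc, yc, C = hyper)
        pred <- predict(fit, Xv)
      }

      safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
      rows[[counter]] <- data.frame(
        repetition = r, fold = f, n_val = length(val),
        hyperparameter = hyper,
        r2 = safe(r_squared(yv, pred)),
        rmse_pct = safe(rmse_percent(yv, pred)),
        sq_pearson = safe(squared_pearson(yv, pred))
      )
    }
  }
  per_fold <- do.call(rbind, rows)

  primary <- if (scenario %in% c("random", "unseen_genotype")) "r2" else "sq_pearson"
  summaries <- summarize_metrics(per_fold)

  structure(
    list(per_fold = per_fold, summaries = summaries,
         primary_metric = primary,
         config = list(trait = trait, model = model,
                       aggregation = aggregation, scenario = scenario,
                       calibration = if (model == "plsr") calibration else "svr_c",
                       k_folds = plan$k_folds, reps = length(plan$repetitions),
                       inner_folds = inner_folds,
                       window = window, scale_by_season = scale_by_season,
                       train_seasons = plan$train_seasons,
                       test_season = plan$test_season, seed = seed),
         scale_params = scale_params),
    class = "evaluation_result"
  )
}

summarize_metrics <- function(per_fold) {
  mets <- c("r2", "rmse_pct", "sq_pearson")
  do.call(rbind, lapply(mets, function(m) {
    v <- per_fold[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m,
               median = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_,
               n_folds = length(v))
  }))
}

#' @export
print.evaluation_result <- function(x, ...) {
  cfg <- x$config
  cat("<evaluation_result> ", cfg$trait, " | ", cfg$model, " | ",
      cfg$scenario, " | aggregation = ", cfg$aggregation, "\n", sep = "")
  cat("  ", nrow(x$per_fold), " validation folds (", cfg$reps,
      " repetition(s) x ", cfg$k_folds, " fold(s))\n", sep = "")
  s <- x$summaries[x$summaries$metric == x$primary_metric, ]
  cat(sprintf("  %s: median %.3f (IQR %.3f)\n", x$primary_metric,
              s$median, s$iqr))
  invisible(x)
}

#' @export
summary.evaluation_result <- function(object, ...) {
  object$summaries
}

#' @export
plot.evaluation_result <- function(x, metric = x$primary_metric, ...) {
  graphics::boxplot(x$per_fold[[metric]], ylab = metric,
                    main = paste(x$config$trait, x$config$scenario, sep = " / "),
                    ...)
  invisible(x)
}

#' Write an evaluation result to CSV and JSON
#'
#' Tidy per-fold CSV (one row per validation fold) plus a JSON summary with
#' the config echo and the median/IQR table, so every reported number can be
#' recomputed from the CSV alone.
#'
#' @param x an `evaluation_result`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, `x`.
#' @export
write_evaluation <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(x$per_fold, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(config = x$config, summaries = x$summaries),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
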
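# Outer-loop fold plans for the four prediction scenarios and the leakage
# audit that every nested-CV run passes through.
#
# random                         : stratification-free random k-fold CV.
# unseen_genotype                : genotype-exclusive k-fold CV (all rows of
#                                  a genotype follow its fold).
# unseen_season                  : train on whole season(s), validate on the
#                                  held-out season (one calibration set).
# unseen_genotype_unseen_season  : validation = k-fold split of the target
#                                  season's genotypes; calibration = rows of
#                                  the training season(s) excluding the
#                                  validation genotypes.

#' Build a cross-validation fold plan for a prediction scenario
#'
#' @param samples metadata data.frame with at least `genotype_id` and
#'   `season` columns (e.g. the `samples` element of a [spectral_dataset()]).
#' @param scenario one of `"random"`, `"unseen_genotype"`, `"unseen_season"`,
#'   `"unseen_genotype_unseen_season"`.
#' @param k_folds folds per repetition (ignored for `"unseen_season"`).
#' @param reps number of repetitions (ignored for `"unseen_season"`).
#' @param train_seasons seasons used for calibration in the season scenarios;
#'   defaults to all seasons except `test_season`. Passing a single season to
#'   the strict scenario gives the single-training-season variant.
#' @param test_season the held-out season (season scenarios only).
#' @param seed master seed; repetition r shuffles with a derived child seed.
#' @return an object of class `fold_plan`: `repetitions` is a list of
#'   repetitions, each a list of folds with integer `calibration` and
#'   `validation` index vectors into `samples`.
#' @export
build_fold_plan <- function(samples,
                            scenario = c("random", "unseen_genotype",
                                         "unseen_season",
                                         "unseen_genotype_unseen_season"),
                            k_folds = 5, reps = 20, train_seasons = NULL,
                            test_season = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  n <- nrow(samples)
  geno <- as.character(samples$genotype_id)
  season <- as.character(samples$season)

  if (scenario %in% c("unseen_season", "unseen_genotype_unseen_season")) {
    if (is.null(test_season)) stop("test_season is required for this scenario")
    test_season <- as.character(test_season)
    if (!test_season %in% season) {
      stop("test season '", test_season, "' absent from the data")
    }
    train_seasons <- as.character(train_seasons %||%
                                    setdiff(unique(season), test_season))
    if (!length(train_seasons) || test_season %in% train_seasons) {
      stop("train_seasons must be non-empty and exclude the test season")
    }
    absent <- setdiff(train_seasons, season)
    if (length(absent)) {
      stop("training season(s) absent from the data: ",
           paste(absent, collapse = ", "))
    }
  }

  repetitions <- switch(
    scenario,
    random = lapply(seq_len(reps), function(r) {
      folds <- make_folds(n, k_folds, child_seed(seed, r))
      lapply(folds, function(v) list(calibration = setdiff(seq_len(n), v),
                                     validation = v))
    }),
    unseen_genotype = {
      if (k_folds > length(unique(geno))) {
        stop("k_folds (", k_folds, ") exceeds the number of genotypes (",
             length(unique(geno)), ")")
      }
      lapply(seq_len(reps), function(r) {
        folds <- make_folds(n, k_folds, child_seed(seed, r), groups = geno)
        lapply(folds, function(v) list(calibration = setdiff(seq_len(n), v),
                                       validation = v))
      })
    },
    unseen_season = {
      cal <- which(season %in% train_seasons)
      val <- which(season == test_season)
      if (!length(cal)) stop("empty calibration set")
      list(list(list(calibration = cal, validation = val)))
    },
    unseen_genotype_unseen_season = {
      target_idx <- which(season == test_season)
      target_geno <- unique(geno[target_idx])
      if (k_folds > length(target_geno)) {
        stop("k_folds (", k_folds, ") exceeds the number of genotypes in the ",
             "test season (", length(target_geno), ")")
      }
      train_pool <- which(season %in% train_seasons)
      lapply(seq_len(reps), function(r) {
        gfolds <- with_seed(child_seed(seed, r), {
          g <- sample(target_geno)
          split(g, rep(seq_len(k_folds), length.out = length(g)))
        })
        lapply(gfolds, function(gs) {
          list(calibration = train_pool[!geno[train_pool] %in% gs],
               validation = target_idx[geno[target_idx] %in% gs])
        })
      })
    }
  )

  structure(
    list(scenario = scenario,
         grouping = switch(scenario, random = "none",
                           unseen_genotype = "genotype_id",
                           unseen_season = "season",
                           unseen_genotype_unseen_season = "genotype_id"),
         repetitions = repetitions,
         k_folds = if (scenario == "unseen_season") 1L else as.integer(k_folds),
         train_seasons = if (exists("train_seasons", inherits = FALSE))
           train_seasons else NULL,
         test_season = test_season %||% NULL,
         n = n, seed = seed),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> scenario = ", x$scenario, " | ",
      length(x$repetitions), " repetition(s) x ", x$k_folds,
      " fold(s) | grouping = ", x$grouping, "\n", sep = "")
  invisible(x)
}

#' Audit a fold plan for information leakage
#'
#' Hard-errors if any fold shares a sample between calibration and
#' validation; if, under genotype grouping, a genotype appears on both sides
#' of a fold; if, under season holdout, a validation-season row enters the
#' calibration set; or if a repetition's validation sets fail to partition
#' the eligible samples. Called internally by [run_nested_cv()] before any
#' model is fitted; exported so corrupted or hand-built plans can be checked
#' directly.
#'
#' @param plan a [build_fold_plan()] result (possibly modified).
#' @param samples the metadata the plan indexes into.
#' @return `TRUE`, invisibly, when the plan is clean.
#' @export
audit_fold_plan <- function(plan, samples) {
  geno <- as.character(samples$genotype_id)
  season <- as.character(samples$season)
  for (r in seq_along(plan$repetitions)) {
    rep_folds <- plan$repetitions[[r]]
    all_val <- unlist(lapply(rep_folds, `[[`, "validation"))
    if (anyDuplicated(all_val)) {
      stop("leakage audit: validation folds overlap in repetition ", r)
    }
    eligible <- switch(plan$scenario,
                       unseen_season = which(season == plan$test_season),
                       unseen_genotype_unseen_season =
                         which(season == plan$test_season),
                       seq_len(plan$n))
    if (!setequal(all_val, eligible)) {
      stop("leakage audit: validation folds do not partition the eligible ",
           "samples in repetition ", r)
    }
    for (f in seq_along(rep_folds)) {
      cal <- rep_folds[[f]]$calibration
      val <- rep_folds[[f]]$validation
      if (length(intersect(cal, val))) {
        stop("leakage audit: sample shared between calibration and ",
             "validation (repetition ", r, ", fold ", f, ")")
      }
      if (plan$grouping == "genotype_id" &&
          length(intersect(geno[cal], geno[val]))) {
        stop("leakage audit: genotype present in both calibration and ",
             "validation (repetition ", r, ", fold ", f, ")")
      }
      if (!is.null(plan$test_season) &&
          any(season[cal] == plan$test_season)) {
        stop("leakage audit: test-season row in the calibration set ",
             "(repetition ", r, ", fold ", f, ")")
      }
    }
  }
  invisible(TRUE)
}
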
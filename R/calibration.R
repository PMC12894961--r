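# Inner-loop hyperparameter selection. Three strategies estimate the PLSR
# number of components (NoC): repeated k-fold CV minimising mean validation
# MSE with a modal consensus across repetitions; a single CV iteration; and
# PRESS accumulated over random train/test sub-samples. A fourth selector
# tunes the SVR cost C by CV MSE. All ties break toward the smallest
# hyperparameter (parsimony).

new_calibration_result <- function(strategy, candidates, error_curve,
                                   per_repetition_opt, consensus, seed) {
  structure(
    list(strategy = strategy, candidates = candidates,
         error_curve = error_curve, per_repetition_opt = per_repetition_opt,
         consensus = consensus, seed = seed),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> strategy = ", x$strategy,
      " | consensus = ", x$consensus, "\n", sep = "")
  if (length(x$per_repetition_opt) > 1) {
    tab <- table(x$per_repetition_opt)
    cat("  per-repetition optima: ",
        paste0(names(tab), " (x", tab, ")", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.calibration_result <- function(x, ...) {
  curve <- if (is.matrix(x$error_curve)) colMeans(x$error_curve) else x$error_curve
  graphics::plot(x$candidates, curve, type = "b", xlab = "candidate",
                 ylab = "CV error", main = paste0("Calibration (", x$strategy, ")"),
                 ...)
  graphics::abline(v = x$consensus, lty = 2)
  invisible(x)
}

# Predictions over a NoC grid from one fit; grid values beyond the model's
# effective component count reuse the converged maximum.
predict_noc_grid <- function(model, X, grid) {
  ncomp_use <- pmin(grid, model$ncomp)
  pred <- predict(model, X, ncomp = sort(unique(ncomp_use)))
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1)
  pred[, match(ncomp_use, sort(unique(ncomp_use))), drop = FALSE]
}

# One k-fold CV pass: mean-over-folds validation MSE per grid value.
cv_mse_noc <- function(X, y, grid, k_folds, seed, groups = NULL) {
  n <- nrow(X)
  folds <- make_folds(n, k_folds, seed, groups)
  mse <- matrix(NA_real_, length(folds), length(grid))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    if (!length(val) || length(val) == n) stop("degenerate fold")
    tr <- setdiff(seq_len(n), val)
    feas <- min(length(tr) - 1, ncol(X))
    if (min(grid) > feas) {
      stop("training fold too small for the NoC grid; feasible maximum is ", feas)
    }
    fit <- fit_plsr(X[tr, , drop = FALSE], y[tr],
                    max_noc = min(max(grid), feas))
    pred <- predict_noc_grid(fit, X[val, , drop = FALSE], grid)
    mse[f, ] <- colMeans((pred - y[val])^2)
  }
  colMeans(mse)
}

#' Select the PLSR number of components by repeated cross-validation
#'
#' Runs `reps` repetitions of `k_folds`-fold CV over the candidate grid. Each
#' repetition selects its own optimum (the grid value minimising the mean
#' validation MSE across folds); the consensus is the most frequently chosen
#' per-repetition optimum, ties broken toward the smaller value. The default
#' design of 20 repetitions of 5-fold CV characterises the stability of NoC
#' selection under data partitioning.
#'
#' @param X n x p predictor matrix.
#' @param y response vector.
#' @param noc_grid integer candidate grid (default 1-40); values infeasible
#'   for the smallest training fold are dropped.
#' @param reps number of CV repetitions.
#' @param k_folds folds per repetition.
#' @param seed master seed; repetition r uses a derived child seed.
#' @param groups optional grouping labels (e.g. genotype); folds are then
#'   group-exclusive, so inner-loop selection honours the outer scenario's
#'   exclusivity.
#' @return a `calibration_result` with the per-candidate error curve
#'   (repetitions x candidates), per-repetition optima, and the consensus.
#' @export
select_noc_repeated_cv <- function(X, y, noc_grid = 1:40, reps = 20,
                                   k_folds = 5, seed = 1, groups = NULL) {
  X <- as.matrix(X)
  grid <- validate_noc_grid(noc_grid, nrow(X), ncol(X), k_folds)
  curve <- matrix(NA_real_, reps, length(grid),
                  dimnames = list(NULL, grid))
  opts <- integer(reps)
  for (r in seq_len(reps)) {
    curve[r, ] <- cv_mse_noc(X, y, grid, k_folds, child_seed(seed, r), groups)
    opts[r] <- grid[which.min(curve[r, ])]
  }
  new_calibration_result("repeated_cv", grid, curve, opts,
                         consensus = mode_smallest(opts), seed = seed)
}

#' Select the PLSR number of components by a single cross-validation
#'
#' One `k_folds`-fold CV iteration; returns the MSE-minimising grid value
#' (ties toward the smaller). Equivalent to [select_noc_repeated_cv()] with
#' `reps = 1`, and the fast default for nested-CV inner loops.
#'
#' @inheritParams select_noc_repeated_cv
#' @return a `calibration_result`.
#' @export
select_noc_single_cv <- function(X, y, noc_grid = 1:40, k_folds = 3,
                                 seed = 1, groups = NULL) {
  out <- select_noc_repeated_cv(X, y, noc_grid, reps = 1, k_folds = k_folds,
                                seed = seed, groups = groups)
  out$strategy <- "single_cv"
  out
}

#' Select the PLSR number of components by the PRESS statistic
#'
#' Draws `n_subsamples` random train/test splits (default 100 splits with an
#' 80/20 ratio), fits on each training part, and accumulates the squared
#' prediction errors of the held-out part per candidate. `NoC_PRESS` is the
#' grid value with the smallest total PRESS, ties toward the smaller value
#' (the global minimum; no one-standard-error rule).
#'
#' @inheritParams select_noc_repeated_cv
#' @param n_subsamples number of random sub-samples.
#' @param train_fraction fraction of samples (or groups) used for training.
#' @return a `calibration_result`; `error_curve` holds per-sub-sample SSE
#'   (rows) and `per_repetition_opt` the per-sub-sample minimisers.
#' @export
select_noc_press <- function(X, y, noc_grid = 1:40, n_subsamples = 100,
                             train_fraction = 0.8, seed = 1, groups = NULL) {
  X <- as.matrix(X)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  n <- nrow(X)
  n_train_target <- if (is.null(groups)) floor(n * train_fraction) else NA
  grid <- validate_noc_grid(noc_grid, nrow(X), ncol(X), k_folds = NULL,
                            n_train = if (is.null(groups)) n_train_target else NULL)
  sse <- matrix(NA_real_, n_subsamples, length(grid),
                dimnames = list(NULL, grid))
  opts <- integer(n_subsamples)
  for (s in seq_len(n_subsamples)) {
    idx <- with_seed(child_seed(seed, s), {
      if (is.null(groups)) {
        sample.int(n, n_train_target)
      } else {
        ug <- unique(groups)
        tr_g <- sample(ug, floor(length(ug) * train_fraction))
        which(groups %in% tr_g)
      }
    })
    test <- setdiff(seq_len(n), idx)
    if (!length(test)) stop("test split of size 0")
    feas <- min(length(idx) - 1, ncol(X))
    if (min(grid) > feas) {
      stop("training sub-sample too small for the NoC grid; feasible maximum is ",
           feas)
    }
    fit <- fit_plsr(X[idx, , drop = FALSE], y[idx],
                    max_noc = min(max(grid), feas))
    pred <- predict_noc_grid(fit, X[test, , drop = FALSE], grid)
    sse[s, ] <- colSums((pred - y[test])^2)
    opts[s] <- grid[which.min(sse[s, ])]
  }
  press <- colSums(sse)
  new_calibration_result("press", grid, sse, opts,
                         consensus = grid[which.min(press)], seed = seed)
}

#' Select the SVR cost hyperparameter by cross-validation
#'
#' k-fold CV mean validation MSE per candidate cost; returns the minimiser,
#' ties toward the smallest C. The default grid spans 1e-3 to 1e3 in 9
#' log-spaced steps.
#'
#' @inheritParams select_noc_repeated_cv
#' @param c_grid positive candidate costs.
#' @param epsilon SVR tube half-width (standardised response scale).
#' @return a `calibration_result`.
#' @export
select_svr_c <- function(X, y, c_grid = 10^seq(-3, 3, length.out = 9),
                         k_folds = 3, seed = 1, groups = NULL,
                         epsilon = 0.1) {
  X <- as.matrix(X)
  if (any(c_grid <= 0)) stop("c_grid values must be positive")
  c_grid <- sort(c_grid)
  n <- nrow(X)
  folds <- make_folds(n, k_folds, child_seed(seed, 1), groups)
  mse <- matrix(NA_real_, length(folds), length(c_grid))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    tr <- setdiff(seq_len(n), val)
    for (j in seq_along(c_grid)) {
      fit <- fit_linear_svr(X[tr, , drop = FALSE], y[tr], C = c_grid[j],
                            epsilon = epsilon)
      mse[f, j] <- mean((predict(fit, X[val, , drop = FALSE]) - y[val])^2)
    }
  }
  curve <- colMeans(mse)
  best <- c_grid[which.min(curve)]
  new_calibration_result("svr_c", c_grid,
                         matrix(curve, 1, dimnames = list(NULL, c_grid)),
                         per_repetition_opt = best, consensus = best,
                         seed = seed)
}

# Truncate a NoC grid to what the smallest training fold can support.
validate_noc_grid <- function(grid, n, p, k_folds, n_train = NULL) {
  if (!length(grid)) stop("noc_grid is empty")
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1)) stop("noc_grid values must be >= 1")
  if (is.null(n_train)) {
    n_train <- if (is.null(k_folds)) n - 1 else n - ceiling(n / k_folds)
  }
  feas <- min(n_train - 1, p)
  kept <- grid[grid <= feas]
  if (!length(kept)) {
    stop("no feasible NoC candidate: smallest training fold supports at most ",
         feas, " components")
  }
  kept
}

#' Write a calibration result to CSV and JSON
#'
#' One CSV row per candidate x repetition plus a JSON summary carrying the
#' strategy, consensus and seed.
#'
#' @param x a `calibration_result`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the long-format data.frame.
#' @export
write_calibration <- function(x, csv_path = NULL, json_path = NULL) {
  curve <- x$error_curve
  if (!is.matrix(curve)) curve <- matrix(curve, 1)
  long <- data.frame(
    repetition = rep(seq_len(nrow(curve)), each = ncol(curve)),
    candidate = rep(x$candidates, times = nrow(curve)),
    error = as.vector(t(curve))
  )
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(strategy = x$strategy, consensus = x$consensus,
           per_repetition_opt = x$per_repetition_opt, seed = x$seed),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(long)
}
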
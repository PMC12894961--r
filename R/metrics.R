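# Validation-fold metrics. R^2 and RMSE% assess agreement on the measured
# scale (within-distribution scenarios); squared Pearson correlation assesses
# the trend only and is invariant to affine rescaling of the predictions
# (cross-season transfer, where trait magnitudes shift between seasons).

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with `SS_tot` about the observed mean of the
#' validation fold. May be negative when predictions are worse than the
#' fold mean.
#'
#' @param obs,pred numeric vectors of equal length (>= 2).
#' @return a real number in (-Inf, 1].
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 2) stop("need at least 2 observations")
  if (stats::sd(obs) == 0) stop("observed values are constant")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Relative root mean squared error, in percent
#'
#' `100 * RMSE / mean(obs)` by default; `normalize = "range"` divides by the
#' observed range instead. Scale-invariant: multiplying both vectors by a
#' positive constant leaves the value unchanged.
#'
#' @param obs,pred numeric vectors of equal length.
#' @param normalize `"mean"` (default) or `"range"`.
#' @return RMSE as a percentage of the normaliser.
#' @export
rmse_percent <- function(obs, pred, normalize = c("mean", "range")) {
  normalize <- match.arg(normalize)
  stopifnot(length(obs) == length(pred))
  rmse <- sqrt(mean((obs - pred)^2))
  denom <- switch(normalize,
                  mean = mean(obs),
                  range = diff(range(obs)))
  if (denom == 0) stop("zero ", normalize, " of observed values")
  100 * rmse / denom
}

#' Squared Pearson correlation
#'
#' @param obs,pred numeric non-constant vectors of length >= 3.
#' @return squared Pearson correlation in \[0, 1\].
#' @export
squared_pearson <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 3) stop("need at least 3 observations")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    stop("constant input: Pearson correlation undefined")
  }
  stats::cor(obs, pred)^2
}
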
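#' Fit a univariate partial least squares regression (NIPALS)
#'
#' Extracts latent components sequentially by the NIPALS algorithm: each
#' component is the direction in predictor space with maximal covariance with
#' the current response residual, and both predictors and response are
#' deflated after every extraction. Predictors and response are mean-centred;
#' unit-variance scaling of the predictors is off by default because
#' reflectance columns share units (set `scale = TRUE` to enable). The model
#' stores enough structure to produce, for any number of components
#' `k <= max_noc`, the coefficient vector and intercept on the original
#' scale, so a single fit serves a whole component grid.
#'
#' Component extraction stops early when the deflated predictor matrix is
#' numerically exhausted (squared Frobenius norm below `1e-12` of its initial
#' value) or a weight/score norm vanishes; `ncomp` records the effective
#' number of extracted components. A constant response yields a valid model
#' with all-zero coefficients and intercept `mean(y)`.
#'
#' @param X numeric n x p predictor matrix (spectra; n >= 3).
#' @param y numeric response vector of length n, no missing values.
#' @param max_noc maximum number of components, `1 <= max_noc <= min(n-1, p)`.
#' @param center,scale centre / unit-variance-scale the predictor columns.
#' @return object of class `plsr_model` with elements `coefficients`
#'   (p x ncomp matrix, column k = original-scale coefficients using k
#'   components), `intercepts`, `scores`, `weights`, `loadings`, `y_loadings`,
#'   `ncomp`, `max_noc`, and the centring/scaling parameters.
#' @seealso [predict.plsr_model()], [coef.plsr_model()]
#' @export
fit_plsr <- function(X, y, max_noc, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 samples")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (!is.numeric(max_noc) || max_noc < 1 || max_noc > min(n - 1, p)) {
    stop("max_noc must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]")
  }
  max_noc <- as.integer(max_noc)
  x_center <- if (center) colMeans(X) else rep(0, p)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  if (all(matrixStats_colvar(X) == 0)) {
    stop("all predictor columns are constant")
  }
  y_center <- mean(y)

  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yc <- y - y_center

  W <- matrix(0, p, max_noc)  # weights
  P <- matrix(0, p, max_noc)  # x loadings
  Tm <- matrix(0, n, max_noc) # scores
  q <- numeric(max_noc)       # y loadings

  if (stats::sd(y) == 0) {
    coefs <- matrix(0, p, max_noc)
    return(new_plsr_model(coefs, rep(y_center, max_noc), Tm, W, P, q,
                          ncomp = max_noc, max_noc, x_center, x_scale,
                          y_center, constant_y = TRUE,
                          train_residuals = y - y_center))
  }

  x0 <- sum(Xc^2)
  ncomp <- 0L
  for (a in seq_len(max_noc)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - t * qa
    ncomp <- a
    if (sum(Xc^2) < 1e-12 * x0) break
  }
  if (ncomp == 0L) stop("no component could be extracted")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]

  # R maps centred X to scores: T = Xc R, with R = W (P'W)^{-1}
  R <- W %*% solve(crossprod(P, W))
  # cumulative coefficient columns: beta_k = R[, 1:k] %*% q[1:k]
  bq <- sweep(R, 2, q, "*")
  coefs_scaled <- if (ncomp == 1) bq else t(apply(bq, 1, cumsum))
  coefs <- sweep(coefs_scaled, 1, x_scale, "/")
  intercepts <- y_center - drop(x_center %*% coefs)

  new_plsr_model(coefs, intercepts, Tm, W, P, q, ncomp, max_noc,
                 x_center, x_scale, y_center, constant_y = FALSE,
                 train_residuals = yc)
}

matrixStats_colvar <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

new_plsr_model <- function(coefficients, intercepts, scores, weights, loadings,
                           y_loadings, ncomp, max_noc, x_center, x_scale,
                           y_center, constant_y, train_residuals = NULL) {
  structure(
    list(coefficients = coefficients, intercepts = intercepts,
         scores = scores, weights = weights, loadings = loadings,
         y_loadings = y_loadings, ncomp = as.integer(ncomp),
         max_noc = as.integer(max_noc), x_center = x_center,
         x_scale = x_scale, y_center = y_center, constant_y = constant_y,
         train_residuals = train_residuals),
    class = "plsr_model"
  )
}

#' Predict from a PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata m x p numeric matrix on the training wavelength grid.
#' @param ncomp number(s) of components to use; each must not exceed the
#'   effective `object$ncomp`. Default: the effective maximum.
#' @param ... unused.
#' @return numeric vector (single `ncomp`) or m x length(ncomp) matrix of
#'   predictions on the original response scale.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$coefficients)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         nrow(object$coefficients))
  }
  if (any(ncomp < 1) || any(ncomp > object$ncomp)) {
    stop("ncomp out of range [1, ", object$ncomp, "]")
  }
  pred <- sweep(X %*% object$coefficients[, ncomp, drop = FALSE], 2,
                object$intercepts[ncomp], "+")
  if (length(ncomp) == 1) drop(pred) else pred
}

#' @param object a `plsr_model`.
#' @param ncomp number of components for the reported coefficient vector.
#' @param ... unused.
#' @rdname fit_plsr
#' @export
coef.plsr_model <- function(object, ncomp = object$ncomp, ...) {
  if (ncomp < 1 || ncomp > object$ncomp) {
    stop("ncomp out of range [1, ", object$ncomp, "]")
  }
  c(`(Intercept)` = object$intercepts[ncomp],
    stats::setNames(object$coefficients[, ncomp],
                    rownames(object$coefficients)))
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("<plsr_model> ", x$ncomp, " components (requested max ", x$max_noc,
      "), p = ", nrow(x$coefficients), "\n", sep = "")
  if (x$constant_y) cat("  constant response: zero coefficients\n")
  invisible(x)
}

#' @export
residuals.plsr_model <- function(object, ...) {
  object$train_residuals
}
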
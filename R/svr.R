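#' Fit a linear-kernel epsilon-insensitive support vector regression
#'
#' Wraps the libsvm epsilon-regression solver (via \pkg{e1071}) with a linear
#' kernel. Predictors are standardised to unit variance and the response is
#' standardised internally (so the default tube half-width `epsilon = 0.1` is
#' on the standardised response scale, and only the cost `C` needs tuning);
#' the fitted affine function is reported on the original scales.
#'
#' @param X numeric n x p predictor matrix (n >= 3).
#' @param y numeric response vector, no missing values.
#' @param C positive regularization (cost) hyperparameter.
#' @param epsilon non-negative tube half-width on the standardised response.
#' @return object of class `svr_model` with original-scale `coefficients`
#'   (length p) and `intercept`, the hyperparameters, and the
#'   standardisation parameters.
#' @export
fit_linear_svr <- function(X, y, C = 1, epsilon = 0.1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stop("C must be positive")
  if (epsilon < 0) stop("epsilon must be non-negative")

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1

  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  fit <- tryCatch(
    e1071::svm(x = Xs, y = ys, type = "eps-regression", kernel = "linear",
               cost = C, epsilon = epsilon, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$tot.nSV == 0) {
    # every point inside the tube: the flat function is optimal
    w_s <- rep(0, ncol(X))
    b_s <- 0
    n_sv <- 0L
  } else {
    w_s <- drop(crossprod(fit$coefs, fit$SV)) # weights on standardised scale
    b_s <- -fit$rho
    n_sv <- nrow(fit$SV)
  }
  beta <- y_scale * w_s / x_scale
  intercept <- y_center + y_scale * (b_s - sum(w_s * x_center / x_scale))

  structure(
    list(coefficients = beta, intercept = intercept, C = C, epsilon = epsilon,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         y_scale = y_scale, n_support = n_sv),
    class = "svr_model"
  )
}

#' Predict from a linear SVR model
#'
#' The prediction is affine in the input spectrum:
#' `X %*% coefficients + intercept`.
#'
#' @param object an `svr_model`.
#' @param newdata m x p numeric matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$coefficients))
  }
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
coef.svr_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> linear kernel, C = ", x$C, ", epsilon = ", x$epsilon,
      ", ", x$n_support, " support vectors\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes the coefficients, intercept, preprocessing parameters and
#' hyperparameters of a `plsr_model` or `svr_model` to a JSON structure for
#' reproducibility; [model_from_json()] restores an equivalent predictor.
#'
#' @param model a `plsr_model` or `svr_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, c("plsr_model", "svr_model")))
  payload <- unclass(model)
  payload$model_class <- class(model)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json a JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  cls <- payload$model_class
  payload$model_class <- NULL
  if (identical(cls, "plsr_model")) {
    payload$coefficients <- as.matrix(payload$coefficients)
    for (nm in c("scores", "weights", "loadings")) {
      payload[[nm]] <- as.matrix(payload[[nm]])
    }
  }
  structure(payload, class = cls)
}
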
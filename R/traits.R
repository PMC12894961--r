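#' Construct a trait table
#'
#' Holds per-sample trait values aligned to a [spectral_dataset()] by sample
#' order, together with a per-trait registry describing how each trait is
#' modelled: the wavelength window its models use and whether its values are
#' centred and scaled within each season before seasons are combined.
#'
#' @param samples metadata data.frame as in [spectral_dataset()].
#' @param values data.frame of numeric trait columns, one row per sample;
#'   `NA` marks a missing measurement. Spectra rows are never dropped for
#'   missing traits; missingness is handled pairwise at model-fitting time.
#' @param registry named list, one entry per trait (optional), each a list
#'   with elements `window` (length-2 numeric in nm, or `NULL` for the full
#'   grid) and `scale_by_season` (logical, default `FALSE`).
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(samples, values, registry = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  values <- as.data.frame(values)
  if (nrow(values) != nrow(samples)) {
    stop("trait values rows (", nrow(values), ") != metadata rows (",
         nrow(samples), ")")
  }
  if (!all(vapply(values, is.numeric, logical(1)))) {
    stop("all trait columns must be numeric")
  }
  registry <- registry %||% list()
  for (tr in names(registry)) {
    if (!tr %in% names(values)) {
      stop("registry names unknown trait '", tr, "'")
    }
    registry[[tr]]$window <- registry[[tr]]$window %||% NULL
    registry[[tr]]$scale_by_season <- isTRUE(registry[[tr]]$scale_by_season)
  }
  structure(list(samples = samples, values = values, registry = registry),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  n_miss <- vapply(x$values, function(v) sum(is.na(v)), integer(1))
  cat("<trait_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " traits\n", sep = "")
  for (tr in names(x$values)) {
    reg <- x$registry[[tr]]
    win <- if (!is.null(reg$window)) {
      paste0(reg$window[1], "-", reg$window[2], " nm")
    } else "full grid"
    cat("  ", tr, ": ", n_miss[[tr]], " missing | window ", win,
        if (isTRUE(reg$scale_by_season)) " | scaled by season" else "",
        "\n", sep = "")
  }
  invisible(x)
}

# Row subset companion to subset_samples().
subset_traits <- function(tt, idx) {
  trait_table(tt$samples[idx, , drop = FALSE],
              tt$values[idx, , drop = FALSE], tt$registry)
}

#' Centre and scale a trait within each season
#'
#' Transforms one trait so that within every season it has mean 0 and sample
#' standard deviation 1. Used before combining seasons as training data when
#' a trait's level shifts between seasons (the situation observed for SLA):
#' the shift is otherwise absorbed as noise and degrades cross-season
#' transfer. The per-season parameters are returned so predictions can be
#' mapped back to the original scale when required; squared Pearson
#' correlation, the transfer metric, is invariant to the choice.
#'
#' @param tt a [trait_table()].
#' @param trait trait name.
#' @return list with `table` (the transformed `trait_table`) and `params`
#'   (data.frame `season`, `mean`, `sd`).
#' @export
center_scale_by_season <- function(tt, trait) {
  if (!trait %in% names(tt$values)) stop("unknown trait '", trait, "'")
  y <- tt$values[[trait]]
  season <- tt$samples$season
  params <- lapply(split(seq_along(y), season), function(idx) {
    v <- y[idx]
    v <- v[!is.na(v)]
    if (length(v) < 2) {
      stop("season needs at least 2 non-missing values of '", trait, "'")
    }
    s <- stats::sd(v)
    if (s == 0) stop("zero within-season standard deviation for '", trait, "'")
    c(mean = mean(v), sd = s)
  })
  out <- y
  for (se in names(params)) {
    idx <- which(season == se)
    out[idx] <- (y[idx] - params[[se]]["mean"]) / params[[se]]["sd"]
  }
  tt$values[[trait]] <- out
  list(
    table = tt,
    params = data.frame(
      season = names(params),
      mean = vapply(params, `[`, numeric(1), "mean"),
      sd = vapply(params, `[`, numeric(1), "sd"),
      row.names = NULL
    )
  )
}
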
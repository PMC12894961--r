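#' Construct a spectral dataset
#'
#' Bundles an n x p leaf reflectance matrix with its wavelength grid and
#' per-sample metadata. Wavelengths must be strictly increasing; reflectance
#' is unitless in (roughly) \[0, 1\]. Metadata carries the field hierarchy:
#' genotype, season, plot, replicate.
#'
#' @param reflectance numeric matrix, one row per leaf sample, one column per
#'   wavelength.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, length equal to `ncol(reflectance)`.
#' @param samples data.frame with columns `sample_id`, `genotype_id`,
#'   `season`, `plot_id`, `replicate_id`; one row per reflectance row.
#'   `sample_id` must be unique, as must the joint
#'   (genotype, season, plot, replicate) key.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(reflectance, wavelengths, samples) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths)) {
    stop("reflectance has ", ncol(reflectance), " columns but ",
         length(wavelengths), " wavelengths were given")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (anyNA(reflectance)) stop("reflectance contains missing values")
  required <- c("sample_id", "genotype_id", "season", "plot_id", "replicate_id")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("samples metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- as.data.frame(lapply(samples[required], as.character),
                           stringsAsFactors = FALSE)
  if (nrow(samples) != nrow(reflectance)) {
    stop("metadata rows (", nrow(samples), ") != reflectance rows (",
         nrow(reflectance), ")")
  }
  dup <- duplicated(samples$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[dup]), collapse = ", "))
  }
  key <- do.call(paste, c(samples[required[-1]], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("(genotype_id, season, plot_id, replicate_id) keys are not unique")
  }
  if (any(reflectance < -0.01 | reflectance > 1.5)) {
    warning("reflectance values outside [-0.01, 1.5] detected")
  }
  rownames(reflectance) <- samples$sample_id
  colnames(reflectance) <- format(wavelengths, trim = TRUE, scientific = FALSE)
  structure(
    list(reflectance = reflectance, wavelengths = wavelengths, samples = samples),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", nrow(x$reflectance), " samples x ",
      length(x$wavelengths), " wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm)\n", sep = "")
  cat("  genotypes: ", length(unique(x$samples$genotype_id)),
      " | seasons: ", paste(sort(unique(x$samples$season)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$reflectance)

# Row subset keeping the container invariants.
subset_samples <- function(ds, idx) {
  spectral_dataset(ds$reflectance[idx, , drop = FALSE], ds$wavelengths,
                   ds$samples[idx, , drop = FALSE])
}

#' Retain every step-th wavelength
#'
#' Keeps wavelength indices 1, 1 + step, 1 + 2 step, ... (the first grid point
#' is always retained). With a 400-2400 nm, 1 nm grid (2001 wavelengths) and
#' `step = 5` this leaves 401 wavelengths, the usual dimension-reduction
#' choice for PLSR on leaf spectra.
#'
#' @param ds a [spectral_dataset()].
#' @param step positive integer stride.
#' @return a `spectral_dataset` on the thinned grid.
#' @export
subsample_wavelengths <- function(ds, step) {
  if (!is.numeric(step) || length(step) != 1 || step < 1 || step != round(step)) {
    stop("step must be a positive integer")
  }
  keep <- seq(1L, length(ds$wavelengths), by = as.integer(step))
  spectral_dataset(ds$reflectance[, keep, drop = FALSE],
                   ds$wavelengths[keep], ds$samples)
}

#' Restrict spectra to a wavelength window
#'
#' Keeps wavelengths in the closed interval `[lo, hi]`. Traits such as leaf
#' nitrogen percentage and C:N are conventionally modelled on the 1500-2400 nm
#' shortwave-infrared window only.
#'
#' @param ds a [spectral_dataset()].
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return a `spectral_dataset` on the restricted grid.
#' @export
restrict_wavelengths <- function(ds, lo, hi) {
  if (!(lo < hi)) stop("lo must be smaller than hi")
  keep <- which(ds$wavelengths >= lo & ds$wavelengths <= hi)
  if (!length(keep)) {
    stop("no wavelengths in window [", lo, ", ", hi, "] nm")
  }
  spectral_dataset(ds$reflectance[, keep, drop = FALSE],
                   ds$wavelengths[keep], ds$samples)
}
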
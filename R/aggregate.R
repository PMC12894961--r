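#' Aggregate replicates by plot or genotype
#'
#' Averages reflectance (wavelength by wavelength) and trait values over the
#' replicate structure. `"plot"` keeps one row per (genotype, season, plot);
#' `"genotype"` keeps one row per (genotype, season). Trait means ignore
#' missing cells (a group with no observed value stays `NA`); reflectance has
#' no missing values by construction. Collapsed hierarchy levels are marked
#' with the sentinel `"*"` in the metadata.
#'
#' @param ds a [spectral_dataset()].
#' @param tt a [trait_table()] aligned to `ds`, or `NULL`.
#' @param level one of `"raw"`, `"plot"`, `"genotype"`.
#' @return list with `spectra` and `traits` at the requested level.
#' @export
aggregate_samples <- function(ds, tt = NULL, level = c("raw", "plot", "genotype")) {
  level <- match.arg(level)
  if (level == "raw") return(list(spectra = ds, traits = tt))
  s <- ds$samples
  if (level == "plot") {
    key <- paste(s$genotype_id, s$season, s$plot_id, sep = "\r")
  } else {
    key <- paste(s$genotype_id, s$season, sep = "\r")
  }
  groups <- split(seq_len(nrow(s)), key)
  # preserve first-appearance order of groups
  groups <- groups[unique(key)]

  refl <- do.call(rbind, lapply(groups, function(idx) {
    colMeans(ds$reflectance[idx, , drop = FALSE])
  }))
  first <- vapply(groups, `[`, integer(1), 1L)
  meta <- s[first, , drop = FALSE]
  meta$replicate_id <- "*"
  if (level == "genotype") meta$plot_id <- "*"
  meta$sample_id <- if (level == "plot") {
    paste(meta$genotype_id, meta$season, meta$plot_id, sep = "_")
  } else {
    paste(meta$genotype_id, meta$season, sep = "_")
  }
  rownames(meta) <- NULL
  ds_out <- spectral_dataset(refl, ds$wavelengths, meta)

  tt_out <- NULL
  if (!is.null(tt)) {
    vals <- as.data.frame(lapply(tt$values, function(v) {
      vapply(groups, function(idx) {
        x <- v[idx][!is.na(v[idx])]
        if (length(x)) mean(x) else NA_real_
      }, numeric(1))
    }))
    rownames(vals) <- NULL
    tt_out <- trait_table(meta, vals, tt$registry)
  }
  list(spectra = ds_out, traits = tt_out)
}
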
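# CSV readers and writers.
#
# Spectra: wide CSV, first column sample_id, remaining headers numeric nm.
# Traits: CSV sample_id + one column per trait, empty cell = missing.
# Metadata: CSV sample_id, genotype_id, season, plot_id, replicate_id.
# Numbers are written with 17 significant digits so that a written dataset
# reads back bit-identically (round-trip guarantee used by the tests).

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", flag = "")
  out <- trimws(out)
  out[is.na(x)] <- ""
  out
}

write_table_raw <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
}

#' Write the three dataset CSV files
#'
#' @param ds a [spectral_dataset()].
#' @param tt a [trait_table()] aligned to `ds` (may be `NULL`).
#' @param spectra_path,traits_path,metadata_path output file paths.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(ds, tt, spectra_path, traits_path = NULL,
                          metadata_path = NULL) {
  spec <- data.frame(sample_id = ds$samples$sample_id, stringsAsFactors = FALSE)
  refl <- apply(ds$reflectance, 2, fmt_num)
  if (is.null(dim(refl))) refl <- matrix(refl, nrow = 1)
  spec <- cbind(spec, as.data.frame(refl, stringsAsFactors = FALSE))
  names(spec) <- c("sample_id", fmt_num(ds$wavelengths))
  write_table_raw(spec, spectra_path)
  written <- spectra_path
  if (!is.null(traits_path) && !is.null(tt)) {
    tr <- data.frame(sample_id = tt$samples$sample_id, stringsAsFactors = FALSE)
    for (nm in names(tt$values)) tr[[nm]] <- fmt_num(tt$values[[nm]])
    write_table_raw(tr, traits_path)
    written <- c(written, traits_path)
  }
  if (!is.null(metadata_path)) {
    write_table_raw(ds$samples, metadata_path)
    written <- c(written, metadata_path)
  }
  invisible(written)
}

#' Load a paired spectra / trait / metadata dataset from CSV
#'
#' Reads the three files, validates them, and aligns trait and metadata rows
#' to the spectra's sample order. Rows whose traits are all missing are
#' retained (missing traits are handled pairwise at fit time); samples absent
#' from the trait file get all-`NA` traits and are reported via a message.
#'
#' @param spectra_path wide spectra CSV (`sample_id` + numeric nm headers).
#' @param traits_path trait CSV (`sample_id` + one column per trait); `NULL`
#'   for a spectra-only load.
#' @param metadata_path metadata CSV with the sample hierarchy columns.
#' @param registry optional trait registry, passed to [trait_table()].
#' @return list with elements `spectra` ([spectral_dataset()]) and `traits`
#'   ([trait_table()], `NULL` when no trait file was given).
#' @export
load_dataset <- function(spectra_path, traits_path = NULL, metadata_path,
                         registry = NULL) {
  for (p in c(spectra_path, traits_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  spec <- utils::read.csv(spectra_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(spec)[1] != "sample_id") {
    stop("spectra file must have 'sample_id' as its first column")
  }
  wl <- suppressWarnings(as.numeric(names(spec)[-1]))
  if (anyNA(wl)) stop("non-numeric wavelength header in spectra file")
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    stop("wavelength header is not strictly increasing")
  }
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_meta <- setdiff(spec$sample_id, meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing sample_id(s): ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  }
  meta <- meta[match(spec$sample_id, meta$sample_id), , drop = FALSE]
  refl <- as.matrix(spec[-1])
  storage.mode(refl) <- "double"
  ds <- spectral_dataset(refl, wl, meta)

  tt <- NULL
  if (!is.null(traits_path)) {
    tr <- utils::read.csv(traits_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (names(tr)[1] != "sample_id") {
      stop("trait file must have 'sample_id' as its first column")
    }
    absent <- setdiff(spec$sample_id, tr$sample_id)
    if (length(absent)) {
      message(length(absent), " sample(s) missing from the trait file; ",
              "their traits are set to NA: ",
              paste(utils::head(absent, 5), collapse = ", "))
    }
    vals <- tr[match(spec$sample_id, tr$sample_id), -1, drop = FALSE]
    rownames(vals) <- NULL
    for (nm in names(vals)) vals[[nm]] <- as.numeric(vals[[nm]])
    tt <- trait_table(ds$samples, vals, registry)
  }
  list(spectra = ds, traits = tt)
}
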
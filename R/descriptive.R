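# Season-comparison descriptive statistics: within-season trait variability,
# rank stability of genotype means between seasons, cross-season similarity
# of genotype-mean spectra by wavelength region, and Mantel permutation tests
# on the genotype-covariance structure of the spectra.

#' Coefficient of variation of a trait within a season
#'
#' `100 * sample SD / mean` over the season's non-missing values.
#'
#' @param tt a [trait_table()].
#' @param trait trait name.
#' @param season season label.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(tt, trait, season) {
  if (!trait %in% names(tt$values)) stop("unknown trait '", trait, "'")
  v <- tt$values[[trait]][tt$samples$season == as.character(season)]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 non-missing values")
  m <- mean(v)
  if (m == 0) stop("zero mean: CV undefined")
  100 * stats::sd(v) / m
}

# genotype-mean trait values for one season, named by genotype
genotype_means <- function(tt, trait, season) {
  idx <- tt$samples$season == as.character(season)
  tapply(tt$values[[trait]][idx], tt$samples$genotype_id[idx],
         function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

#' Between-season Spearman correlation of genotype means
#'
#' Ranks genotype-mean trait values in two seasons over the genotypes present
#' (with a non-missing mean) in both, and returns their Spearman correlation:
#' a measure of how stable the genotype ranking is across seasons.
#'
#' @param tt a [trait_table()].
#' @param trait trait name.
#' @param seasonA,seasonB season labels.
#' @return Spearman rank correlation in \[-1, 1\].
#' @export
between_season_spearman <- function(tt, trait, seasonA, seasonB) {
  a <- genotype_means(tt, trait, seasonA)
  b <- genotype_means(tt, trait, seasonB)
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) < 3) stop("fewer than 3 genotypes shared between seasons")
  stats::cor(a[shared], b[shared], method = "spearman")
}

# genotype-mean spectra for one season: genotypes x wavelengths matrix
genotype_mean_spectra <- function(ds, season) {
  idx <- which(ds$samples$season == as.character(season))
  g <- ds$samples$genotype_id[idx]
  groups <- split(idx, g)
  out <- do.call(rbind, lapply(groups, function(i) {
    colMeans(ds$reflectance[i, , drop = FALSE])
  }))
  rownames(out) <- names(groups)
  out
}

#' Cross-season correlation of genotype-mean spectra in a region
#'
#' For each genotype present in both seasons, computes the Pearson
#' correlation across the region's wavelengths between its season-A and
#' season-B mean spectra, and returns the mean over genotypes. The
#' alternative reading — per-wavelength correlation across genotypes,
#' averaged over the region's wavelengths — is available via
#' `method = "per_wavelength"`.
#'
#' @param ds a [spectral_dataset()].
#' @param region length-2 numeric wavelength window in nm.
#' @param seasonA,seasonB season labels.
#' @param method `"per_genotype"` (default) or `"per_wavelength"`.
#' @return mean correlation.
#' @export
cross_season_spectral_correlation <- function(ds, region, seasonA, seasonB,
                                              method = c("per_genotype",
                                                         "per_wavelength")) {
  method <- match.arg(method)
  sel <- ds$wavelengths >= region[1] & ds$wavelengths <= region[2]
  if (!any(sel)) stop("empty wavelength region")
  A <- genotype_mean_spectra(ds, seasonA)[, sel, drop = FALSE]
  B <- genotype_mean_spectra(ds, seasonB)[, sel, drop = FALSE]
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 3) stop("fewer than 3 genotypes shared between seasons")
  A <- A[shared, , drop = FALSE]; B <- B[shared, , drop = FALSE]
  if (method == "per_genotype") {
    mean(vapply(seq_along(shared),
                function(i) stats::cor(A[i, ], B[i, ]), numeric(1)))
  } else {
    mean(vapply(seq_len(ncol(A)),
                function(j) stats::cor(A[, j], B[, j]), numeric(1)))
  }
}

#' Mantel permutation test between two symmetric matrices
#'
#' The Mantel statistic is the Pearson correlation of the upper off-diagonal
#' triangles of `A` and `B`. Significance comes from simultaneous row/column
#' permutations of `B`: with random permutations the one-sided upper p-value
#' uses the `(count + 1) / (n_perm + 1)` estimator; with `exact = TRUE` all
#' `n!` permutations are enumerated (n <= 8) and `p = #{r_perm >= r_obs} / n!`
#' (the identity permutation counts, so p >= 1/n!).
#'
#' @param A,B symmetric numeric matrices of equal dimension (e.g. covariance
#'   matrices of genotype-mean spectra in two seasons, over shared genotypes).
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all permutations instead of sampling.
#' @return list with `r` (Mantel statistic) and `p` (permutation p-value).
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = 1, exact = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!isSymmetric(unname(A)) || !isSymmetric(unname(B))) {
    stop("A and B must be symmetric")
  }
  if (!all(dim(A) == dim(B))) stop("A and B must have the same dimension")
  n <- nrow(A)
  ut <- upper.tri(A)
  r_obs <- stats::cor(A[ut], B[ut])
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(pp) {
      stats::cor(A[ut], B[pp, pp][ut])
    }, numeric(1))
    p <- mean(r_perm >= r_obs)
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        pp <- sample.int(n)
        stats::cor(A[ut], B[pp, pp][ut]) >= r_obs
      }, logical(1)))
    })
    p <- (count + 1) / (n_perm + 1)
  }
  list(r = r_obs, p = p)
}

#' Season-comparison summary of a multi-season dataset
#'
#' Computes, in one pass: per trait x season coefficients of variation (plus
#' the plain across-season average), per trait the between-season Spearman
#' matrix of genotype means, per wavelength region the mean cross-season
#' correlation of genotype-mean spectra, and per season pair the Mantel
#' statistic and permutation p-value comparing the covariance matrices (over
#' shared genotypes) of genotype-mean spectra.
#'
#' @param ds a [spectral_dataset()].
#' @param tt a [trait_table()].
#' @param traits trait names to summarise (default: all).
#' @param regions named list of length-2 wavelength windows; defaults to the
#'   visible (350-700 nm), near-infrared (700-1300 nm) and shortwave-infrared
#'   (1300-2500 nm) regions, intersected with the dataset grid.
#' @param n_perm Mantel permutations.
#' @param seed RNG seed.
#' @return an object of class `season_summary`.
#' @export
season_summary <- function(ds, tt, traits = names(tt$values),
                           regions = list(visible = c(350, 700),
                                          nir = c(700, 1300),
                                          swir = c(1300, 2500)),
                           n_perm = 999, seed = 1) {
  seasons <- sort(unique(ds$samples$season))
  pairs <- if (length(seasons) > 1) utils::combn(seasons, 2) else NULL

  cv <- do.call(rbind, lapply(traits, function(tr) {
    vals <- vapply(seasons, function(se) {
      tryCatch(coefficient_of_variation(tt, tr, se),
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(trait = tr, season = seasons, cv_percent = vals)
  }))
  cv_mean <- stats::aggregate(cv_percent ~ trait, data = cv, FUN = mean)
  names(cv_mean)[2] <- "mean_cv_percent"

  spearman <- NULL
  spectral_cor <- NULL
  mantel <- NULL
  if (!is.null(pairs)) {
    spearman <- do.call(rbind, lapply(traits, function(tr) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        rho <- tryCatch(
          between_season_spearman(tt, tr, pairs[1, j], pairs[2, j]),
          error = function(e) NA_real_)
        data.frame(trait = tr, seasonA = pairs[1, j], seasonB = pairs[2, j],
                   spearman = rho)
      }))
    }))
    spectral_cor <- do.call(rbind, lapply(names(regions), function(rg) {
      win <- c(max(regions[[rg]][1], min(ds$wavelengths)),
               min(regions[[rg]][2], max(ds$wavelengths)))
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        val <- tryCatch(
          cross_season_spectral_correlation(ds, win, pairs[1, j], pairs[2, j]),
          error = function(e) NA_real_)
        data.frame(region = rg, lo_nm = win[1], hi_nm = win[2],
                   seasonA = pairs[1, j], seasonB = pairs[2, j],
                   mean_correlation = val)
      }))
    }))
    mantel <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      GA <- genotype_mean_spectra(ds, pairs[1, j])
      GB <- genotype_mean_spectra(ds, pairs[2, j])
      shared <- intersect(rownames(GA), rownames(GB))
      CA <- stats::cov(t(GA[shared, , drop = FALSE]))
      CB <- stats::cov(t(GB[shared, , drop = FALSE]))
      mt <- mantel_test(CA, CB, n_perm = n_perm, seed = child_seed(seed, j))
      data.frame(seasonA = pairs[1, j], seasonB = pairs[2, j],
                 mantel_r = mt$r, p_value = mt$p)
    }))
  }

  structure(list(cv = cv, cv_mean = cv_mean, spearman = spearman,
                 spectral_correlation = spectral_cor, mantel = mantel,
                 seasons = seasons),
            class = "season_summary")
}

#' @export
print.season_summary <- function(x, ...) {
  cat("<season_summary> seasons: ", paste(x$seasons, collapse = ", "), "\n",
      sep = "")
  cat("  mean CV% per trait:\n")
  print(x$cv_mean, row.names = FALSE)
  if (!is.null(x$mantel)) {
    cat("  Mantel (spectral covariance across genotypes):\n")
    print(x$mantel, row.names = FALSE)
  }
  invisible(x)
}

#' Write a season summary to CSV files
#'
#' @param x a `season_summary`.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_season_summary <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("cv", "cv_mean", "spearman", "spectral_correlation", "mantel")) {
    if (!is.null(x[[nm]])) {
      f <- file.path(dir, paste0("season_summary_", nm, ".csv"))
      utils::write.csv(x[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
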
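# Synthetic multi-season hyperspectral dataset generator.
#
# Emulates the statistical structure the pipeline assumes: a balanced
# genotype x season x plot x replicate design; smooth reflectance spectra
# driven by a small number of latent factors whose per-sample scores
# decompose into genotype, season, genotype-by-environment (GxE), plot and
# residual Gaussian components; traits that are linear in the latent scores
# plus noise; and an optional per-season raised plateau in the 750-1500 nm
# near-infrared region so season-transfer failure modes are reproducible.
# It is a latent-variable statistical emulator, not a radiative-transfer
# model of leaf optics.

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror a three-season field trial of a large genotype panel:
#' 320 genotypes x 3 seasons x 2 plots x 3 replicates, reflectance on a
#' 400-2400 nm grid at 1 nm steps. Variance components are on the
#' latent-score scale.
#'
#' @param n_genotypes,n_seasons,plots_per_genotype,reps_per_plot design sizes.
#' @param wavelengths wavelength grid in nm (strictly increasing).
#' @param n_latent number of smooth Gaussian-bump spectral basis functions.
#' @param sigma2_G,sigma2_S,sigma2_GxE,sigma2_P,sigma2_E variance components
#'   of the latent scores: genotype, season, genotype-by-season interaction,
#'   plot, and per-sample residual.
#' @param traits named list of trait definitions, each a list with `loadings`
#'   (length `n_latent`, recycled/padded if shorter), `noise_sd`,
#'   `season_shift` (`NULL` or length `n_seasons` additive trait shifts),
#'   `window` (`NULL` or length-2 nm window) and `scale_by_season`. Default:
#'   a structural trait (`"sla"`, full grid) and a biochemical trait
#'   (`"n_pct"`, 1500-2400 nm window), both loading on the leading factors.
#' @param basis_amplitude reflectance amplitude per unit latent score.
#' @param plateau_shift per-season additive shift of the 750-1500 nm
#'   reflectance plateau; default raises it by 0.05 in the second season to
#'   mimic a season with anomalous near-infrared reflectance.
#' @param spectral_noise_sd standard deviation of the smooth per-sample
#'   measurement noise added to the spectra.
#' @param trait_missing_rate fraction of trait cells set missing at random.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genotypes = 320, n_seasons = 3,
                             plots_per_genotype = 2, reps_per_plot = 3,
                             wavelengths = 400:2400, n_latent = 5,
                             sigma2_G = 1, sigma2_S = 0.5, sigma2_GxE = 0.3,
                             sigma2_P = 0.05, sigma2_E = 0.2,
                             traits = NULL, basis_amplitude = 0.012,
                             plateau_shift = NULL,
                             spectral_noise_sd = 0.002,
                             trait_missing_rate = 0) {
  vars <- c(sigma2_G, sigma2_S, sigma2_GxE, sigma2_P, sigma2_E)
  if (any(vars < 0)) stop("variance components must be non-negative")
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (n_latent > length(wavelengths)) stop("n_latent exceeds the grid size")
  if (is.null(plateau_shift)) {
    plateau_shift <- rep(0, n_seasons)
    if (n_seasons >= 2) plateau_shift[2] <- 0.05
  }
  if (length(plateau_shift) != n_seasons) {
    stop("plateau_shift must have one entry per season")
  }
  if (is.null(traits)) {
    trunc_load <- function(x) x[seq_len(min(length(x), n_latent))]
    traits <- list(
      sla = list(loadings = trunc_load(c(1, 0.5, 0.25)), noise_sd = 0.5,
                 season_shift = NULL, window = NULL, scale_by_season = FALSE),
      n_pct = list(loadings = trunc_load(c(0.3, 1, 0, 0.4)), noise_sd = 0.5,
                   season_shift = NULL,
                   window = c(max(1500, min(wavelengths)), max(wavelengths)),
                   scale_by_season = FALSE)
    )
  }
  for (nm in names(traits)) {
    ld <- traits[[nm]]$loadings
    if (length(ld) > n_latent) stop("loadings of '", nm, "' exceed n_latent")
    traits[[nm]]$loadings <- c(ld, rep(0, n_latent - length(ld)))
    traits[[nm]]$noise_sd <- traits[[nm]]$noise_sd %||% 0.5
    traits[[nm]]$scale_by_season <- isTRUE(traits[[nm]]$scale_by_season)
  }
  structure(
    list(n_genotypes = n_genotypes, n_seasons = n_seasons,
         plots_per_genotype = plots_per_genotype, reps_per_plot = reps_per_plot,
         wavelengths = wavelengths, n_latent = n_latent,
         sigma2_G = sigma2_G, sigma2_S = sigma2_S, sigma2_GxE = sigma2_GxE,
         sigma2_P = sigma2_P, sigma2_E = sigma2_E,
         traits = traits, basis_amplitude = basis_amplitude,
         plateau_shift = plateau_shift,
         spectral_noise_sd = spectral_noise_sd,
         trait_missing_rate = trait_missing_rate),
    class = "synthetic_config"
  )
}

# Gaussian-bump basis over the grid: p x k matrix, each column peaking at 1.
gaussian_bumps <- function(wavelengths, k, width_factor = 2) {
  rng <- range(wavelengths)
  centers <- seq(rng[1] + 0.1 * diff(rng), rng[2] - 0.1 * diff(rng),
                 length.out = k)
  width <- diff(rng) / (width_factor * k)
  sapply(centers, function(cc) exp(-0.5 * ((wavelengths - cc) / width)^2))
}

# smooth leaf-like reflectance baseline: low visible, NIR plateau, SWIR decay
reflectance_baseline <- function(w) {
  0.10 + 0.40 * stats::plogis((w - 710) / 25) *
    (1 - 0.35 * stats::plogis((w - 1420) / 150))
}

# smooth window over the 750-1500 nm plateau
plateau_window <- function(w) {
  stats::plogis((w - 750) / 20) * stats::plogis((1500 - w) / 20)
}

#' Generate a synthetic multi-season hyperspectral dataset
#'
#' The latent score of sample i on factor f is
#' `t_if = g_f(genotype) + s_f(season) + gx_f(genotype, season) + p_f(plot) + e_if`,
#' each term Gaussian with its configured variance. A reflectance row is the
#' season baseline plus `basis_amplitude * sum_f t_if basis_f(wavelength)`
#' plus smooth measurement noise, clipped to \[0, 1\] (a warning is issued if
#' clipping touches more than 5% of values). Each trait is
#' `loadings . t_i + season_shift + noise`, where the trait's latent scores
#' share every component with the spectral scores except the
#' genotype-by-season deviation, which is drawn independently: G x E
#' decouples a trait from its spectral signature across seasons, which is the
#' mechanism that limits cross-season model transfer. Identical
#' `(config, seed)` pairs produce bit-identical datasets.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return list with `spectra` ([spectral_dataset()]), `traits`
#'   ([trait_table()] with the registry filled from the config) and `truth`
#'   (latent scores, basis, loadings, the config and seed).
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  G <- cfg$n_genotypes; S <- cfg$n_seasons
  P <- cfg$plots_per_genotype; R <- cfg$reps_per_plot
  L <- cfg$n_latent
  w <- cfg$wavelengths
  p <- length(w)

  meta <- expand.grid(replicate_id = paste0("R", seq_len(R)),
                      plot_id = paste0("P", seq_len(P)),
                      season = paste0("S", seq_len(S)),
                      genotype_id = sprintf("G%04d", seq_len(G)),
                      stringsAsFactors = FALSE)
  meta <- meta[, c("genotype_id", "season", "plot_id", "replicate_id")]
  meta$sample_id <- do.call(paste, c(meta, sep = "_"))
  n <- nrow(meta)

  gi <- match(meta$genotype_id, unique(meta$genotype_id))
  si <- match(meta$season, unique(meta$season))
  pi_ <- match(meta$plot_id, unique(meta$plot_id))

  with_seed(seed, {
    # Spectral and trait latent scores share the genotype, season, plot and
    # residual components; the genotype-by-season (GxE) deviation is drawn
    # independently for the two. A leaf's biochemical response to a season
    # and the optical signature of that response decouple under
    # environment-specific regulation, and it is exactly this decoupling --
    # not G x E variance per se -- that limits cross-season transfer of
    # spectra-trait models. With sigma2_GxE = 0 the two score sets coincide.
    scores <- matrix(0, n, L)        # drives the spectra
    trait_scores <- matrix(0, n, L)  # drives the traits
    for (f in seq_len(L)) {
      g_eff <- stats::rnorm(G, 0, sqrt(cfg$sigma2_G))
      s_eff <- stats::rnorm(S, 0, sqrt(cfg$sigma2_S))
      gx_spec <- matrix(stats::rnorm(G * S, 0, sqrt(cfg$sigma2_GxE)), G, S)
      gx_trait <- matrix(stats::rnorm(G * S, 0, sqrt(cfg$sigma2_GxE)), G, S)
      p_eff <- array(stats::rnorm(G * S * P, 0, sqrt(cfg$sigma2_P)), c(G, S, P))
      e_eff <- stats::rnorm(n, 0, sqrt(cfg$sigma2_E))
      shared <- g_eff[gi] + s_eff[si] + p_eff[cbind(gi, si, pi_)] + e_eff
      scores[, f] <- shared + gx_spec[cbind(gi, si)]
      trait_scores[, f] <- shared + gx_trait[cbind(gi, si)]
    }

    basis <- gaussian_bumps(w, L)
    base <- reflectance_baseline(w)
    plate <- plateau_window(w)
    refl <- matrix(rep(base, each = n), n, p)
    refl <- refl + outer(cfg$plateau_shift[si], plate)
    refl <- refl + cfg$basis_amplitude * tcrossprod(scores, basis)
    if (cfg$spectral_noise_sd > 0) {
      noise_basis <- gaussian_bumps(w, max(12, min(24, p)), width_factor = 1.5)
      noise_coef <- matrix(stats::rnorm(n * ncol(noise_basis), 0,
                                        cfg$spectral_noise_sd),
                           n, ncol(noise_basis))
      refl <- refl + tcrossprod(noise_coef, noise_basis)
    }
    clipped <- mean(refl < 0 | refl > 1)
    if (clipped > 0.05) {
      warning(sprintf(paste0("%.1f%% of reflectance values were clipped to ",
                             "[0, 1]; consider reducing basis_amplitude"),
                      100 * clipped))
    }
    refl[refl < 0] <- 0
    refl[refl > 1] <- 1

    vals <- list()
    registry <- list()
    for (nm in names(cfg$traits)) {
      tr <- cfg$traits[[nm]]
      y <- drop(trait_scores %*% tr$loadings)
      if (!is.null(tr$season_shift)) {
        if (length(tr$season_shift) != S) {
          stop("season_shift of '", nm, "' must have one entry per season")
        }
        y <- y + tr$season_shift[si]
      }
      y <- y + stats::rnorm(n, 0, tr$noise_sd)
      if (cfg$trait_missing_rate > 0) {
        y[stats::runif(n) < cfg$trait_missing_rate] <- NA_real_
      }
      vals[[nm]] <- y
      registry[[nm]] <- list(window = tr$window,
                             scale_by_season = tr$scale_by_season)
    }

    ds <- spectral_dataset(refl, w, meta)
    tt <- trait_table(meta, as.data.frame(vals), registry)
    truth <- list(scores = scores, trait_scores = trait_scores, basis = basis,
                  loadings = lapply(cfg$traits, `[[`, "loadings"),
                  config = cfg, seed = seed)
    list(spectra = ds, traits = tt, truth = truth)
  })
}
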
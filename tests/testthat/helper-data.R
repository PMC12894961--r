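# Fixtures are built in code; nothing is read from disk.

# tiny dataset with a known hierarchy: n_geno genotypes x n_seasons seasons
# x plots x reps on a short wavelength grid
make_toy_ds <- function(n_geno = 2, n_seasons = 1, plots = 2, reps = 3,
                        wavelengths = c(400, 401, 402), seed = 1) {
  meta <- expand.grid(replicate_id = paste0("R", seq_len(reps)),
                      plot_id = paste0("P", seq_len(plots)),
                      season = paste0("S", seq_len(n_seasons)),
                      genotype_id = paste0("G", seq_len(n_geno)),
                      stringsAsFactors = FALSE)
  meta <- meta[, c("genotype_id", "season", "plot_id", "replicate_id")]
  meta$sample_id <- do.call(paste, c(meta, sep = "_"))
  n <- nrow(meta)
  set.seed(seed)
  refl <- matrix(runif(n * length(wavelengths), 0.1, 0.6), n)
  spectral_dataset(refl, wavelengths, meta)
}

# latent-factor regression data: X = scores %*% t(basis) (+ noise),
# y = scores %*% w (+ noise); the truth for NoC-recovery tests
make_latent_data <- function(n, p, k = 3, noise_x = 0, noise_y = 0, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * k), n, k)
  basis <- matrix(rnorm(p * k), p, k)
  w <- seq_len(k)
  X <- tcrossprod(scores, basis) + matrix(rnorm(n * p, 0, noise_x), n, p)
  y <- drop(scores %*% w) + rnorm(n, 0, noise_y)
  list(X = X, y = y, scores = scores, basis = basis, w = w)
}

# minimum-norm least squares fitted values: the independent PLSR oracle
pinv_fitted <- function(X, y, newdata = X) {
  Xc <- scale(X, scale = FALSE)
  beta <- MASS::ginv(Xc) %*% (y - mean(y))
  drop(scale(newdata, center = attr(Xc, "scaled:center"), scale = FALSE) %*%
         beta) + mean(y)
}
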
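make_season_tt <- function(values_by_season, genotypes) {
  seasons <- names(values_by_season)
  meta <- do.call(rbind, lapply(seasons, function(se) {
    data.frame(sample_id = paste(genotypes, se, sep = "_"),
               genotype_id = genotypes, season = se,
               plot_id = "P1", replicate_id = "R1")
  }))
  trait_table(meta, data.frame(tr = unlist(values_by_season, use.names = FALSE)))
}

test_that("coefficient of variation matches hand computation and scales", {
  tt <- make_season_tt(list(S1 = c(1, 3)), c("g1", "g2"))
  expect_equal(coefficient_of_variation(tt, "tr", "S1"),
               100 * sqrt(2) / 2, tolerance = 1e-10)  # 70.71
  tt2 <- make_season_tt(list(S1 = 5 * c(1, 3)), c("g1", "g2"))
  expect_equal(coefficient_of_variation(tt2, "tr", "S1"),
               coefficient_of_variation(tt, "tr", "S1"))
  tt3 <- make_season_tt(list(S1 = c(2, 2, 2)), paste0("g", 1:3))
  expect_equal(coefficient_of_variation(tt3, "tr", "S1"), 0)
  tt4 <- make_season_tt(list(S1 = c(-1, 1)), c("g1", "g2"))
  expect_error(coefficient_of_variation(tt4, "tr", "S1"), "zero mean")
})

test_that("between-season Spearman hits the rank extremes", {
  g <- paste0("g", 1:5)
  tt <- make_season_tt(list(S1 = 1:5, S2 = 2 * (1:5) + 3), g)
  expect_equal(between_season_spearman(tt, "tr", "S1", "S2"), 1)
  tt_rev <- make_season_tt(list(S1 = 1:5, S2 = 5:1), g)
  expect_equal(between_season_spearman(tt_rev, "tr", "S1", "S2"), -1)
  tt_small <- make_season_tt(list(S1 = 1:2, S2 = 2:1), c("g1", "g2"))
  expect_error(between_season_spearman(tt_small, "tr", "S1", "S2"),
               "fewer than 3")
})

test_that("genotype-dominated variation gives high cross-season rank stability", {
  ok <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n_genotypes = 30, n_seasons = 2,
                            plots_per_genotype = 1, reps_per_plot = 2,
                            wavelengths = seq(400, 2400, by = 100),
                            n_latent = 2, sigma2_G = 4, sigma2_GxE = 0.05,
                            sigma2_E = 0.05,
                            traits = list(tr = list(loadings = c(1, 0),
                                                    noise_sd = 0.1)))
    d <- generate_dataset(cfg, seed = 100 + s)
    rho <- between_season_spearman(d$traits, "tr", "S1", "S2")
    if (rho > 0.8) ok <- ok + 1
  }
  expect_equal(ok, 10)
})

test_that("cross-season spectral correlation behaves at its fixed points", {
  set.seed(1)
  g <- paste0("g", 1:20)
  w <- seq(500, 999, by = 1)
  meta <- do.call(rbind, lapply(c("S1", "S2"), function(se) {
    data.frame(sample_id = paste(g, se, sep = "_"), genotype_id = g,
               season = se, plot_id = "P1", replicate_id = "R1")
  }))
  base <- matrix(runif(20 * length(w), 0.2, 0.6), 20)
  # identical spectra across seasons -> 1; constant offset leaves it unchanged
  ds_same <- spectral_dataset(rbind(base, base), w, meta)
  expect_equal(cross_season_spectral_correlation(ds_same, c(500, 999),
                                                 "S1", "S2"), 1)
  ds_off <- spectral_dataset(rbind(base, base + 0.05), w, meta)
  expect_equal(cross_season_spectral_correlation(ds_off, c(500, 999),
                                                 "S1", "S2"), 1,
               tolerance = 1e-10)
  # independent white-noise spectra -> near zero
  noise <- matrix(runif(20 * length(w), 0.2, 0.6), 20)
  ds_null <- spectral_dataset(rbind(base, noise), w, meta)
  expect_lt(abs(cross_season_spectral_correlation(ds_null, c(500, 999),
                                                  "S1", "S2")), 0.1)
  expect_error(cross_season_spectral_correlation(ds_same, c(2000, 2100),
                                                 "S1", "S2"), "empty")
})

test_that("Mantel statistic and p behave at fixed points", {
  set.seed(2)
  M <- crossprod(matrix(rnorm(36), 6))
  res <- mantel_test(M, M, n_perm = 99, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  # r invariant to adding a constant to the off-diagonal entries of B
  B2 <- M + 0.7; diag(B2) <- diag(M)
  expect_equal(mantel_test(M, B2, n_perm = 9, seed = 1)$r, 1)
  expect_error(mantel_test(matrix(1:4, 2), M[1:2, 1:2]), "symmetric")
})

test_that("vectorised Mantel r equals a naive double-loop implementation", {
  set.seed(4)
  A <- crossprod(matrix(rnorm(25), 5))
  B <- crossprod(matrix(rnorm(25), 5))
  naive_r <- function(A, B) {
    av <- c(); bv <- c()
    for (i in 1:(nrow(A) - 1)) {
      for (j in (i + 1):ncol(A)) {
        av <- c(av, A[i, j]); bv <- c(bv, B[i, j])
      }
    }
    stats::cor(av, bv)
  }
  expect_equal(mantel_test(A, B, n_perm = 9, seed = 1)$r, naive_r(A, B))
})

test_that("exact Mantel p matches brute-force enumeration and vegan agrees on r", {
  set.seed(5)
  A <- crossprod(matrix(rnorm(16), 4))
  B <- crossprod(matrix(rnorm(16), 4))
  res <- mantel_test(A, B, exact = TRUE)
  # independent oracle: enumerate all 24 simultaneous row/col permutations
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    perms[[length(perms) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  r_perm <- vapply(perms, function(pp) cor(A[ut], B[pp, pp][ut]), numeric(1))
  expect_equal(res$p, mean(r_perm >= r_obs))
  expect_equal(res$r, r_obs)
  # cross-check the statistic against vegan on a larger instance
  A6 <- crossprod(matrix(rnorm(49), 7))
  B6 <- crossprod(matrix(rnorm(49), 7))
  vg <- vegan::mantel(A6, B6, permutations = 9)
  expect_equal(mantel_test(A6, B6, n_perm = 9, seed = 1)$r,
               unname(vg$statistic), tolerance = 1e-10)
})

test_that("descriptive statistics are deterministic given a seed", {
  cfg <- synthetic_config(n_genotypes = 10, n_seasons = 2,
                          plots_per_genotype = 1, reps_per_plot = 2,
                          wavelengths = seq(400, 2400, by = 100), n_latent = 2)
  d <- generate_dataset(cfg, seed = 3)
  s1 <- season_summary(d$spectra, d$traits, n_perm = 49, seed = 8)
  s2 <- season_summary(d$spectra, d$traits, n_perm = 49, seed = 8)
  expect_identical(s1$mantel, s2$mantel)
  expect_identical(s1$cv, s2$cv)
})
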
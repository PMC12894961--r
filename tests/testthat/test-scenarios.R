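test_that("metrics match hand computations", {
  expect_equal(r_squared(1:4, 1:4), 1)
  expect_equal(r_squared(c(1, 2, 3, 4), rep(2.5, 4)), 0)
  expect_equal(r_squared(c(1, 2, 3, 4), rep(2, 4)), -0.2)  # SS_res 6, SS_tot 5
  expect_error(r_squared(c(2, 2), c(1, 3)), "constant")

  expect_equal(rmse_percent(c(1, 3), c(2, 2)), 50)  # RMSE 1, mean 2
  expect_equal(rmse_percent(1:4, 1:4), 0)
  expect_equal(rmse_percent(10 * c(1, 3), 10 * c(2, 2)), 50)  # scale-invariant
  expect_error(rmse_percent(c(-1, 1), c(0, 0)), "zero mean")

  expect_equal(squared_pearson(1:3, 2 * (1:3) + 5), 1)
  expect_equal(squared_pearson(c(1, 2, 3), c(1, 3, 2)), 0.25)  # r = 0.5
  expect_error(squared_pearson(1:3, c(2, 2, 2)), "constant")
})

test_that("genotype-exclusive fold plans never split a genotype", {
  ds <- make_toy_ds(n_geno = 10, n_seasons = 1, plots = 2, reps = 3)
  plan <- build_fold_plan(ds$samples, "unseen_genotype", k_folds = 5,
                          reps = 3, seed = 4)
  expect_identical(audit_fold_plan(plan, ds$samples), TRUE)
  for (rep_folds in plan$repetitions) {
    for (fold in rep_folds) {
      g_val <- unique(ds$samples$genotype_id[fold$validation])
      g_cal <- unique(ds$samples$genotype_id[fold$calibration])
      expect_length(g_val, 2)           # 10 genotypes / 5 folds
      expect_length(fold$validation, 12) # 2 genotypes x 6 rows
      expect_length(intersect(g_val, g_cal), 0)
    }
    expect_equal(sort(unlist(lapply(rep_folds, `[[`, "validation"))),
                 seq_len(nrow(ds$samples)))
  }
})

test_that("k equal to the genotype count gives leave-one-genotype-out", {
  ds <- make_toy_ds(n_geno = 6, n_seasons = 1, plots = 1, reps = 2)
  plan <- build_fold_plan(ds$samples, "unseen_genotype", k_folds = 6,
                          reps = 1, seed = 1)
  for (fold in plan$repetitions[[1]]) {
    expect_length(unique(ds$samples$genotype_id[fold$validation]), 1)
  }
  expect_error(build_fold_plan(ds$samples, "unseen_genotype", k_folds = 7,
                               reps = 1), "exceeds the number of genotypes")
})

test_that("season holdout keeps zero test-season rows in calibration", {
  ds <- make_toy_ds(n_geno = 4, n_seasons = 3, plots = 1, reps = 2)
  plan <- build_fold_plan(ds$samples, "unseen_season",
                          train_seasons = c("S1", "S2"), test_season = "S3")
  expect_length(plan$repetitions, 1)
  fold <- plan$repetitions[[1]][[1]]
  expect_false(any(ds$samples$season[fold$calibration] == "S3"))
  expect_true(all(ds$samples$season[fold$validation] == "S3"))
  expect_error(build_fold_plan(ds$samples, "unseen_season",
                               train_seasons = "S1", test_season = "S9"),
               "absent")
})

test_that("the strict scenario excludes validation genotypes from training seasons", {
  ds <- make_toy_ds(n_geno = 8, n_seasons = 3, plots = 1, reps = 2)
  plan <- build_fold_plan(ds$samples, "unseen_genotype_unseen_season",
                          k_folds = 4, reps = 2, test_season = "S2", seed = 2)
  audit_fold_plan(plan, ds$samples)
  for (rep_folds in plan$repetitions) {
    for (fold in rep_folds) {
      expect_true(all(ds$samples$season[fold$validation] == "S2"))
      expect_false(any(ds$samples$season[fold$calibration] == "S2"))
      expect_length(intersect(ds$samples$genotype_id[fold$validation],
                              ds$samples$genotype_id[fold$calibration]), 0)
    }
  }
  # single-training-season variant behind the train_seasons argument
  plan1 <- build_fold_plan(ds$samples, "unseen_genotype_unseen_season",
                           k_folds = 4, reps = 1, train_seasons = "S1",
                           test_season = "S2", seed = 2)
  for (fold in plan1$repetitions[[1]]) {
    expect_true(all(ds$samples$season[fold$calibration] == "S1"))
  }
})

test_that("the leakage audit rejects corrupted plans", {
  ds <- make_toy_ds(n_geno = 6, n_seasons = 1, plots = 1, reps = 2)
  plan <- build_fold_plan(ds$samples, "unseen_genotype", k_folds = 3,
                          reps = 1, seed = 5)
  # leak one validation sample into the calibration side
  bad <- plan
  bad$repetitions[[1]][[1]]$calibration <-
    c(bad$repetitions[[1]][[1]]$calibration,
      bad$repetitions[[1]][[1]]$validation[1])
  expect_error(audit_fold_plan(bad, ds$samples), "leakage audit")
  # move a row of a validation genotype across (keep sets disjoint)
  bad2 <- plan
  vg <- ds$samples$genotype_id[bad2$repetitions[[1]][[1]]$validation[1]]
  row2 <- which(ds$samples$genotype_id == vg)[2]
  bad2$repetitions[[1]][[1]]$validation <-
    setdiff(bad2$repetitions[[1]][[1]]$validation, row2)
  bad2$repetitions[[1]][[2]]$calibration <-
    unique(c(bad2$repetitions[[1]][[2]]$calibration, row2))
  expect_error(audit_fold_plan(bad2, ds$samples), "leakage audit")
})

test_that("nested CV recovers a noiseless latent trait almost perfectly", {
  cfg <- synthetic_config(n_genotypes = 20, n_seasons = 1,
                          plots_per_genotype = 1, reps_per_plot = 3,
                          wavelengths = seq(400, 2400, by = 20), n_latent = 3,
                          traits = list(tr = list(loadings = c(1, 0.5, 0.25),
                                                  noise_sd = 0)),
                          sigma2_GxE = 0,  # zero noise: no trait-spectra decoupling
                          spectral_noise_sd = 0)
  d <- generate_dataset(cfg, seed = 10)
  res <- run_nested_cv(d$spectra, d$traits, "tr", scenario = "random",
                       k_folds = 5, reps = 2, noc_grid = 1:5, seed = 3)
  expect_equal(nrow(res$per_fold), 10)
  med <- res$summaries$median[res$summaries$metric == "r2"]
  expect_gte(med, 0.99)
})

test_that("a trait independent of the spectra scores near zero", {
  cfg <- synthetic_config(n_genotypes = 20, n_seasons = 1,
                          plots_per_genotype = 1, reps_per_plot = 3,
                          wavelengths = seq(400, 2400, by = 20), n_latent = 3,
                          traits = list(null_tr = list(loadings = c(0, 0, 0),
                                                       noise_sd = 1)))
  d <- generate_dataset(cfg, seed = 11)
  res <- run_nested_cv(d$spectra, d$traits, "null_tr", scenario = "random",
                       k_folds = 5, reps = 4, noc_grid = 1:4, seed = 5)
  med <- res$summaries$median[res$summaries$metric == "r2"]
  # no predictive signal: the median never rises meaningfully above zero
  # (small validation folds bias a null model's R^2 slightly negative)
  expect_lt(med, 0.05)
  expect_gt(med, -0.75)
})

test_that("evaluation results serialise to a recomputable CSV + JSON pair", {
  cfg <- synthetic_config(n_genotypes = 12, n_seasons = 1,
                          plots_per_genotype = 1, reps_per_plot = 2,
                          wavelengths = seq(400, 2400, by = 50), n_latent = 2,
                          traits = list(tr = list(loadings = c(1, 0.5),
                                                  noise_sd = 0.3)))
  d <- generate_dataset(cfg, seed = 12)
  res <- run_nested_cv(d$spectra, d$traits, "tr", scenario = "random",
                       k_folds = 3, reps = 2, noc_grid = 1:3, seed = 6)
  dir <- withr::local_tempdir()
  write_evaluation(res, file.path(dir, "folds.csv"),
                   file.path(dir, "summary.json"))
  back <- utils::read.csv(file.path(dir, "folds.csv"))
  expect_equal(nrow(back), nrow(res$per_fold))
  expect_equal(stats::median(back$r2),
               res$summaries$median[res$summaries$metric == "r2"])
})
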
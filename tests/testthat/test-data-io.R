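test_that("CSV loader parses wavelengths, aligns metadata, and reports problems", {
  ds <- make_toy_ds()
  tt <- trait_table(ds$samples,
                    data.frame(sla = seq_len(nrow(ds$reflectance))))
  tt$values$sla[2] <- NA
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "spectra.csv")
  trp <- file.path(dir, "traits.csv")
  mp <- file.path(dir, "meta.csv")
  write_dataset(ds, tt, sp, trp, mp)

  loaded <- load_dataset(sp, trp, mp)
  expect_equal(loaded$spectra$wavelengths, c(400, 401, 402))
  expect_identical(loaded$spectra$reflectance, ds$reflectance)
  expect_identical(loaded$spectra$samples, ds$samples)
  expect_equal(sum(is.na(loaded$traits$values$sla)), 1)
  expect_equal(nrow(loaded$traits$values), nrow(ds$reflectance))

  # metadata missing a sample -> error naming it
  meta_bad <- ds$samples[-1, ]
  mp2 <- file.path(dir, "meta_bad.csv")
  utils::write.csv(meta_bad, mp2, row.names = FALSE)
  expect_error(load_dataset(sp, trp, mp2), ds$samples$sample_id[1],
               fixed = TRUE)

  # duplicate sample_id -> hard error
  lines <- readLines(sp)
  writeLines(c(lines, lines[2]), file.path(dir, "dup.csv"))
  expect_error(load_dataset(file.path(dir, "dup.csv"), trp, mp),
               "duplicate sample_id")

  # non-monotone wavelength header -> hard error
  hdr <- strsplit(lines[1], ",")[[1]]
  writeLines(c(paste(hdr[c(1, 3, 2, 4)], collapse = ","), lines[-1]),
             file.path(dir, "nonmono.csv"))
  expect_error(load_dataset(file.path(dir, "nonmono.csv"), trp, mp),
               "strictly increasing")
})

test_that("out-of-range reflectance warns but loads", {
  ds <- make_toy_ds()
  expect_warning(
    spectral_dataset({r <- ds$reflectance; r[1, 1] <- 1.7; r},
                     ds$wavelengths, ds$samples),
    "outside")
})

test_that("wavelength subsetting follows the retained-grid rules", {
  n <- 4
  grid <- 400:2400
  meta <- data.frame(sample_id = paste0("s", 1:n), genotype_id = paste0("g", 1:n),
                     season = "S1", plot_id = "P1", replicate_id = "R1")
  ds <- spectral_dataset(matrix(0.5, n, length(grid)), grid, meta)
  expect_equal(length(ds$wavelengths), 2001)
  ds5 <- subsample_wavelengths(ds, 5)
  expect_equal(length(ds5$wavelengths), 401)
  expect_equal(ds5$wavelengths[1:3], c(400, 405, 410))
  expect_identical(subsample_wavelengths(ds, 1)$wavelengths, ds$wavelengths)
  expect_error(subsample_wavelengths(ds, 0), "positive integer")

  win <- restrict_wavelengths(ds, 1500, 2400)
  expect_equal(length(win$wavelengths), 901)
  expect_identical(restrict_wavelengths(ds, 400, 2400)$wavelengths,
                   ds$wavelengths)
  expect_error(restrict_wavelengths(ds, 3000, 3100), "no wavelengths")

  # small-grid stride arithmetic
  ds11 <- spectral_dataset(matrix(0.5, n, 11), 0:10, meta)
  expect_equal(subsample_wavelengths(ds11, 5)$wavelengths, c(0, 5, 10))
})

test_that("subsample and restrict commute when the boundary is on the kept grid", {
  ds <- make_toy_ds(wavelengths = seq(400, 500, by = 1))
  a <- restrict_wavelengths(subsample_wavelengths(ds, 5), 420, 480)
  b <- subsample_wavelengths(restrict_wavelengths(ds, 420, 480), 5)
  expect_identical(a$wavelengths, b$wavelengths)
  expect_identical(a$reflectance, b$reflectance)
})

test_that("aggregation averages replicates and keeps sentinel metadata", {
  ds <- make_toy_ds(n_geno = 1, plots = 2, reps = 3, wavelengths = c(500, 600))
  ds$reflectance[, 1] <- (1:6) / 10  # P1 holds rows 1-3, P2 rows 4-6
  tt <- trait_table(ds$samples, data.frame(tr = c(1, NA, 3, 4, 5, 6)))

  g <- aggregate_samples(ds, tt, "genotype")
  expect_equal(nrow(g$spectra$reflectance), 1)
  expect_equal(unname(g$spectra$reflectance[1, 1]), 0.35)
  expect_equal(g$spectra$samples$plot_id, "*")
  expect_equal(g$spectra$samples$replicate_id, "*")

  p <- aggregate_samples(ds, tt, "plot")
  expect_equal(unname(p$spectra$reflectance[, 1]), c(0.2, 0.5))
  expect_equal(p$spectra$samples$replicate_id, c("*", "*"))
  # missing-aware trait mean within plot 1: mean(1, 3) = 2
  expect_equal(p$traits$values$tr, c(2, 5))

  raw <- aggregate_samples(ds, tt, "raw")
  expect_identical(raw$spectra$reflectance, ds$reflectance)
})

test_that("row counts equal the number of distinct grouping keys", {
  ds <- make_toy_ds(n_geno = 3, n_seasons = 2, plots = 2, reps = 3)
  tt <- trait_table(ds$samples, data.frame(tr = rnorm(nrow(ds$reflectance))))
  expect_equal(nrow(aggregate_samples(ds, tt, "plot")$spectra$reflectance),
               3 * 2 * 2)
  expect_equal(nrow(aggregate_samples(ds, tt, "genotype")$spectra$reflectance),
               3 * 2)
})

test_that("genotype aggregation equals plot-then-average only in the balanced case", {
  ds <- make_toy_ds(n_geno = 1, plots = 2, reps = 3, wavelengths = c(500, 600))
  # balanced, no missing: the two routes agree
  tt <- trait_table(ds$samples, data.frame(tr = c(1, 2, 3, 4, 5, 6)))
  direct <- aggregate_samples(ds, tt, "genotype")$traits$values$tr
  via_plot <- mean(aggregate_samples(ds, tt, "plot")$traits$values$tr)
  expect_equal(direct, via_plot)
  # unbalanced missingness: a counterexample
  tt2 <- trait_table(ds$samples, data.frame(tr = c(1, NA, NA, 4, 5, 6)))
  direct2 <- aggregate_samples(ds, tt2, "genotype")$traits$values$tr  # mean(1,4,5,6)=4
  via_plot2 <- mean(aggregate_samples(ds, tt2, "plot")$traits$values$tr)  # mean(1,5)=3
  expect_equal(direct2, 4)
  expect_equal(via_plot2, 3)
  expect_false(isTRUE(all.equal(direct2, via_plot2)))
})

test_that("per-season centring/scaling gives mean 0, sd 1 within each season", {
  ds <- make_toy_ds(n_geno = 4, n_seasons = 2, plots = 1, reps = 3, seed = 5)
  set.seed(5)
  y <- rnorm(nrow(ds$reflectance), 10)
  y[ds$samples$season == "S2"] <- y[ds$samples$season == "S2"] + 10  # shift
  tt <- trait_table(ds$samples, data.frame(tr = y))
  cs <- center_scale_by_season(tt, "tr")
  for (se in c("S1", "S2")) {
    v <- cs$table$values$tr[ds$samples$season == se]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  expect_equal(sort(cs$params$season), c("S1", "S2"))

  # two seasons with identical shapes shifted by +10: identical after transform
  y2 <- rep(seq_len(6), 2)
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     genotype_id = paste0("g", rep(1:6, 2)),
                     season = rep(c("A", "B"), each = 6),
                     plot_id = "P1", replicate_id = "R1")
  tt2 <- trait_table(meta, data.frame(tr = c(y2[1:6], y2[7:12] + 10)))
  cs2 <- center_scale_by_season(tt2, "tr")
  expect_equal(cs2$table$values$tr[1:6], cs2$table$values$tr[7:12])

  # hand-derived: season with values [1, 3] -> (x - 2)/sqrt(2)
  meta3 <- meta[1:2, ]
  tt3 <- trait_table(meta3, data.frame(tr = c(1, 3)))
  cs3 <- center_scale_by_season(tt3, "tr")
  expect_equal(cs3$table$values$tr, c(-1, 1) / sqrt(2), tolerance = 1e-10)

  # zero within-season SD errors
  tt4 <- trait_table(meta3, data.frame(tr = c(2, 2)))
  expect_error(center_scale_by_season(tt4, "tr"), "zero within-season")
})

test_that("single-season scaling equals the global z-score", {
  meta <- data.frame(sample_id = paste0("s", 1:5), genotype_id = paste0("g", 1:5),
                     season = "S1", plot_id = "P1", replicate_id = "R1")
  y <- c(3, 1, 4, 1, 5)
  tt <- trait_table(meta, data.frame(tr = y))
  cs <- center_scale_by_season(tt, "tr")
  expect_equal(cs$table$values$tr, as.numeric(scale(y)), tolerance = 1e-12)
})
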
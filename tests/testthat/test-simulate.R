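quiet_cfg <- function(seed, ...) {
  generator_config(seed = seed, noise_cv = 0, baseline_level = 0,
                   ppm_drift_range = c(0, 0), lockmass_mz = 0,
                   group_effect_sd = 0, ...)
}

test_that("templates respect overlap, peak budget and determinism", {
  t0 <- make_templates(2, n_peaks = 20, overlap_fraction = 0, seed = 1)
  expect_length(intersect(t0[[1]]$peaks$mz, t0[[2]]$peaks$mz), 0)

  t1 <- make_templates(3, n_peaks = 15, overlap_fraction = 1, seed = 2)
  expect_equal(t1[[1]]$peaks$mz, t1[[2]]$peaks$mz)
  expect_equal(t1[[2]]$peaks$mz, t1[[3]]$peaks$mz)

  ta <- make_templates(2, n_peaks = 10, seed = 3)
  tb <- make_templates(2, n_peaks = 10, seed = 3)
  expect_identical(ta, tb)

  for (tp in t0) {
    expect_equal(sum(tp$peaks$mean_rel_intensity), 1)
    expect_true(all(tp$peaks$mz > 600 & tp$peaks$mz < 1000))
  }
  expect_error(
    make_templates(2, n_peaks = 5000, overlap_fraction = 0, seed = 1),
    "resolvable"
  )
})

test_that("a pure noiseless spectrum is proportional to its template", {
  tmpl <- make_templates(2, n_peaks = 10, overlap_fraction = 0, seed = 4,
                         cv = 0)
  cfg <- quiet_cfg(1)
  s <- withr::with_seed(1, simulate_spectrum(c(1, 0), tmpl, cfg))
  expect_equal(s$mz, tmpl[[1]]$peaks$mz)
  expect_equal(s$intensity / sum(s$intensity),
               tmpl[[1]]$peaks$mean_rel_intensity, tolerance = 1e-12)
})

test_that("mean mixture spectra converge to the convex combination", {
  tmpl <- make_templates(2, n_peaks = 10, overlap_fraction = 0.5, seed = 5)
  cfg <- generator_config(seed = 1, baseline_level = 0,
                          ppm_drift_range = c(0, 0), lockmass_mz = 0,
                          group_effect_sd = 0)
  mzs <- sort(unique(c(tmpl[[1]]$peaks$mz, tmpl[[2]]$peaks$mz)))
  expected <- vapply(mzs, function(m) {
    0.5 * sum(tmpl[[1]]$peaks$mean_rel_intensity[tmpl[[1]]$peaks$mz == m]) +
      0.5 * sum(tmpl[[2]]$peaks$mean_rel_intensity[tmpl[[2]]$peaks$mz == m])
  }, numeric(1))
  draws <- withr::with_seed(6, {
    replicate(500, {
      s <- simulate_spectrum(c(0.5, 0.5), tmpl, cfg)
      v <- s$intensity[match(mzs, s$mz)]
      v / sum(v)
    })
  })
  expect_equal(rowMeans(draws), expected, tolerance = 0.01)
})

test_that("applied mass drift is recovered by lock-mass correction", {
  tmpl <- make_templates(1, n_peaks = 10, seed = 7, cv = 0)
  cfg <- generator_config(seed = 1, noise_cv = 0, baseline_level = 0,
                          group_effect_sd = 0)
  s <- withr::with_seed(2, {
    simulate_spectrum(1, tmpl, cfg, ppm_drift = 20)
  })
  lc <- lockmass_correct(s)
  expect_true(lc$corrected)
  expect_equal(lc$applied_ppm, -20, tolerance = 0.01)
})

test_that("cohorts have the designed shape and are seed-reproducible", {
  tmpl <- make_templates(2, n_peaks = 10, seed = 8,
                         names = c("tumor", "soft"))
  cfg <- generator_config(seed = 9, n_per_class = c(8, 7), n_groups = 5)
  coh <- simulate_cohort(cfg, tmpl)
  expect_length(coh$series, 15)
  expect_equal(unname(table(coh$truth$class_label)[c("tumor", "soft")]),
               c(8, 7), ignore_attr = TRUE)
  expect_equal(dplyr::n_distinct(coh$truth$group_id), 5)
  # burn-shaped TIC: interior maximum
  tics <- coh$series[[1]]$tic
  expect_equal(length(tics), 8)
  expect_true(which.max(tics) %in% 3:6)

  coh2 <- simulate_cohort(cfg, tmpl)
  expect_identical(coh$truth, coh2$truth)
  expect_equal(coh$series[[3]]$peaks[[2]]$intensity,
               coh2$series[[3]]$peaks[[2]]$intensity, tolerance = 1e-12)
})

test_that("without group effects, class mean profiles agree across groups", {
  tmpl <- make_templates(1, n_peaks = 10, seed = 10, names = "a")
  cfg <- generator_config(seed = 11, n_per_class = 40, n_groups = 2,
                          group_effect_sd = 0, noise_cv = 0.05,
                          baseline_level = 0, ppm_drift_range = c(0, 0))
  coh <- simulate_cohort(cfg, tmpl)
  fm <- preprocess_cohort(coh$series, reims_cells_config())
  fm$group_id <- coh$truth$group_id
  v <- fm_values(fm)
  m1 <- colMeans(v[fm$group_id == "g01", ])
  m2 <- colMeans(v[fm$group_id == "g02", ])
  expect_lt(max(abs(m1 - m2)), 0.01)
})

test_that("the dilution design reproduces the full assay shape", {
  tmpl <- make_templates(2, n_peaks = 10, seed = 12,
                         names = c("tumor", "myoblast"))
  cfg <- generator_config(seed = 13)
  dil <- simulate_dilution_series(cfg, tmpl)
  expect_length(dil$series, 336)
  expect_equal(
    unname(table(dil$truth$tumor_fraction)[c("0", "0.1", "0.25", "0.5", "1")]),
    c(93, 49, 57, 44, 93), ignore_attr = TRUE
  )
  # pure points span five replicates, mixtures three
  pure <- dil$truth[dil$truth$tumor_fraction %in% c(0, 1), ]
  mixd <- dil$truth[!dil$truth$tumor_fraction %in% c(0, 1), ]
  expect_equal(dplyr::n_distinct(pure$group_id), 5)
  expect_equal(dplyr::n_distinct(mixd$group_id), 3)
  expect_equal(unique(dil$truth$class_label[dil$truth$tumor_fraction == 0.1]),
               "tumor")
  expect_equal(unique(dil$truth$class_label[dil$truth$tumor_fraction == 0]),
               "muscle")
  # stored composition matches the design
  m <- series_meta(dil$series[[100]])
  expect_equal(sum(m$composition), 1)

  empty <- simulate_dilution_series(cfg, tmpl, fractions = c(1, 0),
                                    n_per_point = c(0, 0))
  expect_length(empty$series, 0)
})

test_that("injected aberrant spectra are flagged by the outlier rule", {
  tmpl <- make_templates(1, n_peaks = 20, seed = 14, names = "a")
  cfg <- generator_config(seed = 15)
  n <- 500
  truth <- withr::with_seed(17, stats::runif(n) < 0.01)
  prof <- withr::with_seed(16, {
    lapply(seq_len(n), function(i) {
      s <- simulate_spectrum(1, tmpl, cfg, outlier = truth[[i]])
      normalize_tic(bin_spectrum(s, reims_cells_config()))
    })
  })
  vals <- do.call(rbind, lapply(prof, as.numeric))
  fm <- feature_matrix(
    vals, attr(prof[[1]], "edges"),
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                   class_label = "a")
  )
  mask <- flag_outliers(fm, k = 5)
  expect_gt(sum(truth), 2)
  expect_gte(sum(mask & truth) / sum(truth), 0.95)
  expect_equal(sum(mask & !truth), 0)
})

test_that("simulated MSI grids follow the region map deterministically", {
  tmpl <- make_templates(2, n_peaks = 10, overlap_fraction = 0, seed = 16,
                         names = c("muscle", "tumor"))
  map <- tibble::tibble(
    x = rep(1:10, 10), y = rep(1:10, each = 10),
    label = rep(c("muscle", "tumor"), each = 50)
  )
  cfg <- generator_config(seed = 17)
  grid <- simulate_msi_grid(map, tmpl, cfg)
  expect_equal(nrow(grid), 100)
  grid2 <- simulate_msi_grid(map, tmpl, cfg)
  expect_equal(grid$peaks[[5]]$intensity, grid2$peaks[[5]]$intensity,
               tolerance = 1e-12)
  expect_error(
    simulate_msi_grid(dplyr::mutate(map, label = "nerve"), tmpl, cfg),
    "nerve"
  )
})

test_that("separable MSI regions are segmented perfectly", {
  skip_if_not_installed("mclust")
  tmpl <- make_templates(2, n_peaks = 10, overlap_fraction = 0, seed = 18,
                         names = c("muscle", "tumor"), cv = 0.05)
  map <- tibble::tibble(
    x = rep(1:10, 10), y = rep(1:10, each = 10),
    label = rep(c("muscle", "tumor"), each = 50)
  )
  cfg <- generator_config(seed = 19, noise_cv = 0.05)
  grid <- simulate_msi_grid(map, tmpl, cfg)
  seg <- kmeans_segment(grid, k = 2, seed = 20)
  expect_equal(mclust::adjustedRandIndex(seg$labels$cluster, map$label), 1)
})
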
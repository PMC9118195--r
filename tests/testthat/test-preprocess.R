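make_series <- function(tics) {
  # one peak per scan whose intensity equals the desired TIC
  specs <- lapply(seq_along(tics), function(i) {
    spectrum(700, tics[[i]], scan_time = i)
  })
  scan_series(specs, sample_meta("s1"))
}

test_that("burn-scan selection picks the TIC maximum or the peak top", {
  s <- make_series(c(1, 10, 9, 2))
  one <- select_burn_scans(s, preprocess_config(scan_mode = "one_per_spot"))
  expect_length(one, 1)
  expect_equal(tic(one[[1]]), 10)

  top <- select_burn_scans(s, preprocess_config(scan_mode = "top_of_peak"))
  expect_length(top, 2)
  expect_equal(vapply(top, tic, numeric(1)), c(10, 9))

  # threshold block must be contiguous and contain the maximum
  s2 <- make_series(c(9, 1, 10, 2))
  top2 <- select_burn_scans(s2, preprocess_config(scan_mode = "top_of_peak"))
  expect_equal(vapply(top2, tic, numeric(1)), 10)

  single <- make_series(5)
  expect_equal(tic(select_burn_scans(single, preprocess_config())[[1]]), 5)
  expect_error(select_burn_scans(make_series(c(0, 0)), preprocess_config()),
               "No signal")
})

test_that("lock-mass correction inverts a known ppm shift", {
  base <- spectrum(c(554.2615, 700.1, 899.9), c(50, 100, 20))
  for (shift in c(-50, -20, 5, 20, 50)) {
    drifted <- spectrum(base$mz * (1 + shift / 1e6), base$intensity)
    lc <- lockmass_correct(drifted, 554.2615, 0.25)
    expect_true(lc$corrected)
    expect_equal(lc$applied_ppm, -shift, tolerance = 0.01 / max(1, abs(shift)))
    expect_true(all(abs(lc$spectrum$mz - base$mz) < 1e-3))
    expect_equal(lc$spectrum$mz[[1]], 554.2615, tolerance = 1e-9)
  }
})

test_that("lock-mass correction is the identity when already calibrated", {
  base <- spectrum(c(554.2615, 700.1), c(50, 100))
  lc <- lockmass_correct(base)
  expect_equal(lc$applied_ppm, 0)
  expect_equal(lc$spectrum$mz, base$mz)
})

test_that("missing lock-mass peak leaves the spectrum flagged, unchanged", {
  s <- spectrum(c(700.1, 800.2), c(1, 2))
  expect_warning(lc <- lockmass_correct(s), "uncorrected")
  expect_false(lc$corrected)
  expect_equal(lc$spectrum$mz, s$mz)
})

test_that("binning assigns each peak to one half-open bin", {
  cfg <- preprocess_config(bin_width = 0.1, mass_range = c(100, 101))
  b <- bin_spectrum(spectrum(c(100.05, 100.09), c(7, 3)), cfg)
  expect_length(b, 10)
  expect_equal(unname(b[[1]]), 10)
  expect_equal(sum(b), 10)

  empty <- bin_spectrum(spectrum(numeric(), numeric()), cfg)
  expect_true(all(empty == 0))
})

test_that("binning conserves in-range intensity exactly", {
  cfg <- preprocess_config(bin_width = 0.1, mass_range = c(100, 1500))
  withr::with_seed(7, {
    mz <- runif(1000, 50, 1600)
    ints <- rexp(1000)
  })
  s <- spectrum(mz, ints)
  b <- bin_spectrum(s, cfg)
  in_range <- s$mz >= 100 & s$mz < 1500
  expect_identical(sum(b), sum(s$intensity[in_range]))
})

test_that("exclusion windows zero exactly the intersecting bins", {
  cfg <- preprocess_config(bin_width = 0.1, mass_range = c(100, 1500))
  s <- spectrum(c(553.85, 554.05, 557.95, 596.5, 1110.0, 1136.0, 700.0),
                rep(1, 7))
  b <- bin_spectrum(s, cfg)
  masked <- apply_exclusions(b, cfg$exclusion_windows)
  edges <- attr(masked, "edges")
  val_at <- function(x, e) unname(x[[which.min(abs(edges - e))]])
  expect_equal(val_at(masked, 553.8), 1)  # below the window: untouched
  expect_equal(val_at(masked, 554.0), 0)  # inside 554-558
  expect_equal(val_at(masked, 557.9), 0)
  expect_equal(val_at(masked, 596.5), 0)  # inside 594-597
  expect_equal(val_at(masked, 1110.0), 0) # inside 1109-1112
  expect_equal(val_at(masked, 1136.0), 0) # inside 1131-1137
  expect_equal(val_at(masked, 700.0), 1)  # far away: untouched
  # the zeroed set is exactly the bins intersecting the four windows
  zeroed <- edges[b > 0 & masked == 0]
  wins <- cfg$exclusion_windows
  inside <- vapply(zeroed, function(e) {
    any(vapply(wins, function(w) e <= w[2] && e + 0.1 > w[1], logical(1)))
  }, logical(1))
  expect_true(all(inside))
})

test_that("background subtraction removes the 5th-percentile baseline", {
  b <- binned_vector(c(10, 10, 110), c(100, 100.1, 100.2))
  out <- background_subtract(b)
  # quantile(c(10,10,110), .05) == 10 -> (0, 0, 100)
  expect_equal(unname(as.numeric(out)), c(0, 0, 100))
  expect_equal(attr(out, "baseline"), 10)

  zero <- binned_vector(c(0, 0, 0), c(100, 100.1, 100.2))
  expect_equal(as.numeric(background_subtract(zero)), c(0, 0, 0))
})

test_that("background subtraction cancels a constant offset on non-zero bins", {
  withr::with_seed(3, v <- c(rexp(20) + 1, 0, 0))
  b <- binned_vector(v, seq(100, 102.1, by = 0.1))
  shifted <- binned_vector(v + (v > 0) * 2.5, seq(100, 102.1, by = 0.1))
  expect_equal(as.numeric(background_subtract(shifted)),
               as.numeric(background_subtract(b)), tolerance = 1e-9)
})

test_that("TIC normalization yields a unit-sum vector and is idempotent", {
  b <- binned_vector(c(2, 3, 5), c(100, 100.1, 100.2))
  n1 <- normalize_tic(b)
  expect_equal(unname(as.numeric(n1)), c(0.2, 0.3, 0.5))
  expect_equal(sum(n1), 1, tolerance = 1e-12)
  expect_true(attr(n1, "normalized"))
  expect_equal(as.numeric(normalize_tic(n1)), as.numeric(n1))
  expect_error(normalize_tic(binned_vector(c(0, 0), c(100, 100.1))), "zero")
})

test_that("outlier flagging finds a grossly displaced spectrum and only it", {
  p <- disjoint_profiles()
  withr::with_seed(11, {
    base <- matrix(rep(p$a, each = 50), nrow = 50) +
      matrix(rnorm(500, sd = 0.003), nrow = 50)
    base <- pmax(base, 0)
  })
  # estimate the within-class distance scale, then displace one sample far
  centre <- colMeans(base)
  d <- sqrt(rowSums(sweep(base, 2, centre)^2))
  displaced <- p$a + 40 * mean(d) * c(1, -1, 1, 0, 0, 0, 1, 0, 0, 0) / sqrt(4)
  vals <- rbind(base, pmax(displaced, 0))
  vals <- vals / rowSums(vals)
  fm <- feature_matrix(
    vals, p$edges,
    tibble::tibble(sample_id = sprintf("s%02d", 1:51),
                   class_label = "A")
  )
  mask <- flag_outliers(fm, k = 5)
  expect_true(mask[[51]])
  expect_false(any(mask[1:50]))
  # verify against a direct distance computation
  v <- fm_values(fm)
  ctr <- colMeans(v[1:51, ])
  dd <- sqrt(rowSums(sweep(v, 2, ctr)^2))
  cls_d <- dd
  expect_identical(unname(mask), unname(cls_d > mean(cls_d) + 5 * sd(cls_d)))
  # the 25-SD rule flags nothing on clean Gaussian data
  expect_false(any(flag_outliers(fm[1:50, ], k = 25)))
})

test_that("classes with fewer than three members are never flagged", {
  p <- disjoint_profiles()
  fm <- feature_matrix(
    rbind(p$a, p$a * 100), p$edges,
    tibble::tibble(sample_id = c("a", "b"), class_label = "A")
  )
  expect_message(mask <- flag_outliers(fm, k = 5), "not applied")
  expect_false(any(mask))
})

test_that("the full chain yields a normalized vector with zeroed exclusions", {
  cfg <- preprocess_config()
  withr::with_seed(5, {
    mz <- c(554.2615, runif(50, 100, 1490))
    ints <- c(500, rexp(50) * 100)
  })
  specs <- lapply(1:3, function(i) {
    spectrum(mz * (1 + 15 / 1e6), ints * c(0.5, 1, 0.6)[i], scan_time = i)
  })
  out <- preprocess_series(scan_series(specs, sample_meta("s1")), cfg)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_true(attr(out, "normalized"))
  expect_equal(attr(out, "applied_ppm"), -15, tolerance = 0.01)
  edges <- attr(out, "edges")
  in_excl <- edges <= 558 & edges + 0.1 > 554
  expect_true(all(out[in_excl] == 0))
})
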
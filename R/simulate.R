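#' Synthetic-data generator configuration
#'
#' Fixes every stochastic ingredient of the synthetic spectra: noise
#' model and level, per-group (patient / biological replicate)
#' multiplicative effects, mass-axis drift, baseline contamination,
#' aberrant-spectrum injection, and the mandatory seed.
#'
#' Defaults describe a well-behaved benchtop acquisition: multiplicative
#' Gaussian peak noise with 15% coefficient of variation, log-normal
#' per-group per-peak effects with log-SD 0.1, uniform mass drift within
#' +/-20 ppm (removed again by lock-mass correction), a low diffuse
#' baseline, and no aberrant spectra unless requested.
#'
#' @param seed Integer seed; required, there is no silent nondeterminism.
#' @param mass_range Mass range of generated peaks (Th).
#' @param n_per_class Samples per class for cohort generation.
#' @param n_groups Number of patients / biological replicates.
#' @param group_effect_sd Log-scale SD of the multiplicative per-group
#'   per-peak effects.
#' @param noise_model `"gaussian_cv"` (multiplicative Gaussian, per-peak
#'   CV from the template) or `"poisson_counts"`.
#' @param noise_cv Default per-peak coefficient of variation.
#' @param baseline_level Baseline intensity as a fraction of the total
#'   ion current, spread over `n_baseline_peaks` random positions.
#' @param n_baseline_peaks Number of baseline positions per spectrum.
#' @param ppm_drift_range Uniform range of the per-spectrum mass drift
#'   (ppm).
#' @param outlier_rate Probability that a sample is aberrant.
#' @param outlier_magnitude Contaminant-to-signal total-intensity ratio
#'   of aberrant spectra (contaminant peaks at random m/z).
#' @param total_counts Expected total ion current of one full-intensity
#'   scan (arbitrary counts).
#' @param lockmass_mz m/z of the continuously infused lock-mass ion added
#'   to every scan (0 disables it).
#' @param lockmass_frac Lock-mass peak intensity relative to the total
#'   ion current.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             mass_range = c(600, 1000),
                             n_per_class = 50,
                             n_groups = 5,
                             group_effect_sd = 0.1,
                             noise_model = c("gaussian_cv", "poisson_counts"),
                             noise_cv = 0.15,
                             baseline_level = 0.02,
                             n_baseline_peaks = 50,
                             ppm_drift_range = c(-20, 20),
                             outlier_rate = 0,
                             outlier_magnitude = 10,
                             total_counts = 1e5,
                             lockmass_mz = 554.2615,
                             lockmass_frac = 0.05) {
  if (missing(seed)) abort("`seed` is mandatory for the generator.")
  noise_model <- match.arg(noise_model)
  stopifnot(group_effect_sd >= 0, noise_cv >= 0, baseline_level >= 0,
            outlier_rate >= 0, outlier_rate <= 1, outlier_magnitude >= 0,
            total_counts > 0)
  structure(
    list(
      seed = as.integer(seed), mass_range = as.numeric(mass_range),
      n_per_class = n_per_class, n_groups = n_groups,
      group_effect_sd = group_effect_sd, noise_model = noise_model,
      noise_cv = noise_cv, baseline_level = baseline_level,
      n_baseline_peaks = n_baseline_peaks,
      ppm_drift_range = as.numeric(ppm_drift_range),
      outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
      total_counts = total_counts, lockmass_mz = lockmass_mz,
      lockmass_frac = lockmass_frac
    ),
    class = "generator_config"
  )
}

#' Generative peak templates for cell or tissue classes
#'
#' Each class receives `n_peaks` peaks on the 0.1 Th bin-centre grid of
#' the mass range: a fraction of positions is shared across all classes
#' (with independently drawn intensities), the rest are class-exclusive.
#' Relative intensities are exponential draws normalized to sum to one.
#' Deterministic for a given seed.
#'
#' @param n_classes Number of classes.
#' @param n_peaks Peaks per class.
#' @param overlap_fraction Fraction of peak positions shared by all
#'   classes, in `[0, 1]`.
#' @param seed Integer seed.
#' @param mass_range Mass range (Th).
#' @param names Class names (default `class1`, `class2`, ...).
#' @param cv Per-peak coefficient of variation stored in the template.
#' @param ionization_efficiency Per-class efficiency scalars (default 1).
#' @return A list of `class_template`s: each has `name`, `peaks` (tibble
#'   `mz`, `mean_rel_intensity`, `cv`) and `ionization_efficiency`.
#' @export
make_templates <- function(n_classes, n_peaks = 30, overlap_fraction = 0.25,
                           seed = 1, mass_range = c(600, 1000),
                           names = NULL, cv = 0.15,
                           ionization_efficiency = rep(1, n_classes)) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must be in [0, 1].")
  }
  centres <- seq(mass_range[[1]] + 0.05, mass_range[[2]] - 0.05, by = 0.1)
  n_shared <- round(overlap_fraction * n_peaks)
  n_excl <- n_peaks - n_shared
  if (n_shared + n_classes * n_excl > length(centres)) {
    abort("More peaks requested than resolvable 0.1 Th bins in the range.")
  }
  names <- names %||% sprintf("class%d", seq_len(n_classes))
  stopifnot(length(names) == n_classes,
            length(ionization_efficiency) == n_classes)
  withr::with_seed(seed, {
    pool <- sample(centres)
    shared_mz <- sort(pool[seq_len(n_shared)])
    if (n_shared) pool <- pool[-seq_len(n_shared)]
    stats::setNames(lapply(seq_len(n_classes), function(c) {
      excl_mz <- if (n_excl) sort(pool[((c - 1) * n_excl + 1):(c * n_excl)])
                 else numeric()
      mz <- c(shared_mz, excl_mz)
      rel <- stats::rexp(length(mz))
      structure(
        list(
          name = names[[c]],
          peaks = tibble(
            mz = mz, mean_rel_intensity = rel / sum(rel),
            cv = rep(cv, length(mz))
          ),
          ionization_efficiency = ionization_efficiency[[c]]
        ),
        class = "class_template"
      )
    }), names)
  })
}

#' @export
print.class_template <- function(x, ...) {
  cat(sprintf("<class_template '%s': %d peaks, eta = %g>\n",
              x$name, nrow(x$peaks), x$ionization_efficiency))
  invisible(x)
}

#' Simulate one spectrum from a mixture of class templates
#'
#' The expected peak pattern is the ionization-efficiency-weighted convex
#' combination of the class templates, renormalized so the composition
#' weights are cell-count fractions (as in pellet preparation), not
#' signal fractions.  Optional per-group effects multiply per-peak means;
#' noise follows the configured model; a diffuse baseline, the lock-mass
#' ion and a ppm mass drift are added.  Draws from the current RNG
#' stream: callers (the cohort generators) fix the seed.
#'
#' @param weights Named non-negative weights over `templates`, summing
#'   to 1.
#' @param templates List of templates from [make_templates()].
#' @param config A [generator_config()].
#' @param group_effect Optional list (one numeric vector per template) of
#'   per-peak multiplicative effects.
#' @param scale Intensity scale of this scan relative to
#'   `config$total_counts` (used for burn-shaped TIC profiles).
#' @param ppm_drift Mass drift in ppm; `NULL` draws one from
#'   `config$ppm_drift_range`.
#' @param outlier Force aberrant-spectrum distortion on (`TRUE`) or off
#'   (`FALSE`); `NULL` draws from `config$outlier_rate`.
#' @param scan_time Scan time recorded on the spectrum (s).
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(weights, templates, config,
                              group_effect = NULL, scale = 1,
                              ppm_drift = NULL, outlier = NULL,
                              scan_time = NA_real_) {
  stopifnot(length(weights) == length(templates), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) abort("`weights` must sum to 1.")
  eta <- vapply(templates, `[[`, numeric(1), "ionization_efficiency")
  denom <- sum(weights * eta)
  contrib <- lapply(seq_along(templates), function(c) {
    pk <- templates[[c]]$peaks
    g <- if (is.null(group_effect)) 1 else group_effect[[c]]
    tibble(
      mz = pk$mz,
      mean = weights[[c]] * eta[[c]] * pk$mean_rel_intensity * g / denom,
      cv = pk$cv
    )
  })
  all_pk <- dplyr::bind_rows(contrib)
  agg <- dplyr::summarise(
    dplyr::group_by(all_pk, .data$mz),
    mean = sum(.data$mean), cv = max(.data$cv), .groups = "drop"
  )
  mean_int <- agg$mean * config$total_counts * scale
  ints <- switch(config$noise_model,
    gaussian_cv = pmax(0, mean_int * (1 + stats::rnorm(length(mean_int)) * agg$cv)),
    poisson_counts = stats::rpois(length(mean_int), mean_int)
  )
  mz <- agg$mz
  if (is.null(outlier)) outlier <- stats::runif(1) < config$outlier_rate
  if (outlier) {
    # aberrant spectrum (contamination burn / arcing): contaminant peaks
    # at random positions swamp the signal, `outlier_magnitude` times the
    # clean peak intensity in total
    n_cont <- max(length(ints), 10L)
    c_mz <- stats::runif(n_cont, config$mass_range[[1]],
                         config$mass_range[[2]])
    c_int <- stats::rexp(n_cont)
    c_int <- c_int / sum(c_int) * config$outlier_magnitude * sum(ints)
    mz <- c(mz, c_mz)
    ints <- c(ints, c_int)
  }
  if (config$baseline_level > 0 && config$n_baseline_peaks > 0) {
    b_mz <- stats::runif(config$n_baseline_peaks,
                         config$mass_range[[1]], config$mass_range[[2]])
    b_int <- stats::rexp(config$n_baseline_peaks) *
      config$baseline_level * config$total_counts * scale /
      config$n_baseline_peaks
    mz <- c(mz, b_mz)
    ints <- c(ints, b_int)
  }
  if (config$lockmass_mz > 0) {
    lock_int <- config$lockmass_frac * config$total_counts * scale *
      max(0, 1 + stats::rnorm(1) * config$noise_cv)
    mz <- c(mz, config$lockmass_mz)
    ints <- c(ints, lock_int)
  }
  if (is.null(ppm_drift)) {
    ppm_drift <- stats::runif(1, config$ppm_drift_range[[1]],
                              config$ppm_drift_range[[2]])
  }
  keep <- ints > 0
  spectrum(mz[keep] * (1 + ppm_drift / 1e6), ints[keep],
           scan_time = scan_time)
}

draw_group_effects <- function(templates, config, group_ids) {
  stats::setNames(lapply(group_ids, function(g) {
    lapply(templates, function(tp) {
      exp(stats::rnorm(nrow(tp$peaks)) * config$group_effect_sd)
    })
  }), group_ids)
}

# Burn-shaped TIC profile: triangular rise, plateau at the top, fall.
BURN_SHAPE <- c(0.05, 0.3, 0.7, 1.0, 1.0, 0.7, 0.3, 0.05)

simulate_burn_series <- function(weights, templates, config, group_effect,
                                 meta) {
  ppm <- stats::runif(1, config$ppm_drift_range[[1]],
                      config$ppm_drift_range[[2]])
  outlier <- stats::runif(1) < config$outlier_rate
  scans <- lapply(seq_along(BURN_SHAPE), function(i) {
    simulate_spectrum(
      weights, templates, config, group_effect = group_effect,
      scale = BURN_SHAPE[[i]], ppm_drift = ppm, outlier = outlier,
      scan_time = i
    )
  })
  s <- scan_series(scans, meta)
  attr(s, "outlier") <- outlier
  s
}

#' Simulate a cohort of burn series
#'
#' Emulates the design of an ex vivo tissue library: `n_per_class`
#' samples per class template, spread over `n_groups` patients /
#' replicates, each sample acquired as an eight-scan burn with a
#' rise-plateau-fall TIC so that burn-scan selection is exercised.
#' Per-group multiplicative effects are drawn once per group.
#' Bit-identical output for a given config.
#'
#' @param config A [generator_config()]; `n_per_class` may be a vector
#'   (one entry per template) for unbalanced designs such as 94 + 91.
#' @param templates List of class templates.
#' @return A list with `series` (list of [scan_series()]) and `truth`
#'   (tibble: `sample_id`, `group_id`, `class_label`, `outlier`).
#' @export
simulate_cohort <- function(config, templates) {
  if (config$n_groups < 2) abort("Need `n_groups` >= 2.")
  n_per_class <- rep_len(config$n_per_class, length(templates))
  group_ids <- sprintf("g%02d", seq_len(config$n_groups))
  withr::with_seed(config$seed, {
    effects <- draw_group_effects(templates, config, group_ids)
    series <- list()
    rows <- list()
    k <- 0L
    for (c in seq_along(templates)) {
      w <- rep(0, length(templates))
      w[c] <- 1
      for (i in seq_len(n_per_class[[c]])) {
        k <- k + 1L
        g <- group_ids[[(i - 1L) %% config$n_groups + 1L]]
        sid <- sprintf("s%04d", k)
        meta <- sample_meta(
          sid, group_id = g, class_label = templates[[c]]$name
        )
        s <- simulate_burn_series(w, templates, config, effects[[g]], meta)
        series[[k]] <- s
        rows[[k]] <- tibble(
          sample_id = sid, group_id = g,
          class_label = templates[[c]]$name,
          outlier = attr(s, "outlier")
        )
      }
    }
    list(series = series, truth = dplyr::bind_rows(rows))
  })
}

#' Simulate a tumor/myoblast dilution series
#'
#' Emulates the cell-pellet dilution design: for each tumor fraction a
#' given number of burns, pure points spread over five biological
#' replicates and mixtures over three, as in the assay (93 at 100%, 44
#' at 50%, 57 at 25%, 49 at 10%, 93 at 0%; 336 profiles in total).
#'
#' @param config A [generator_config()].
#' @param templates Named list with templates `tumor` and `myoblast`.
#' @param fractions Tumor fractions of the design.
#' @param n_per_point Burns per fraction (same length as `fractions`).
#' @param reps_pure,reps_mixture Number of biological replicates used
#'   for pure (fraction 0 or 1) and mixture points.
#' @return A list with `series` and `truth` (tibble: `sample_id`,
#'   `group_id`, `tumor_fraction`, `class_label`, `outlier`), where
#'   `class_label` applies the dilution-model rule (tumor when the
#'   fraction is at least 10%, muscle when it is zero).
#' @export
simulate_dilution_series <- function(config, templates,
                                     fractions = c(1, 0.5, 0.25, 0.10, 0),
                                     n_per_point = c(93, 44, 57, 49, 93),
                                     reps_pure = 5, reps_mixture = 3) {
  if (length(fractions) != length(n_per_point)) {
    abort("`fractions` and `n_per_point` must have the same length.")
  }
  stopifnot(all(c("tumor", "myoblast") %in% names(templates)))
  templates <- templates[c("tumor", "myoblast")]
  group_ids <- sprintf("rep%d", seq_len(max(reps_pure, reps_mixture)))
  withr::with_seed(config$seed, {
    effects <- draw_group_effects(templates, config, group_ids)
    series <- list()
    rows <- list()
    k <- 0L
    for (p in seq_along(fractions)) {
      f <- fractions[[p]]
      n_reps <- if (f %in% c(0, 1)) reps_pure else reps_mixture
      for (i in seq_len(n_per_point[[p]])) {
        k <- k + 1L
        g <- group_ids[[(i - 1L) %% n_reps + 1L]]
        sid <- sprintf("d%04d", k)
        meta <- sample_meta(
          sid, group_id = g,
          class_label = if (f >= 0.10) "tumor" else if (f == 0) "muscle"
                        else NA_character_,
          composition = c(tumor = f, myoblast = 1 - f)
        )
        s <- simulate_burn_series(c(f, 1 - f), templates, config,
                                  effects[[g]], meta)
        series[[k]] <- s
        rows[[k]] <- tibble(
          sample_id = sid, group_id = g, tumor_fraction = f,
          class_label = meta$class_label, outlier = attr(s, "outlier")
        )
      }
    }
    list(series = series, truth = dplyr::bind_rows(rows))
  })
}

#' Separable dilution-series study conditions
#'
#' Templates and generator configuration for a dilution experiment in
#' which every tumor-containing mixture is separable from pure muscle:
#' disjoint peak sets, low noise (5% CV, 2% replicate effects) and a
#' tenfold tumor ionization-efficiency advantage.  The efficiency
#' asymmetry is what makes 10% cell mixtures detectable by a linear
#' classifier: with equal efficiencies a normalized mixture spectrum is
#' linear in the cell fraction, so a nearest-centroid rule can never
#' call a 10% mixture tumor regardless of noise, whereas a tenfold
#' advantage puts the tumor signal share of a 10% mixture above one
#' half.  See the methods vignette for the full argument.
#'
#' @param seed Integer seed (drives both templates and generator).
#' @return A list with `templates` (tumor, myoblast) and `config`.
#' @export
separable_dilution_setup <- function(seed) {
  list(
    templates = make_templates(
      2, n_peaks = 30, overlap_fraction = 0,
      seed = seed, names = c("tumor", "myoblast"), cv = 0.05,
      ionization_efficiency = c(10, 1)
    ),
    config = generator_config(seed = seed + 1L, noise_cv = 0.05,
                              group_effect_sd = 0.02)
  )
}

#' Simulate an MSI grid from a region map
#'
#' One spectrum per mapped pixel, drawn from the region's class template
#' (single scan, no burn shape).  Unmapped labels raise an error; pixels
#' absent from the map stay absent.
#'
#' @param region_map Tibble with columns `x`, `y`, `label`.
#' @param templates Named list of class templates covering every label.
#' @param config A [generator_config()].
#' @return An [msi_dataset()].
#' @export
simulate_msi_grid <- function(region_map, templates, config) {
  labs <- unique(region_map$label)
  missing <- setdiff(labs, names(templates))
  if (length(missing)) {
    abort(sprintf("No template for region label '%s'.", missing[[1]]))
  }
  withr::with_seed(config$seed, {
    specs <- lapply(seq_len(nrow(region_map)), function(i) {
      w <- as.numeric(names(templates) == region_map$label[[i]])
      simulate_spectrum(w, templates, config)
    })
    msi_dataset(
      tibble(x = region_map$x, y = region_map$y, peaks = specs),
      pixel_size = 30
    )
  })
}
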
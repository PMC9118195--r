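#' Preprocessing configuration
#'
#' Bundles every tunable of the raw-spectrum-to-feature-vector chain.
#' Defaults follow the tissue workflow: 0.1 Th bins over m/z 100-1500,
#' exclusion windows around the leucine-enkephalin lock-mass ion and its
#' associated peaks (m/z 554-558, 594-597, 1109-1112, 1131-1137), a
#' 5-standard-deviation outlier rule, and one spectrum per sampling spot.
#'
#' @param bin_width Bin width in Th.
#' @param mass_range Two-element numeric, `[low, high)` mass range in Th.
#' @param exclusion_windows List of `[low, high]` windows (Th) whose bins
#'   are zeroed after binning.
#' @param lockmass_mz Reference m/z of the lock-mass ion; the default is
#'   the monoisotopic \[LeuEnk-H\]- mass, 554.2615 Th.
#' @param lockmass_tol Search half-window around `lockmass_mz` in Th.
#' @param outlier_k Standard-deviation multiplier of the outlier rule
#'   (5 for tissue, 25 for cell pellets).
#' @param scan_mode `"one_per_spot"` (single maximum-TIC scan) or
#'   `"top_of_peak"` (all scans near the burn maximum).
#' @param top_frac TIC fraction of the event maximum defining "top of
#'   peak" scans.
#' @return A `preprocess_config` list.
#' @seealso [reims_tissue_config()], [reims_cells_config()],
#'   [desi_config()] for the canned workflow configurations.
#' @export
preprocess_config <- function(bin_width = 0.1,
                              mass_range = c(100, 1500),
                              exclusion_windows = list(
                                c(554, 558), c(594, 597),
                                c(1109, 1112), c(1131, 1137)
                              ),
                              lockmass_mz = 554.2615,
                              lockmass_tol = 0.25,
                              outlier_k = 5,
                              scan_mode = c("one_per_spot", "top_of_peak"),
                              top_frac = 0.7) {
  scan_mode <- match.arg(scan_mode)
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  if (length(mass_range) != 2 || diff(mass_range) <= 0) {
    abort("`mass_range` must be c(low, high) with low < high.")
  }
  if (outlier_k <= 0) abort("`outlier_k` must be positive.")
  if (lockmass_tol <= 0) abort("`lockmass_tol` must be positive.")
  structure(
    list(
      bin_width = bin_width, mass_range = as.numeric(mass_range),
      exclusion_windows = exclusion_windows, lockmass_mz = lockmass_mz,
      lockmass_tol = lockmass_tol, outlier_k = outlier_k,
      scan_mode = scan_mode, top_frac = top_frac
    ),
    class = "preprocess_config"
  )
}

#' @rdname preprocess_config
#' @export
reims_tissue_config <- function() preprocess_config()

#' @rdname preprocess_config
#' @details `reims_cells_config()` follows the cell-pellet workflow:
#'   m/z 600-1000, the 25-SD outlier rule, top-of-peak scan selection and
#'   no exclusion windows (the lock-mass regions fall outside the range).
#' @export
reims_cells_config <- function() {
  preprocess_config(
    mass_range = c(600, 1000), exclusion_windows = list(),
    outlier_k = 25, scan_mode = "top_of_peak"
  )
}

#' @rdname preprocess_config
#' @export
desi_config <- function() {
  preprocess_config(
    mass_range = c(600, 1000), exclusion_windows = list(),
    scan_mode = "one_per_spot"
  )
}

#' Select burn scans from a scan series
#'
#' In `"one_per_spot"` mode the single scan with maximal total ion
#' current is returned.  In `"top_of_peak"` mode the contiguous block of
#' scans around the TIC maximum whose TIC stays at or above
#' `top_frac` of that maximum is returned.
#'
#' @param series A [scan_series()].
#' @param config A [preprocess_config()].
#' @return A list of [spectrum()] objects.
#' @export
select_burn_scans <- function(series, config = preprocess_config()) {
  if (!nrow(series)) abort("Empty scan series.")
  tics <- series$tic
  if (all(tics == 0)) {
    abort(sprintf("No signal in series '%s' (all-zero TIC).",
                  series_meta(series)$sample_id))
  }
  imax <- which.max(tics)
  if (config$scan_mode == "one_per_spot") {
    return(series$peaks[imax])
  }
  ok <- tics >= config$top_frac * tics[imax]
  lo <- imax
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- imax
  while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  series$peaks[lo:hi]
}

#' Lock-mass recalibration of a spectrum
#'
#' Finds the most intense peak within `tol` Th of the lock-mass reference
#' and applies a single-point multiplicative (ppm) correction so that it
#' sits exactly at the reference m/z.  If no peak lies in the window the
#' spectrum is returned unchanged with `corrected = FALSE` and a warning.
#'
#' @param spec A [spectrum()].
#' @param lockmass_mz Reference m/z (Th).
#' @param tol Search half-window (Th).
#' @return A list with elements `spectrum` (recalibrated), `applied_ppm`
#'   (the ppm shift that was applied) and `corrected` (logical).
#' @export
lockmass_correct <- function(spec, lockmass_mz = 554.2615, tol = 0.25) {
  if (tol <= 0) abort("`tol` must be positive.")
  in_win <- which(abs(spec$mz - lockmass_mz) <= tol)
  if (!length(in_win)) {
    warn(sprintf(
      "No lock-mass peak within %g Th of %g; spectrum left uncorrected.",
      tol, lockmass_mz
    ))
    return(list(spectrum = spec, applied_ppm = 0, corrected = FALSE))
  }
  found <- spec$mz[in_win[which.max(spec$intensity[in_win])]]
  factor <- lockmass_mz / found
  out <- spectrum(spec$mz * factor, spec$intensity, scan_time(spec))
  list(
    spectrum = out,
    applied_ppm = (factor - 1) * 1e6,
    corrected = TRUE
  )
}

#' Bin a spectrum onto a fixed m/z axis
#'
#' Half-open bins `[edge, edge + width)` anchored at the lower end of the
#' mass range; every in-range peak contributes its full intensity to
#' exactly one bin, so total in-range intensity is conserved exactly.
#' Peaks outside the mass range are dropped.
#'
#' @param spec A [spectrum()].
#' @param config A [preprocess_config()] (uses `bin_width`, `mass_range`).
#' @return A `binned_vector`: named numeric vector of per-bin intensities
#'   with attributes `edges` and `normalized`.
#' @export
bin_spectrum <- function(spec, config = preprocess_config()) {
  low <- config$mass_range[[1]]
  high <- config$mass_range[[2]]
  w <- config$bin_width
  n_bins <- ceiling((high - low) / w - 1e-9)
  edges <- low + w * (0:(n_bins - 1))
  vals <- numeric(n_bins)
  idx <- floor((spec$mz - low) / w)
  keep <- spec$mz >= low & idx >= 0 & idx < n_bins
  if (any(keep)) {
    agg <- rowsum(spec$intensity[keep], idx[keep])
    vals[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  binned_vector(vals, edges)
}

#' Construct a binned intensity vector
#' @param values Non-negative per-bin intensities.
#' @param edges Bin lower edges, one per value.
#' @param normalized Whether the vector has been TIC-normalized.
#' @return A `binned_vector`.
#' @export
binned_vector <- function(values, edges, normalized = FALSE) {
  stopifnot(length(values) == length(edges))
  structure(
    stats::setNames(as.numeric(values), bin_col_name(edges)),
    edges = as.numeric(edges), normalized = normalized,
    class = "binned_vector"
  )
}

#' @export
print.binned_vector <- function(x, ...) {
  cat(sprintf(
    "<binned_vector: %d bins, %s>\n", length(x),
    if (attr(x, "normalized")) "normalized" else "raw"
  ))
  invisible(x)
}

#' Zero out excluded m/z windows
#'
#' Every bin whose half-open interval intersects one of the (closed)
#' exclusion windows is set to zero; all other bins are untouched.  The
#' tissue workflow excludes the leucine-enkephalin-associated regions.
#'
#' @param binned A `binned_vector`.
#' @param windows List of `c(low, high)` windows in Th.
#' @return The masked `binned_vector`.
#' @export
apply_exclusions <- function(binned, windows) {
  edges <- attr(binned, "edges")
  if (length(edges) < 1 || !length(windows)) return(binned)
  w <- if (length(edges) > 1) stats::median(diff(edges)) else 0.1
  drop <- rep(FALSE, length(edges))
  for (win in windows) {
    drop <- drop | (edges <= win[[2]] & edges + w > win[[1]])
  }
  binned[drop] <- 0
  binned
}

#' Subtract a per-spectrum background level
#'
#' The baseline is the 5th percentile of the non-zero bin intensities; it
#' is subtracted from every non-zero bin and results are clipped at zero.
#' An all-zero vector is returned unchanged.
#'
#' @param binned A `binned_vector` (unnormalized).
#' @param prob Percentile (as a fraction) defining the baseline.
#' @return The background-subtracted `binned_vector`, with the estimated
#'   baseline recorded in the `baseline` attribute.
#' @export
background_subtract <- function(binned, prob = 0.05) {
  nz <- binned > 0
  if (!any(nz)) return(binned)
  b <- stats::quantile(binned[nz], prob, names = FALSE)
  binned[nz] <- pmax(binned[nz] - b, 0)
  attr(binned, "baseline") <- b
  binned
}

#' Normalize a binned vector to unit total ion current
#'
#' @param binned A `binned_vector` with positive sum.
#' @return The normalized vector (`normalized` attribute set; values sum
#'   to 1).
#' @export
normalize_tic <- function(binned) {
  s <- sum(binned)
  if (s <= 0) abort("Cannot TIC-normalize a vector with zero total.")
  out <- binned / s
  attributes(out) <- attributes(binned)
  attr(out, "normalized") <- TRUE
  out
}

#' Preprocess one scan series into one feature vector
#'
#' The canonical chain: burn-scan selection, per-scan lock-mass
#' recalibration, pooling of the selected scans, binning, exclusion-window
#' masking, background subtraction, TIC normalization.
#'
#' @param series A [scan_series()].
#' @param config A [preprocess_config()].
#' @return A normalized `binned_vector` with attributes `applied_ppm`
#'   (mean over selected scans) and `n_scans`.
#' @export
preprocess_series <- function(series, config = preprocess_config()) {
  scans <- select_burn_scans(series, config)
  ppms <- numeric(length(scans))
  corrected <- lapply(seq_along(scans), function(i) {
    lc <- lockmass_correct(scans[[i]], config$lockmass_mz, config$lockmass_tol)
    ppms[i] <<- lc$applied_ppm
    lc$spectrum
  })
  pooled <- spectrum(
    unlist(lapply(corrected, `[[`, "mz")),
    unlist(lapply(corrected, `[[`, "intensity"))
  )
  out <- bin_spectrum(pooled, config)
  out <- apply_exclusions(out, config$exclusion_windows)
  out <- background_subtract(out)
  out <- normalize_tic(out)
  attr(out, "applied_ppm") <- mean(ppms)
  attr(out, "n_scans") <- length(scans)
  out
}

#' Preprocess a cohort of scan series into a feature matrix
#'
#' Applies [preprocess_series()] to every series and assembles the
#' normalized profiles into a wide feature-matrix tibble (metadata
#' columns followed by `mz_*` bin columns).
#'
#' @param series_list List of [scan_series()].
#' @param config A [preprocess_config()].
#' @param tumor_component Composition component reported as
#'   `tumor_fraction`.
#' @return A feature-matrix tibble with one row per series.
#' @export
preprocess_cohort <- function(series_list, config = preprocess_config(),
                              tumor_component = "tumor") {
  stopifnot(length(series_list) > 0)
  profs <- lapply(series_list, preprocess_series, config = config)
  vals <- do.call(rbind, lapply(profs, as.numeric))
  metas <- lapply(series_list, series_meta)
  comp <- lapply(metas, `[[`, "composition")
  meta <- tibble(
    sample_id = vapply(metas, `[[`, character(1), "sample_id"),
    group_id = vapply(metas, `[[`, character(1), "group_id"),
    class_label = vapply(metas, `[[`, character(1), "class_label"),
    modality = vapply(metas, `[[`, character(1), "modality"),
    tumor_fraction = vapply(comp, function(x) {
      if (is.null(x) || !tumor_component %in% names(x)) NA_real_
      else unname(x[[tumor_component]])
    }, numeric(1)),
    composition = comp
  )
  feature_matrix(vals, attr(profs[[1]], "edges"), meta)
}

#' Flag outlier spectra within classes
#'
#' For each class the Euclidean distance of every sample to the class mean
#' profile is computed (over the bins inside `mass_range`); a sample is
#' flagged when its distance exceeds the class mean distance by more than
#' `k` standard deviations of the within-class distances.  Classes with
#' fewer than three members are never flagged (with a message).  The
#' tissue workflow uses `k = 5`, the cell-pellet workflow `k = 25`.
#'
#' @param x A feature-matrix tibble.
#' @param k Standard-deviation multiplier.
#' @param mass_range Optional `c(low, high)` restriction in Th.
#' @param class_col Metadata column holding the class labels.
#' @return A logical mask, one entry per row of `x` (`TRUE` = outlier),
#'   named by `sample_id`.  `x` itself is never modified.
#' @export
flag_outliers <- function(x, k = 5, mass_range = NULL,
                          class_col = "class_label") {
  vals <- fm_values(x)
  if (!is.null(mass_range)) {
    e <- bin_edges(x)
    vals <- vals[, e >= mass_range[[1]] & e < mass_range[[2]], drop = FALSE]
  }
  labels <- x[[class_col]]
  mask <- rep(FALSE, nrow(x))
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    if (length(rows) < 3) {
      inform(sprintf(
        "Class '%s' has %d sample(s) (< 3); outlier rule not applied.",
        cl, length(rows)
      ))
      next
    }
    centre <- colMeans(vals[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(vals[rows, , drop = FALSE], 2, centre)^2))
    thr <- mean(d) + k * stats::sd(d)
    mask[rows] <- d > thr
  }
  stats::setNames(mask, x$sample_id)
}
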
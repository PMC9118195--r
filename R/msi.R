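bin_pixel_matrix <- function(data, config) {
  profs <- lapply(data$peaks, function(sp) {
    as.numeric(bin_spectrum(sp, config))
  })
  vals <- do.call(rbind, profs)
  edges <- attr(bin_spectrum(data$peaks[[1]], config), "edges")
  list(values = vals, edges = edges)
}

#' Pixel-group metabolic profiles from annotated regions
#'
#' Within each annotated region of interest, pixels are tiled row-major
#' (scanline order: by `y`, then `x`) into consecutive groups of
#' `group_size` adjacent pixels; each group's spectra are summed and
#' TIC-normalized into one metabolic profile labelled with the region
#' label.  The imaging workflow combines groups of six adjacent pixels.
#' Leftover pixels that do not fill a group are dropped (a message gives
#' the count); regions smaller than one group are skipped with a warning.
#'
#' @param data An [msi_dataset()].
#' @param roi Region map: tibble with columns `x`, `y`, `label`.
#' @param group_size Pixels per profile.
#' @param config A [preprocess_config()] supplying the bin axis (the
#'   imaging workflow uses m/z 600-1000, 0.1 Th bins).
#' @return A feature-matrix tibble, one row per pixel group, with the
#'   region label in `class_label`.
#' @export
roi_group_profiles <- function(data, roi, group_size = 6,
                               config = desi_config()) {
  stopifnot(all(c("x", "y", "label") %in% names(roi)))
  joined <- dplyr::inner_join(
    as_tibble(data), as_tibble(roi)[, c("x", "y", "label")],
    by = c("x", "y")
  )
  if (!nrow(joined)) abort("No ROI pixel matches the dataset.")
  out_rows <- list()
  out_meta <- list()
  for (lab in unique(roi$label)) {
    px <- joined[joined$label == lab, , drop = FALSE]
    px <- px[order(px$y, px$x), , drop = FALSE]
    n_groups <- nrow(px) %/% group_size
    if (n_groups == 0) {
      warn(sprintf("ROI '%s' has %d pixel(s) (< %d); skipped.",
                   lab, nrow(px), group_size))
      next
    }
    leftover <- nrow(px) %% group_size
    if (leftover) {
      inform(sprintf("ROI '%s': %d leftover pixel(s) dropped.", lab, leftover))
    }
    bm <- bin_pixel_matrix(px, config)
    for (g in seq_len(n_groups)) {
      rows <- ((g - 1) * group_size + 1):(g * group_size)
      prof <- colSums(bm$values[rows, , drop = FALSE])
      if (sum(prof) <= 0) {
        warn(sprintf("ROI '%s' group %d has zero signal; skipped.", lab, g))
        next
      }
      out_rows[[length(out_rows) + 1L]] <- prof / sum(prof)
      out_meta[[length(out_meta) + 1L]] <- tibble(
        sample_id = sprintf("%s_%03d", lab, g),
        group_id = lab, class_label = lab, modality = "DESI"
      )
    }
  }
  if (!length(out_rows)) abort("No ROI produced any profile.")
  bm_edges <- bin_pixel_matrix(joined[1, , drop = FALSE], config)$edges
  feature_matrix(do.call(rbind, out_rows), bm_edges,
                 dplyr::bind_rows(out_meta))
}

#' K-means segmentation of an MSI dataset
#'
#' Pixels are binned onto the configured axis, restricted to the mass
#' range, TIC-normalized, and clustered with k-means (k-means++-style
#' multiple random restarts, Euclidean distance).  The segmentation is
#' deterministic for a given seed.
#'
#' @param data An [msi_dataset()].
#' @param k Number of clusters.
#' @param config A [preprocess_config()] (bin axis and mass range).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts.
#' @return An `msi_segmentation`: list with `labels` (tibble `x`, `y`,
#'   `cluster`), `centers` (cluster-mean spectra matrix), `k`.
#' @export
kmeans_segment <- function(data, k, config = desi_config(), seed = 1,
                           nstart = 10) {
  if (k > nrow(data)) {
    abort(sprintf("k = %d exceeds the %d available pixels.", k, nrow(data)))
  }
  bm <- bin_pixel_matrix(data, config)
  sums <- rowSums(bm$values)
  if (any(sums <= 0)) abort("A pixel has zero intensity in the mass range.")
  vals <- bm$values / sums
  km <- withr::with_seed(seed, {
    stats::kmeans(vals, centers = k, nstart = nstart, iter.max = 100)
  })
  centers <- km$centers
  colnames(centers) <- bin_col_name(bm$edges)
  structure(
    list(
      labels = tibble(x = data$x, y = data$y,
                      cluster = as.integer(km$cluster)),
      centers = centers,
      k = k,
      tot_withinss = km$tot.withinss
    ),
    class = "msi_segmentation"
  )
}

#' @export
print.msi_segmentation <- function(x, ...) {
  cat(sprintf("<msi_segmentation: k = %d over %d pixels>\n",
              x$k, nrow(x$labels)))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' Extracted ion image
#'
#' Per-pixel summed intensity within `target_mz` plus/minus `tol`.
#' Pixels absent from the (possibly sparse) dataset are absent from the
#' result, never reported as zero.
#'
#' @param data An [msi_dataset()].
#' @param target_mz Target m/z (Th), e.g. 698.5 for the
#'   ether-phosphatidylethanolamine marker or 465.3 for cholesterol
#'   sulfate.
#' @param tol Half-window in Th (default 0.05, matching 0.1 Th bins).
#' @return Tibble with `x`, `y`, `intensity`.
#' @export
ion_image <- function(data, target_mz, tol = 0.05) {
  if (tol <= 0) abort("`tol` must be positive.")
  intensity <- vapply(data$peaks, function(sp) {
    sum(sp$intensity[abs(sp$mz - target_mz) <= tol])
  }, numeric(1))
  tibble(x = data$x, y = data$y, intensity = intensity)
}

#' Mean spectrum of an MSI dataset
#'
#' Bins every pixel onto a common axis and averages, returning the mean
#' profile as a centroided spectrum (bin centres as m/z) suitable for
#' [peak_pick()].
#'
#' @param data An [msi_dataset()].
#' @param config A [preprocess_config()] supplying bin width and range.
#' @return A [spectrum()].
#' @export
msi_mean_spectrum <- function(data, config = desi_config()) {
  bm <- bin_pixel_matrix(data, config)
  m <- colMeans(bm$values)
  keep <- m > 0
  spectrum(bm$edges[keep] + config$bin_width / 2, m[keep])
}

#' Peak picking with baseline correction and deisotoping
#'
#' Mirrors a conventional average-spectrum peak-picking chain: a rolling
#' minimum over a 10 Th window estimates the baseline, which is
#' subtracted; surviving local maxima above a signal-to-noise threshold
#' are retained; greedy deisotoping in ascending m/z then removes peaks
#' lying one isotope spacing (1.00335 Th, within `gap_tol`) above a more
#' intense peak of the same envelope, returning monoisotopic peaks only.
#'
#' @param spec A [spectrum()] (typically [msi_mean_spectrum()] output).
#' @param baseline_window Width of the rolling-minimum window (Th).
#' @param dense_min_pts Minimum number of data points a window must hold
#'   for the rolling minimum to apply; sparser (centroided) regions get a
#'   zero baseline, so an isolated peak is never its own baseline.
#' @param snr Signal-to-noise multiplier; the noise scale is the median
#'   absolute deviation of the baseline-subtracted intensities.
#' @param isotope_gap Isotope spacing in Th.
#' @param gap_tol Tolerance on the spacing (Th).
#' @param local_window Neighbourhood (Th) within which a peak must beat
#'   its list neighbours to count as a local maximum.
#' @return Tibble with `mz`, `intensity` (baseline-subtracted) and
#'   `baseline`.
#' @export
peak_pick <- function(spec, baseline_window = 10, dense_min_pts = 8,
                      snr = 3, isotope_gap = 1.00335, gap_tol = 0.01,
                      local_window = 0.2) {
  if (!nrow(spec)) abort("Cannot peak-pick an empty spectrum.")
  mz <- spec$mz
  ints <- spec$intensity
  n <- length(mz)
  half <- baseline_window / 2
  baseline <- vapply(seq_len(n), function(i) {
    win <- abs(mz - mz[i]) <= half
    if (sum(win) >= dense_min_pts) min(ints[win]) else 0
  }, numeric(1))
  net <- ints - baseline
  noise <- stats::mad(net)
  thr <- snr * noise
  is_max <- vapply(seq_len(n), function(i) {
    nb <- which(abs(mz - mz[i]) <= local_window & seq_len(n) != i)
    all(net[i] >= net[nb])
  }, logical(1))
  cand <- which(is_max & net > thr & net > 0)
  if (!length(cand)) return(tibble(mz = numeric(), intensity = numeric(),
                                   baseline = numeric()))
  cand <- cand[order(mz[cand])]
  retained <- integer()
  envelope <- integer()  # retained peaks plus their identified isotopes
  for (i in cand) {
    prev <- envelope[
      mz[i] - mz[envelope] >= isotope_gap - gap_tol &
        mz[i] - mz[envelope] <= isotope_gap + gap_tol &
        net[envelope] > net[i]
    ]
    if (length(prev)) {
      envelope <- c(envelope, i)  # isotope: joins the envelope, not retained
    } else {
      retained <- c(retained, i)
      envelope <- c(envelope, i)
    }
  }
  tibble(mz = mz[retained], intensity = net[retained],
         baseline = baseline[retained])
}
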
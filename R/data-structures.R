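#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Metadata columns recognised in feature-matrix tibbles; everything named
# `mz_*` is a bin column, everything else rides along untouched.
META_COLS <- c(
  "sample_id", "group_id", "class_label", "modality",
  "tumor_fraction", "composition"
)

#' Construct a mass spectrum
#'
#' A spectrum is a tibble with columns `mz` (Thomson, strictly increasing)
#' and `intensity` (non-negative, arbitrary counts).  Unsorted input is
#' sorted; peaks at identical m/z are merged by summing their intensities.
#'
#' @param mz Numeric vector of mass-to-charge ratios (Th).
#' @param intensity Non-negative numeric vector, same length as `mz`.
#' @param scan_time Acquisition time of the scan in seconds.
#' @return A `ms_spectrum` tibble with columns `mz`, `intensity` and a
#'   `scan_time` attribute.
#' @examples
#' spectrum(c(200, 100), c(7, 5))
#' @export
spectrum <- function(mz, intensity, scan_time = NA_real_) {
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.")
  }
  if (length(intensity) && any(intensity < 0)) {
    abort("Intensities must be non-negative.")
  }
  if (length(mz) && any(!is.finite(mz))) {
    abort("All m/z values must be finite.")
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  out <- tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  attr(out, "scan_time") <- as.numeric(scan_time)
  class(out) <- c("ms_spectrum", class(out))
  out
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum: %d peaks%s>\n", nrow(x),
    if (is.na(scan_time(x))) "" else sprintf(", t = %gs", scan_time(x))
  ))
  NextMethod()
}

#' Scan time of a spectrum
#' @param x An `ms_spectrum`.
#' @return Scan time in seconds (`NA` if unknown).
#' @export
scan_time <- function(x) attr(x, "scan_time") %||% NA_real_

#' Total ion current of a spectrum
#' @param x An `ms_spectrum` (any tibble with an `intensity` column).
#' @return Summed intensity of all peaks.
#' @export
tic <- function(x) sum(x$intensity)

#' Sample metadata
#'
#' Describes one sampling event: the sample identifier, the grouping unit
#' used for leave-one-group-out cross-validation (patient for tissue data,
#' biological replicate for cell pellets), an optional class label, an
#' optional known composition (named fractions over cell lines, summing to
#' one), and the acquisition modality.
#'
#' @param sample_id Sample identifier.
#' @param group_id Patient / biological-replicate identifier.
#' @param class_label Class label, or `NA` when unknown.
#' @param composition Named numeric vector of cell-line fractions in
#'   `[0, 1]` summing to 1, or `NULL`.
#' @param modality `"REIMS"` or `"DESI"`.
#' @return A `sample_meta` list.
#' @export
sample_meta <- function(sample_id, group_id = sample_id,
                        class_label = NA_character_, composition = NULL,
                        modality = c("REIMS", "DESI")) {
  modality <- match.arg(modality)
  if (!is.null(composition)) {
    if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
      abort("`composition` must be a named numeric vector.")
    }
    if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
      abort("Composition fractions must be non-negative and sum to 1.")
    }
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      group_id = as.character(group_id),
      class_label = as.character(class_label),
      composition = composition,
      modality = modality
    ),
    class = "sample_meta"
  )
}

#' Construct a scan series
#'
#' The time-ordered scans of one sampling event (one cauterization "burn"
#' for REIMS), stored as a tibble with one row per scan: `scan` index,
#' `scan_time`, `tic` (total ion current) and a `peaks` list-column of
#' spectra.  Scans are ordered by scan time.
#'
#' @param spectra List of [spectrum()] objects.
#' @param meta A [sample_meta()] object.
#' @return A `scan_series` tibble.
#' @export
scan_series <- function(spectra, meta = sample_meta("sample")) {
  if (!length(spectra)) abort("A scan series needs at least one scan.")
  stopifnot(inherits(meta, "sample_meta"))
  times <- vapply(spectra, scan_time, numeric(1))
  if (all(is.na(times))) times <- seq_along(spectra)
  ord <- order(times)
  out <- tibble(
    scan = seq_along(spectra),
    scan_time = as.numeric(times[ord]),
    tic = vapply(spectra[ord], tic, numeric(1)),
    peaks = spectra[ord]
  )
  attr(out, "meta") <- meta
  class(out) <- c("scan_series", class(out))
  out
}

#' @export
print.scan_series <- function(x, ...) {
  m <- series_meta(x)
  cat(sprintf(
    "<scan_series: sample %s, group %s, %d scans>\n",
    m$sample_id, m$group_id, nrow(x)
  ))
  NextMethod()
}

#' Metadata of a scan series
#' @param x A `scan_series`.
#' @return The attached [sample_meta()].
#' @export
series_meta <- function(x) attr(x, "meta")

# Canonical bin-column name: lower edge rounded to 1e-6 Th so that the
# same physical edge always formats identically and name-based matching
# across matrices is exact.
bin_col_name <- function(edges) sprintf("mz_%g", round(edges, 6))

#' Bin columns of a feature matrix
#' @param x A feature-matrix tibble.
#' @return Character vector of `mz_*` column names, in increasing m/z order.
#' @export
bin_cols <- function(x) {
  cols <- grep("^mz_", names(x), value = TRUE)
  cols[order(as.numeric(sub("^mz_", "", cols)))]
}

#' Bin lower edges of a feature matrix
#' @param x A feature-matrix tibble.
#' @return Numeric vector of bin lower edges (Th), increasing.
#' @export
bin_edges <- function(x) as.numeric(sub("^mz_", "", bin_cols(x)))

#' Bin width of a feature matrix
#' @param x A feature-matrix tibble.
#' @return The (constant) bin width in Th.
#' @export
bin_width <- function(x) {
  e <- bin_edges(x)
  if (length(e) < 2) return(NA_real_)
  stats::median(diff(e))
}

#' Extract the sample-by-bin intensity matrix
#' @param x A feature-matrix tibble.
#' @return Numeric matrix (samples in rows, bins in columns, edges as
#'   column names without the `mz_` prefix).
#' @export
fm_values <- function(x) {
  cols <- bin_cols(x)
  m <- as.matrix(as.data.frame(x)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- sub("^mz_", "", cols)
  rownames(m) <- x$sample_id
  m
}

#' Assemble a feature matrix from components
#'
#' @param values Numeric samples-by-bins matrix, non-negative.
#' @param edges Bin lower edges (Th), strictly increasing, constant width.
#' @param meta Tibble of per-sample metadata (one row per matrix row);
#'   must contain `sample_id`.
#' @return A tibble with the metadata columns followed by `mz_*` bin
#'   columns.
#' @export
feature_matrix <- function(values, edges, meta) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(meta)) {
    abort("`values` and `meta` must have the same number of rows.")
  }
  if (ncol(values) != length(edges)) {
    abort("`edges` must have one entry per value column.")
  }
  if (length(edges) > 1) {
    d <- diff(edges)
    if (any(d <= 0)) abort("Bin edges must be strictly increasing.")
    if (max(d) - min(d) > 1e-6 * stats::median(d)) {
      abort("Bin edges must be equally spaced.")
    }
  }
  if (any(values < 0)) abort("Feature-matrix intensities must be non-negative.")
  if (!"sample_id" %in% names(meta)) abort("`meta` must contain `sample_id`.")
  vals <- as_tibble(as.data.frame(values, optional = TRUE),
                    .name_repair = "minimal")
  names(vals) <- bin_col_name(edges)
  dplyr::bind_cols(as_tibble(meta), vals)
}
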
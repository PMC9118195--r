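#' Parse a mixture-composition string
#'
#' Dilution points are labelled with strings such as `"90/10"`.  The
#' numbers are percentages of the named components, first number for the
#' first-named component.
#'
#' @param x Character vector of composition strings (`"50/50"`, `"90/10"`,
#'   `"100"`, ...).
#' @param components Character vector naming the components in the order
#'   the numbers are written.
#' @return A list of named numeric fraction vectors summing to 1.
#' @examples
#' parse_composition("90/10", c("myoblast", "tumor"))
#' @export
parse_composition <- function(x, components) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- suppressWarnings(as.numeric(strsplit(s, "/", fixed = TRUE)[[1]]))
    if (any(is.na(parts))) {
      abort(sprintf("Cannot parse composition string '%s'.", s))
    }
    if (length(parts) == 1) parts <- c(parts, rep(0, length(components) - 1))
    if (length(parts) != length(components)) {
      abort(sprintf(
        "Composition '%s' has %d parts but %d components were named.",
        s, length(parts), length(components)
      ))
    }
    if (sum(parts) <= 0) abort(sprintf("Composition '%s' sums to zero.", s))
    stats::setNames(parts / sum(parts), components)
  })
}

read_one_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(sprintf("Peak-list file '%s' contains no data.", basename(path)))
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf(
      "Peak-list file '%s': line %d does not have two columns.",
      basename(path), bad[[1]]
    ))
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad <- which(apply(matrix(is.na(vals), ncol = 2, byrow = TRUE), 1, any))
    abort(sprintf(
      "Peak-list file '%s': non-numeric value on line %d.",
      basename(path), bad[[1]]
    ))
  }
  m <- matrix(vals, ncol = 2, byrow = TRUE)
  spectrum(m[, 1], m[, 2])
}

# Split a TIC trace into sampling events: scans whose TIC stays below
# `frac` of the series maximum for >= `min_run` consecutive scans are
# treated as between-burn background and separate events.
segment_events <- function(tics, frac = 0.05, min_run = 2) {
  if (!length(tics)) return(integer())
  low <- tics < frac * max(tics)
  r <- rle(low)
  sep <- r$values & r$lengths >= min_run
  event <- integer(length(tics))
  ev <- 0L
  idx <- 1L
  new_event <- TRUE
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[[j]]
    if (sep[[j]]) {
      event[idx:(idx + len - 1L)] <- NA_integer_
      new_event <- TRUE
    } else {
      if (new_event) ev <- ev + 1L
      event[idx:(idx + len - 1L)] <- ev
      new_event <- FALSE
    }
    idx <- idx + len
  }
  event
}

meta_from_row <- function(row, components = NULL) {
  comp <- NULL
  if (!is.null(components) && !is.null(row$composition) &&
      !is.na(row$composition)) {
    comp <- parse_composition(row$composition, components)[[1]]
  }
  sample_meta(
    sample_id = row$sample_id,
    group_id = if (!is.null(row$group_id) && !is.na(row$group_id)) {
      row$group_id
    } else {
      row$sample_id
    },
    class_label = row$class_label %||% NA_character_,
    composition = comp,
    modality = row$modality %||% "REIMS"
  )
}

#' Read raw scan data into scan series
#'
#' Reads either mzML (via the mzR parser) or the plain peak-list dialect:
#' one file per scan with two delimited numeric columns (m/z, intensity;
#' tab or comma separated, `#` comments), plus a sidecar metadata table.
#' Scans are grouped into one [scan_series()] per sampling event, either by
#' the `sample_id` column of the metadata or, when no metadata is given,
#' by gaps in the total ion current (TIC below 5% of the series maximum
#' for at least two consecutive scans).
#'
#' @param path mzML file, or a directory of peak-list files.
#' @param format `"mzml"` or `"peaklist"`; `"auto"` decides from `path`.
#' @param meta Metadata table (data frame, or path to a TSV).  For
#'   peak lists it must contain `file` and `sample_id`; for mzML, `scan`
#'   (1-based index) and `sample_id`.  Optional columns: `scan_time`,
#'   `group_id`, `class_label`, `composition`, `modality`.  For a peak-list
#'   directory, a `meta.tsv` file inside the directory is picked up
#'   automatically.
#' @param components Component names used to interpret `composition`
#'   strings such as `"90/10"` (first number = first component).
#' @param tic_frac,min_gap TIC-segmentation parameters used when no
#'   metadata maps scans to events.
#' @return A list of [scan_series()].
#' @export
read_scans <- function(path, format = c("auto", "mzml", "peaklist"),
                       meta = NULL, components = NULL,
                       tic_frac = 0.05, min_gap = 2) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "peaklist" else "mzml"
  }
  if (is.character(meta) && length(meta) == 1) {
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  }
  if (format == "peaklist") {
    if (!dir.exists(path)) abort(sprintf("Directory '%s' not found.", path))
    if (is.null(meta)) {
      side <- file.path(path, "meta.tsv")
      if (file.exists(side)) {
        meta <- utils::read.delim(side, stringsAsFactors = FALSE)
      }
    }
    files <- sort(setdiff(
      list.files(path, full.names = FALSE),
      c("meta.tsv")
    ))
    files <- files[!dir.exists(file.path(path, files))]
    if (!length(files)) abort(sprintf("No peak-list files in '%s'.", path))
    specs <- lapply(file.path(path, files), read_one_peaklist)
    if (!is.null(meta)) {
      if (!all(c("file", "sample_id") %in% names(meta))) {
        abort("Peak-list metadata needs `file` and `sample_id` columns.")
      }
      idx <- match(files, meta$file)
      if (anyNA(idx)) {
        abort(sprintf("No metadata row for scan file '%s'.",
                      files[which(is.na(idx))[1]]))
      }
      meta <- meta[idx, , drop = FALSE]
      if ("scan_time" %in% names(meta)) {
        for (i in seq_along(specs)) {
          attr(specs[[i]], "scan_time") <- as.numeric(meta$scan_time[[i]])
        }
      }
      split_ids <- meta$sample_id
      unname(lapply(split(seq_along(specs), factor(split_ids, unique(split_ids))),
        function(i) {
          scan_series(specs[i],
                      meta_from_row(as.list(meta[i[[1]], ]), components))
        }
      ))
    } else {
      tics <- vapply(specs, tic, numeric(1))
      event <- segment_events(tics, tic_frac, min_gap)
      keep <- !is.na(event)
      unname(lapply(split(which(keep), event[keep]), function(i) {
        scan_series(specs[i], sample_meta(sprintf("event%02d", event[i[[1]]])))
      }))
    }
  } else {
    if (!file.exists(path)) abort(sprintf("File '%s' not found.", path))
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("Reading mzML requires the mzR package.")
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    hdr <- mzR::header(handle)
    if (!nrow(hdr)) abort(sprintf("mzML file '%s' contains no scans.", path))
    specs <- lapply(seq_len(nrow(hdr)), function(i) {
      pk <- mzR::peaks(handle, i)
      spectrum(pk[, 1], pk[, 2], scan_time = hdr$retentionTime[[i]])
    })
    if (!is.null(meta)) {
      if (!all(c("scan", "sample_id") %in% names(meta))) {
        abort("mzML metadata needs `scan` and `sample_id` columns.")
      }
      meta <- meta[order(meta$scan), , drop = FALSE]
      specs <- specs[meta$scan]
      ids <- meta$sample_id
      unname(lapply(split(seq_along(specs), factor(ids, unique(ids))),
        function(i) {
          scan_series(specs[i],
                      meta_from_row(as.list(meta[i[[1]], ]), components))
        }
      ))
    } else {
      tics <- vapply(specs, tic, numeric(1))
      event <- segment_events(tics, tic_frac, min_gap)
      keep <- !is.na(event)
      unname(lapply(split(which(keep), event[keep]), function(i) {
        scan_series(specs[i], sample_meta(sprintf("event%02d", event[i[[1]]])))
      }))
    }
  }
}

#' Write scan series as a peak-list directory
#'
#' Inverse of [read_scans()] for the peak-list dialect: one tab-separated
#' file per scan plus a `meta.tsv` sidecar.  `read_scans(write_scans(x))`
#' reproduces m/z and intensities to the printed precision (17 significant
#' digits, i.e. exactly for doubles).
#'
#' @param series A list of [scan_series()] (or a single one).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scans <- function(series, dir) {
  if (inherits(series, "scan_series")) series <- list(series)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  n <- 0L
  for (s in series) {
    m <- series_meta(s)
    for (i in seq_len(nrow(s))) {
      n <- n + 1L
      fname <- sprintf("scan%04d.tsv", n)
      sp <- s$peaks[[i]]
      writeLines(
        c("# m/z\tintensity",
          sprintf("%.17g\t%.17g", sp$mz, sp$intensity)),
        file.path(dir, fname)
      )
      rows[[n]] <- tibble(
        file = fname, sample_id = m$sample_id, scan_time = s$scan_time[[i]],
        group_id = m$group_id, class_label = m$class_label,
        modality = m$modality
      )
    }
  }
  utils::write.table(dplyr::bind_rows(rows), file.path(dir, "meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
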
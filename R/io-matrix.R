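#' Read a feature matrix from delimited text
#'
#' Reads a samples-by-bins table.  Bin columns are identified by the
#' `mz_` name prefix (the canonical layout written by [write_matrix()]);
#' alternatively `layout$bin_cols` can name them explicitly, and
#' `layout$rename` can map arbitrary metadata column names onto the
#' canonical ones (`sample_id`, `group_id`, `class_label`, `modality`).
#' A composition column holding strings such as `"90/10"` is parsed via
#' [parse_composition()] when `layout$composition_col` and
#' `layout$components` are given; the fraction of `layout$tumor_component`
#' (default `"tumor"`) is then exposed as `tumor_fraction`.
#'
#' @param path Delimited text file (TSV or CSV, decided by extension or
#'   `layout$sep`).
#' @param layout List of layout options, see Details.
#' @return A feature-matrix tibble.
#' @export
read_matrix <- function(path, layout = list()) {
  if (!file.exists(path)) abort(sprintf("File '%s' not found.", path))
  sep <- layout$sep %||% if (grepl("\\.csv$", path)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, fill = FALSE,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) {
      abort(sprintf("Malformed table '%s': %s", basename(path),
                    conditionMessage(e)))
    }
  )
  if (!is.null(layout$rename)) {
    for (canon in names(layout$rename)) {
      names(df)[names(df) == layout$rename[[canon]]] <- canon
    }
  }
  bin_names <- layout$bin_cols %||% grep("^mz_", names(df), value = TRUE)
  if (!length(bin_names)) {
    abort("No bin columns found (expected names starting with 'mz_').")
  }
  vals <- as.matrix(df[, bin_names, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) abort("Bin columns contain non-numeric values.")
  if (any(vals < 0)) {
    bad <- which(rowSums(vals < 0) > 0)[1]
    abort(sprintf("Negative intensity in row %d.", bad))
  }
  edges <- as.numeric(sub("^mz_", "", bin_names))
  ord <- order(edges)
  meta <- as_tibble(df[, setdiff(names(df), bin_names), drop = FALSE])
  if (!"sample_id" %in% names(meta)) {
    meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  }
  meta$sample_id <- as.character(meta$sample_id)
  comp_col <- layout$composition_col
  if (!is.null(comp_col) && comp_col %in% names(meta) &&
      !is.null(layout$components)) {
    comp <- parse_composition(meta[[comp_col]], layout$components)
    meta$composition <- comp
    tumor <- layout$tumor_component %||% "tumor"
    meta$tumor_fraction <- vapply(
      comp, function(x) if (is.null(x)) NA_real_ else unname(x[tumor]),
      numeric(1)
    )
  }
  feature_matrix(vals[, ord, drop = FALSE], edges[ord], meta)
}

#' Write a feature matrix as delimited text
#'
#' Writes metadata columns followed by `mz_*` bin columns at full double
#' precision, so that `read_matrix(write_matrix(x))` reproduces the
#' intensities exactly.  List-columns (e.g. `composition`) are dropped
#' with a message; `tumor_fraction` carries the mixture information in
#' flat form.
#'
#' @param x A feature-matrix tibble.
#' @param path Output file (`.csv` for comma-separated, anything else is
#'   tab-separated).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    inform(sprintf("Dropping list column(s) on write: %s",
                   paste(names(x)[is_list], collapse = ", ")))
    x <- x[, !is_list, drop = FALSE]
  }
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
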
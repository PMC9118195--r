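#' Construct an MSI dataset
#'
#' A mass-spectrometry-imaging dataset: one spectrum per occupied pixel of
#' an integer grid.  Stored as a tibble with columns `x`, `y` (1-based
#' grid indices) and a `peaks` list-column of [spectrum()] objects.  The
#' grid may be sparse: missing pixels are absent rows, never zero spectra.
#'
#' @param pixels Tibble with columns `x`, `y`, `peaks`.
#' @param pixel_size Pixel edge length in micrometres.
#' @return An `msi_dataset` tibble.
#' @export
msi_dataset <- function(pixels, pixel_size = 30) {
  stopifnot(all(c("x", "y", "peaks") %in% names(pixels)))
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (anyDuplicated(pixels[, c("x", "y")])) {
    abort("Pixel coordinates must be unique.")
  }
  out <- as_tibble(pixels)
  out$x <- as.integer(out$x)
  out$y <- as.integer(out$y)
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("msi_dataset", class(out))
  out
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(
    "<msi_dataset: %d pixels on a %d x %d grid, pixel %g um>\n",
    nrow(x), max(x$x), max(x$y), pixel_size(x)
  ))
  NextMethod()
}

#' Pixel size of an MSI dataset
#' @param x An `msi_dataset`.
#' @return Pixel edge length in micrometres.
#' @export
pixel_size <- function(x) attr(x, "pixel_size") %||% NA_real_

ibd_uuid <- function() as.raw(c(
  0x76, 0x61, 0x70, 0x6f, 0x72, 0x63, 0x6c, 0x61,
  0x73, 0x73, 0x00, 0x00, 0x00, 0x00, 0x00, 0x01
))

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write an MSI dataset as an imzML/ibd pair
#'
#' Writes the "processed" imzML layout (per-pixel m/z and intensity arrays,
#' 64-bit floats, no compression, external binary `.ibd` file).  Only the
#' subset of the standard needed to round-trip [read_imzml()] is emitted.
#'
#' @param data An [msi_dataset()].
#' @param path Output `.imzML` path; the `.ibd` companion is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(data, path) {
  p <- imzml_paths(path)
  con <- file(p$ibd, "wb")
  writeBin(ibd_uuid(), con)
  offset <- 16
  entries <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    sp <- data$peaks[[i]]
    writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
    writeBin(as.numeric(sp$intensity), con, size = 8, endian = "little")
    n <- nrow(sp)
    entries[[i]] <- list(
      x = data$x[[i]], y = data$y[[i]], n = n,
      mz_off = offset, int_off = offset + 8 * n
    )
    offset <- offset + 16 * n
  }
  close(con)

  arr <- function(acc, name, off, n) sprintf(
    '<binaryDataArray encodedLength="0"><cvParam cvRef="MS" accession="%s" name="%s"/><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/><cvParam cvRef="MS" accession="MS:1000576" name="no compression"/><cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/><binary/></binaryDataArray>',
    acc, name, off, n, 8 * n
  )
  spectra <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    sprintf(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d"><scanList count="1"><scan><cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/></scan></scanList><binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>',
      i - 1L, i, e$n, e$x, e$y,
      arr("MS:1000514", "m/z array", e$mz_off, e$n),
      arr("MS:1000515", "intensity array", e$int_off, e$n)
    )
  }, character(1))
  doc <- sprintf(
    '<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
<fileDescription><fileContent><cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/><cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/></fileContent></fileDescription>
<scanSettingsList count="1"><scanSettings id="ss1"><cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/><cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/></scanSettings></scanSettingsList>
<run id="r1"><spectrumList count="%d">
%s
</spectrumList></run>
</mzML>',
    paste(format(ibd_uuid()), collapse = ""),
    max(data$x), max(data$y), pixel_size(data),
    length(spectra), paste(spectra, collapse = "\n")
  )
  writeLines(doc, p$xml)
  invisible(path)
}

imzml_cv <- function(node, accession) {
  v <- xml2::xml_attr(
    xml2::xml_find_first(
      node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", accession)
    ),
    "value"
  )
  v
}

#' Read an imzML/ibd pair into an MSI dataset
#'
#' Supports the "processed" layout with uncompressed 64-bit float arrays.
#' Pixels absent from the file stay absent in the returned dataset (they
#' are not filled with zeros).
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit
#'   next to it.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) abort(sprintf("File '%s' not found.", p$xml))
  if (!file.exists(p$ibd)) {
    abort(sprintf("Binary companion '%s' is missing.", p$ibd))
  }
  ibd <- readBin(p$ibd, "raw", n = file.size(p$ibd))
  doc <- xml2::read_xml(p$xml)
  px <- imzml_cv(doc, "IMS:1000046")
  px <- if (is.na(px)) 30 else as.numeric(px)
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (!length(nodes)) abort(sprintf("'%s' contains no spectra.", p$xml))
  rows <- lapply(nodes, function(node) {
    x <- as.integer(imzml_cv(node, "IMS:1000050"))
    y <- as.integer(imzml_cv(node, "IMS:1000051"))
    arrays <- xml2::xml_find_all(node, ".//*[local-name()='binaryDataArray']")
    vals <- lapply(arrays, function(a) {
      off <- as.numeric(imzml_cv(a, "IMS:1000102"))
      n <- as.numeric(imzml_cv(a, "IMS:1000103"))
      need <- off + 8 * n
      if (need > length(ibd)) {
        abort(sprintf(
          "Corrupt ibd: array needs %d bytes but '%s' has %d.",
          need, basename(p$ibd), length(ibd)
        ))
      }
      readBin(ibd[(off + 1):(off + 8 * n)], "double", n = n,
              size = 8, endian = "little")
    })
    is_mz <- vapply(arrays, function(a) {
      !is.na(xml2::xml_attr(xml2::xml_find_first(
        a, ".//*[local-name()='cvParam'][@accession='MS:1000514']"
      ), "accession"))
    }, logical(1))
    list(x = x, y = y,
         spec = spectrum(vals[[which(is_mz)]], vals[[which(!is_mz)]]))
  })
  msi_dataset(
    tibble(
      x = vapply(rows, `[[`, integer(1), "x"),
      y = vapply(rows, `[[`, integer(1), "y"),
      peaks = lapply(rows, `[[`, "spec")
    ),
    pixel_size = px
  )
}
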
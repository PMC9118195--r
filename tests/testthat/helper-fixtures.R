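# Shared fixtures and independent oracles, built in code at test time.

# Two tiny class profiles with disjoint non-zero bins on a 10-bin axis.
disjoint_profiles <- function() {
  edges <- seq(600, 600.9, by = 0.1)
  a <- c(5, 0, 3, 0, 2, 0, 0, 0, 0, 0)
  b <- c(0, 4, 0, 0, 0, 1, 0, 5, 0, 0)
  list(edges = edges, a = a / sum(a), b = b / sum(b))
}

# Feature matrix of n_a + n_b noisy samples around the two profiles,
# spread over `n_groups` groups; separation >> within-class noise.
separable_fm <- function(n_a = 10, n_b = 10, n_groups = 5, noise = 0.002,
                         seed = 42) {
  p <- disjoint_profiles()
  withr::with_seed(seed, {
    vals <- rbind(
      t(replicate(n_a, pmax(p$a + rnorm(10, sd = noise), 0))),
      t(replicate(n_b, pmax(p$b + rnorm(10, sd = noise), 0)))
    )
    vals <- vals / rowSums(vals)
    n <- n_a + n_b
    meta <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      group_id = sprintf("g%d", (seq_len(n) - 1L) %% n_groups + 1L),
      class_label = rep(c("A", "B"), c(n_a, n_b))
    )
    feature_matrix(vals, p$edges, meta)
  })
}

# Minimal valid mzML writer (centroided, 64-bit float, no compression)
# used to build text fixtures for the mzR-backed reader.
write_tiny_mzml <- function(scans, path) {
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  spec_xml <- function(i, mz, inten, rt) {
    sprintf(
      paste0(
        '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
        '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
        '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%g" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>',
        '<binaryDataArrayList count="2">',
        '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/><binary>%s</binary></binaryDataArray>',
        '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>',
        '</binaryDataArrayList></spectrum>'
      ),
      i - 1L, i, length(mz), rt,
      nchar(enc(mz)), enc(mz), nchar(enc(inten)), enc(inten)
    )
  }
  body <- vapply(seq_along(scans), function(i) {
    spec_xml(i, scans[[i]]$mz, scans[[i]]$intensity,
             scans[[i]]$rt %||% i)
  }, character(1))
  doc <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
      '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '<cv id="UO" fullName="Unit Ontology" URI="http://purl.obolibrary.org/obo/uo.obo"/></cvList>\n',
      '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>\n',
      '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>\n',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
      '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
      '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
      '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n</spectrumList>\n',
      '</run>\n</mzML>'
    ),
    length(scans), paste(body, collapse = "\n")
  )
  writeLines(doc, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exhaustive-enumeration oracle for the iterative truth-threshold ROC:
# plain loops over thresholds and samples, trapezoid AUC over points
# sorted by (fpr, tpr) with (0,0)/(1,1) anchors.  Independent of the
# package implementation.
roc_oracle <- function(f, pred) {
  fracs <- sort(unique(f))
  thetas <- fracs[fracs != max(fracs)]
  pts <- data.frame()
  for (th in thetas) {
    tp <- fn <- fp <- tn <- 0L
    for (i in seq_along(f)) {
      truth_tumor <- f[i] > th
      pred_tumor <- pred[i] == "tumor"
      if (truth_tumor && pred_tumor) tp <- tp + 1L
      if (truth_tumor && !pred_tumor) fn <- fn + 1L
      if (!truth_tumor && pred_tumor) fp <- fp + 1L
      if (!truth_tumor && !pred_tumor) tn <- tn + 1L
    }
    if ((tp + fn) == 0 || (fp + tn) == 0) next
    pts <- rbind(pts, data.frame(
      theta = th, tp = tp, fn = fn, fp = fp, tn = tn,
      tpr = tp / (tp + fn), fpr = fp / (fp + tn)
    ))
  }
  curve <- rbind(
    data.frame(fpr = 0, tpr = 0),
    pts[, c("fpr", "tpr")],
    data.frame(fpr = 1, tpr = 1)
  )
  curve <- curve[order(curve$fpr, curve$tpr), ]
  auc <- 0
  for (i in seq_len(nrow(curve) - 1)) {
    auc <- auc + (curve$fpr[i + 1] - curve$fpr[i]) *
      (curve$tpr[i] + curve$tpr[i + 1]) / 2
  }
  list(points = pts, auc = auc)
}

# Random dilution design for property tests: a few distinct fractions,
# arbitrary predictions.
random_roc_design <- function(n_max = 25) {
  n <- sample(4:n_max, 1)
  n_frac <- sample(2:5, 1)
  fracs <- sort(sample(c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 1), n_frac))
  f <- sample(fracs, n, replace = TRUE)
  while (length(unique(f)) < 2) f <- sample(fracs, n, replace = TRUE)
  pred <- sample(c("tumor", "muscle"), n, replace = TRUE)
  list(f = f, pred = pred)
}
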
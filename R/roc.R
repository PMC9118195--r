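#' Binary truth labels for a dilution series
#'
#' Implements the labelling rule of the dilution model: a sample is
#' "muscle" only when it contains no tumor cells at all, and "tumor" when
#' its tumor fraction reaches the design cutoff (10% in the assay).
#' Fractions strictly between zero and the cutoff fall in neither class;
#' they are labelled `"indeterminate"` and should be excluded from model
#' training (a message reports how many).
#'
#' @param fractions Numeric tumor fractions in `[0, 1]`.
#' @param cutoff Smallest fraction labelled tumor, in `(0, 1]`.
#' @param positive,negative Label strings.
#' @return Character vector of labels.
#' @examples
#' assign_binary_labels(c(1, 0.5, 0.25, 0.10, 0))
#' @export
assign_binary_labels <- function(fractions, cutoff = 0.10,
                                 positive = "tumor", negative = "muscle") {
  if (cutoff <= 0 || cutoff > 1) abort("`cutoff` must be in (0, 1].")
  if (!length(fractions)) return(character())
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE)) {
    abort("Tumor fractions must lie in [0, 1].")
  }
  out <- ifelse(fractions >= cutoff, positive,
                ifelse(fractions == 0, negative, "indeterminate"))
  n_ind <- sum(out == "indeterminate", na.rm = TRUE)
  if (n_ind) {
    inform(sprintf(
      "%d sample(s) with 0 < fraction < %g are indeterminate; exclude them from training.",
      n_ind, cutoff
    ))
  }
  out
}

#' Iterative truth-threshold ROC for a dilution series
#'
#' The classifier's predicted labels stay fixed while the ground-truth
#' boundary between tumor and muscle is swept across the known dilution
#' fractions: at truth threshold `theta` a sample counts as truly tumor
#' iff its tumor fraction exceeds `theta` (strictly), so at `theta = 0.10`
#' the 10% mixtures predicted as muscle count as correctly classified.
#' One (FPR, TPR) point with its full 2x2 confusion is produced per
#' threshold (the distinct fractions except the largest); the curve is
#' anchored at (0,0) and (1,1) and the AUC is the trapezoid area over the
#' points sorted by FPR.  The AUC standard error uses the Hanley-McNeil
#' formula with the class sizes at the lowest threshold.
#'
#' @param data Tibble of dilution samples.
#' @param fraction_col Column with the known tumor fraction.
#' @param predicted_col Column with the fixed predicted labels.
#' @param positive,negative The two label values.
#' @return A `roc_curve`: list with `points` (tibble: `theta`, `tp`,
#'   `fn`, `fp`, `tn`, `tpr`, `fpr`), `curve` (points plus anchors,
#'   sorted), `auc`, `auc_se`, `fractions` (sorted distinct design
#'   fractions) and `n`.
#' @export
iterative_roc <- function(data, fraction_col = "tumor_fraction",
                          predicted_col = ".pred_class",
                          positive = "tumor", negative = "muscle") {
  f <- data[[fraction_col]]
  pred <- as.character(data[[predicted_col]])
  if (anyNA(f) || anyNA(pred)) abort("Fractions and predictions must be complete.")
  bad <- setdiff(unique(pred), c(positive, negative))
  if (length(bad)) {
    abort(sprintf("Unexpected predicted label '%s'.", bad[[1]]))
  }
  fracs <- sort(unique(f))
  if (length(fracs) < 2) {
    abort("Need at least two distinct dilution fractions.")
  }
  thresholds <- fracs[-length(fracs)]
  pts <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[[i]]
    truth_pos <- f > th
    if (!any(truth_pos) || all(truth_pos)) {
      inform(sprintf("Threshold %g leaves an empty truth class; skipped.", th))
      next
    }
    tp <- sum(truth_pos & pred == positive)
    fn <- sum(truth_pos & pred == negative)
    fp <- sum(!truth_pos & pred == positive)
    tn <- sum(!truth_pos & pred == negative)
    pts[[i]] <- tibble(
      theta = th, tp = tp, fn = fn, fp = fp, tn = tn,
      tpr = tp / (tp + fn), fpr = fp / (fp + tn)
    )
  }
  pts <- dplyr::bind_rows(pts)
  if (!nrow(pts)) abort("Degenerate design: every threshold was skipped.")
  curve <- dplyr::arrange(
    dplyr::bind_rows(
      tibble(theta = NA_real_, tp = NA_integer_, fn = NA_integer_,
             fp = NA_integer_, tn = NA_integer_, tpr = 0, fpr = 0),
      pts,
      tibble(theta = NA_real_, tp = NA_integer_, fn = NA_integer_,
             fp = NA_integer_, tn = NA_integer_, tpr = 1, fpr = 1)
    ),
    .data$fpr, .data$tpr
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  first <- pts[which.min(pts$theta), ]
  n1 <- first$tp + first$fn
  n2 <- first$fp + first$tn
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  structure(
    list(points = pts, curve = curve, auc = auc, auc_se = auc_se,
         fractions = fracs, n = length(f),
         positive = positive, negative = negative),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.3f +/- %.3f over %d samples, %d thresholds>\n",
              x$auc, x$auc_se, x$n, nrow(x$points)))
  print(x$points)
  invisible(x)
}

#' Best operating cutoff of an iterative ROC curve
#'
#' Selects the truth threshold with the highest true positive rate
#' together with the lowest false positive rate, i.e. the threshold
#' maximising Youden's J = TPR - FPR.  Ties go to the smaller (more
#' sensitive) threshold, with a message.
#'
#' @param roc A `roc_curve`.
#' @return The selected threshold (a tumor fraction).
#' @export
best_cutoff <- function(roc) {
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1) {
    inform("Several thresholds tie on Youden's J; smallest kept.")
  }
  min(pts$theta[best])
}

#' Limit of detection from an iterative ROC curve
#'
#' The smallest non-zero design fraction `f` such that the truth
#' threshold immediately below `f` reaches the required sensitivity and
#' specificity: at that threshold, mixtures with at least `f` tumor cells
#' count as truly tumor, so TPR is the rate at which they are detected.
#'
#' @param roc A `roc_curve`.
#' @param min_tpr Required sensitivity (true positive rate).
#' @param min_specificity Required specificity (one minus FPR).
#' @return The detection limit as a tumor fraction, or `NA` if no design
#'   fraction qualifies.
#' @export
detection_limit <- function(roc, min_tpr = 0.8, min_specificity = 0.8) {
  if (min_tpr <= 0 && min_specificity <= 0) {
    # vacuous bounds: every fraction qualifies
  }
  fracs <- roc$fractions
  for (f in sort(fracs[fracs > 0])) {
    below <- roc$points$theta[roc$points$theta < f]
    if (!length(below)) next
    pt <- roc$points[roc$points$theta == max(below), ]
    if (nrow(pt) && pt$tpr >= min_tpr && (1 - pt$fpr) >= min_specificity) {
      return(f)
    }
  }
  NA_real_
}

#' Score-based ROC curve (continuous mode)
#'
#' Alternative to the hard-label [iterative_roc()]: when the classifier
#' emits a continuous tumor score, a conventional ROC over that score is
#' computed (via pROC) against the binary truth labels from
#' [assign_binary_labels()].
#'
#' @param data Tibble of dilution samples.
#' @param score_col Column with the continuous tumor score.
#' @param fraction_col Column with the known tumor fraction.
#' @param cutoff Truth cutoff passed to [assign_binary_labels()].
#' @return A list with `points` (tibble of `threshold`, `tpr`, `fpr`),
#'   `auc` and `n`.
#' @export
score_roc <- function(data, score_col = ".score_tumor",
                      fraction_col = "tumor_fraction", cutoff = 0.10) {
  if (!requireNamespace("pROC", quietly = TRUE)) {
    abort("Score-mode ROC requires the pROC package.")
  }
  truth <- assign_binary_labels(data[[fraction_col]], cutoff)
  keep <- truth != "indeterminate"
  r <- pROC::roc(
    response = truth[keep], predictor = data[[score_col]][keep],
    levels = c("muscle", "tumor"), direction = "<", quiet = TRUE
  )
  list(
    points = tibble(
      threshold = r$thresholds,
      tpr = r$sensitivities,
      fpr = 1 - r$specificities
    ),
    auc = as.numeric(r$auc),
    n = sum(keep)
  )
}
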
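#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_pca `tidy()` returns one row per component with its
#'   explained variance ratio.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.pca_model <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_len(x$n_pc)),
    explained_variance_ratio = x$explained_variance_ratio
  )
}

#' @describeIn fit_pca `glance()` returns a one-row model summary.
#' @export
glance.pca_model <- function(x, ...) {
  tibble(
    n_pc = x$n_pc,
    n_bins = nrow(x$loadings),
    variance_captured = sum(x$explained_variance_ratio)
  )
}

#' @describeIn fit_pca_lda `tidy()` returns the class centroids in
#'   discriminant space, one row per class.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.pca_lda_model <- function(x, ...) {
  cent <- x$class_centroids
  colnames(cent) <- paste0("LD", seq_len(ncol(cent)))
  dplyr::bind_cols(tibble(class = rownames(cent)), as_tibble(cent))
}

#' @describeIn fit_pca_lda `glance()` returns a one-row model summary.
#' @export
glance.pca_lda_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes), n_pc = x$n_pc, n_ld = x$n_ld,
    variance_captured = sum(x$pca$explained_variance_ratio)
  )
}

#' @describeIn cross_validate_logo `tidy()` returns the pooled per-sample
#'   predictions.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) as_tibble(x$predictions)

#' @describeIn cross_validate_logo `glance()` returns accuracy, sample
#'   and fold counts.
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, n = sum(x$confusion),
    n_folds = length(x$per_fold), n_classes = nrow(x$confusion)
  )
}

#' @describeIn iterative_roc `tidy()` returns the per-threshold points
#'   with their confusion counts.
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @describeIn iterative_roc `glance()` returns AUC, its standard error,
#'   the best cutoff and the sample count.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(
    auc = x$auc, auc_se = x$auc_se, best_cutoff = best_cutoff(x),
    n = x$n, n_thresholds = nrow(x$points)
  )
}
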
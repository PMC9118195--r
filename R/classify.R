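fix_signs <- function(m) {
  for (j in seq_len(ncol(m))) {
    if (m[which.max(abs(m[, j])), j] < 0) m[, j] <- -m[, j]
  }
  m
}

#' Fit a principal component analysis model
#'
#' Centered-data singular value decomposition over the `mz_*` bin columns
#' of a feature matrix.  Loadings follow a deterministic sign convention:
#' the largest-magnitude element of every component is positive, so score
#' plots are reproducible across runs and platforms.
#'
#' @param x A feature-matrix tibble.
#' @param n_pc Number of components to keep; at most
#'   `min(n_samples - 1, n_bins)`.
#' @return A `pca_model` with elements `mean`, `loadings` (bins by
#'   components, orthonormal), `explained_variance_ratio` (fractions of
#'   the total variance), `edges` and `n_pc`.
#' @export
fit_pca <- function(x, n_pc = 10) {
  vals <- fm_values(x)
  max_pc <- min(nrow(vals) - 1L, ncol(vals))
  if (n_pc > max_pc) {
    abort(sprintf("`n_pc` = %d exceeds the maximum %d for this matrix.",
                  n_pc, max_pc))
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  loadings <- fix_signs(pc$rotation[, seq_len(n_pc), drop = FALSE])
  structure(
    list(
      mean = pc$center,
      loadings = loadings,
      explained_variance_ratio = pc$sdev[seq_len(n_pc)]^2 / total_var,
      edges = bin_edges(x),
      n_pc = n_pc
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model: %d components over %d bins; variance captured %.1f%%>\n",
    x$n_pc, nrow(x$loadings), 100 * sum(x$explained_variance_ratio)
  ))
  invisible(x)
}

#' Project samples into PCA space
#' @param model A `pca_model`.
#' @param x A feature-matrix tibble on the same bin axis.
#' @return Tibble of per-sample scores (`sample_id`, `PC1`, `PC2`, ...).
#' @export
pca_scores <- function(model, x) {
  vals <- fm_values(x)
  if (ncol(vals) != nrow(model$loadings)) {
    abort("Bin axis of `x` does not match the model; see harmonize_bins().")
  }
  sc <- sweep(vals, 2, model$mean) %*% model$loadings
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  dplyr::bind_cols(tibble(sample_id = x$sample_id), as_tibble(sc))
}

#' Fit a PCA-LDA classifier
#'
#' Principal component scores are fed to Fisher linear discriminant
#' analysis: the discriminant directions maximise between-class over
#' within-class scatter, with a small ridge (1e-6) added to the diagonal
#' of the pooled within-class scatter for numerical stability.  Class
#' centroids are stored in discriminant space and classification is by
#' nearest centroid.
#'
#' @param x A feature-matrix tibble.
#' @param class_col Metadata column holding class labels.
#' @param n_pc Number of principal components (the tissue and cell models
#'   use 10).
#' @param n_ld Number of discriminant axes; at most `n_classes - 1`
#'   (default).
#' @param ridge Ridge added to the within-class scatter diagonal.
#' @return A `pca_lda_model`.
#' @export
fit_pca_lda <- function(x, class_col = "class_label", n_pc = 10,
                        n_ld = NULL, ridge = 1e-6) {
  labels <- as.character(x[[class_col]])
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("Need at least two classes.")
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(sprintf("Every class needs >= 2 samples (class '%s' has %d).",
                  names(counts)[which.min(counts)], min(counts)))
  }
  n_ld <- n_ld %||% (length(classes) - 1L)
  if (n_ld > length(classes) - 1L) {
    abort(sprintf("`n_ld` = %d exceeds n_classes - 1 = %d.",
                  n_ld, length(classes) - 1L))
  }
  n_pc <- min(n_pc, nrow(x) - 1L, length(bin_cols(x)))
  if (n_ld > n_pc) abort("`n_ld` cannot exceed `n_pc`.")
  pca <- fit_pca(x, n_pc)
  sc <- as.matrix(pca_scores(pca, x)[, -1, drop = FALSE])

  grand <- colMeans(sc)
  sw <- matrix(0, n_pc, n_pc)
  sb <- matrix(0, n_pc, n_pc)
  for (cl in classes) {
    rows <- sc[labels == cl, , drop = FALSE]
    mu <- colMeans(rows)
    dev <- sweep(rows, 2, mu)
    sw <- sw + crossprod(dev)
    sb <- sb + nrow(rows) * tcrossprod(mu - grand)
  }
  sw <- sw / (nrow(sc) - length(classes))
  diag(sw) <- diag(sw) + ridge
  dec <- tryCatch(
    eigen(solve(sw, sb)),
    error = function(e) {
      abort(sprintf(
        "Within-class scatter is singular despite ridge (classes: %s).",
        paste(classes, collapse = ", ")
      ))
    }
  )
  w <- fix_signs(Re(dec$vectors[, seq_len(n_ld), drop = FALSE]))
  proj <- sc %*% w
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(proj[labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  structure(
    list(
      pca = pca, lda_weights = w, class_centroids = centroids,
      classes = classes, n_pc = n_pc, n_ld = n_ld,
      class_col = class_col
    ),
    class = "pca_lda_model"
  )
}

#' @export
print.pca_lda_model <- function(x, ...) {
  cat(sprintf(
    "<pca_lda_model: %d classes (%s), %d PC, %d LD>\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$n_pc, x$n_ld
  ))
  invisible(x)
}

#' Classify samples with a fitted PCA-LDA model
#'
#' Samples are centred, projected through the PCA loadings and the
#' discriminant weights, and assigned to the nearest class centroid
#' (Euclidean distance; ties go to the lexicographically first class,
#' with a message).  Per-class scores are the softmin of the centroid
#' distances and sum to one for every sample.
#'
#' @param object A `pca_lda_model`.
#' @param newdata A feature-matrix tibble on the model's bin axis.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `.pred_class` and one `.score_*`
#'   column per class.
#' @export
predict.pca_lda_model <- function(object, newdata, ...) {
  vals <- fm_values(newdata)
  if (ncol(vals) != nrow(object$pca$loadings)) {
    abort("Bin axis of `newdata` does not match the model; see harmonize_bins().")
  }
  proj <- sweep(vals, 2, object$pca$mean) %*%
    object$pca$loadings %*% object$lda_weights
  cent <- object$class_centroids
  d2 <- sapply(seq_len(nrow(cent)), function(k) {
    rowSums(sweep(proj, 2, cent[k, ])^2)
  })
  d2 <- matrix(d2, nrow = nrow(proj))
  d <- sqrt(d2)
  ties <- apply(d, 1, function(r) sum(r - min(r) < 1e-12) > 1)
  if (any(ties)) {
    inform(sprintf(
      "%d sample(s) equidistant from several centroids; first class by lexicographic order assigned.",
      sum(ties)
    ))
  }
  pred <- object$classes[apply(d, 1, which.min)]
  sm <- exp(-sweep(d, 1, apply(d, 1, min)))
  sm <- sm / rowSums(sm)
  colnames(sm) <- paste0(".score_", object$classes)
  dplyr::bind_cols(
    tibble(sample_id = newdata$sample_id, .pred_class = pred),
    as_tibble(sm)
  )
}

#' Leave-one-group-out cross-validation of a PCA-LDA classifier
#'
#' One fold per distinct group (patient for tissue data, biological
#' replicate for cell pellets).  The model is refitted on the remaining
#' groups and the held-out group is predicted; pooled predictions form a
#' single confusion matrix.  Deterministic given its inputs.
#'
#' @param x A feature-matrix tibble.
#' @param class_col,group_col Metadata columns with class labels and
#'   group identifiers.
#' @param n_pc,n_ld,ridge Passed to [fit_pca_lda()].
#' @return A `cv_result` with elements `confusion` (actual by predicted
#'   counts), `accuracy`, `predictions` (per-sample tibble) and
#'   `per_fold`.
#' @export
cross_validate_logo <- function(x, class_col = "class_label",
                                group_col = "group_id", n_pc = 10,
                                n_ld = NULL, ridge = 1e-6) {
  groups <- as.character(x[[group_col]])
  labels <- as.character(x[[class_col]])
  classes <- sort(unique(labels))
  fold_ids <- sort(unique(groups))
  if (length(fold_ids) < 2) abort("Need at least two groups for LOGO-CV.")
  preds <- vector("list", length(fold_ids))
  for (i in seq_along(fold_ids)) {
    g <- fold_ids[[i]]
    train <- x[groups != g, , drop = FALSE]
    test <- x[groups == g, , drop = FALSE]
    missing <- setdiff(classes, unique(as.character(train[[class_col]])))
    if (length(missing)) {
      abort(sprintf(
        "Fold '%s' would leave no training samples of class '%s'.",
        g, missing[[1]]
      ))
    }
    fit <- fit_pca_lda(train, class_col, n_pc = n_pc, n_ld = n_ld,
                       ridge = ridge)
    p <- stats::predict(fit, test)
    p$fold <- g
    p$actual <- as.character(test[[class_col]])
    preds[[i]] <- p
  }
  predictions <- dplyr::bind_rows(preds)
  confusion <- table(
    actual = factor(predictions$actual, classes),
    predicted = factor(predictions$.pred_class, classes)
  )
  structure(
    list(
      confusion = unclass(confusion),
      accuracy = confusion_accuracy(unclass(confusion)),
      predictions = predictions,
      per_fold = split(predictions$.pred_class, predictions$fold)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: accuracy %.3f over %d samples, %d folds>\n",
              x$accuracy, sum(x$confusion), length(x$per_fold)))
  print(x$confusion)
  invisible(x)
}

#' Accuracy of a confusion matrix
#'
#' @param confusion Square actual-by-predicted count matrix.
#' @return Fraction of counts on the diagonal.
#' @examples
#' confusion_accuracy(matrix(c(8, 3, 2, 7), 2))
#' @export
confusion_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    abort("Confusion matrix must be square.")
  }
  total <- sum(confusion)
  if (total == 0) abort("Confusion matrix has no counts.")
  sum(diag(confusion)) / total
}

#' Restrict two feature matrices to a common bin axis
#'
#' Both matrices are cut down to the bins they share (matched by the
#' canonical bin-column names, which requires equal bin width) and every
#' row is re-normalized to unit TIC on the common range.  This enables
#' cross-modality prediction, e.g. applying a classifier trained on one
#' platform's m/z 100-1500 profiles to another platform's 600-1000
#' profiles.
#'
#' @param a,b Feature-matrix tibbles.
#' @return A list with elements `a` and `b` on the shared axis.
#' @export
harmonize_bins <- function(a, b) {
  wa <- bin_width(a)
  wb <- bin_width(b)
  if (is.finite(wa) && is.finite(wb) && abs(wa - wb) > 1e-9) {
    abort("Bin widths differ; matrices cannot be harmonized.")
  }
  common <- intersect(bin_cols(a), bin_cols(b))
  if (!length(common)) abort("Bin axes do not overlap.")
  common <- common[order(as.numeric(sub("^mz_", "", common)))]
  cut <- function(x) {
    keep <- c(setdiff(names(x), bin_cols(x)), common)
    out <- x[, keep, drop = FALSE]
    vals <- fm_values(out)
    sums <- rowSums(vals)
    if (any(sums <= 0)) abort("A sample has zero intensity on the common axis.")
    out[, common] <- as_tibble(vals / sums, .name_repair = "minimal")
    out
  }
  list(a = cut(a), b = cut(b))
}
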
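#' Linear unmixing of mixture spectra against pure profiles
#'
#' Estimates the composition of each mixture spectrum as the convex
#' combination of pure class profiles that best fits it in least squares:
#' minimise \eqn{\lVert s - P w \rVert_2} subject to \eqn{w \ge 0} and
#' \eqn{\sum w = 1}.  Solved exactly by enumerating candidate support
#' sets: for every non-empty subset of components the sum-constrained
#' least-squares problem is solved in closed form (KKT system) and the
#' best non-negative solution is kept.  Exact and robust for the small
#' numbers of pure profiles used in practice (the cost grows as
#' \eqn{2^k}).
#'
#' @param x Mixture spectra: a feature-matrix tibble (one row per
#'   mixture) or a single `binned_vector`.
#' @param pure Pure profiles: a feature-matrix tibble with one row per
#'   component and component names in `class_label`.  All profiles must
#'   be TIC-normalized and share the bin axis of `x`.
#' @return A tibble with `sample_id`, one weight column per component,
#'   and `residual` (L2 norm of the fit residual).
#' @examples
#' edges <- seq(600, 600.9, by = 0.1)
#' a <- c(5, 0, 3, 0, 2, 0, 0, 0, 0, 0); a <- a / sum(a)
#' b <- c(0, 4, 0, 0, 0, 1, 0, 5, 0, 0); b <- b / sum(b)
#' pure <- feature_matrix(rbind(a, b), edges,
#'   tibble::tibble(sample_id = c("A", "B"), class_label = c("A", "B")))
#' mix <- feature_matrix(rbind(0.3 * a + 0.7 * b), edges,
#'   tibble::tibble(sample_id = "m1"))
#' unmix(mix, pure)
#' @export
unmix <- function(x, pure) {
  if (inherits(x, "binned_vector")) {
    x <- feature_matrix(matrix(as.numeric(x), nrow = 1),
                        attr(x, "edges"), tibble(sample_id = "s1"))
  }
  if (nrow(pure) < 2) abort("Need at least two pure profiles.")
  if (!identical(bin_cols(x), bin_cols(pure))) {
    abort("Mixtures and pure profiles must share one bin axis; see harmonize_bins().")
  }
  p <- t(fm_values(pure))
  components <- as.character(pure$class_label)
  colnames(p) <- components
  cors <- stats::cor(p)
  if (any(cors[upper.tri(cors)] > 1 - 1e-9)) {
    warn("Pure profiles are collinear; the unmixing problem is ill-posed.")
  }
  k <- ncol(p)
  gram <- crossprod(p)
  vals <- fm_values(x)
  supports <- lapply(seq_len(2^k - 1), function(m) {
    which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
  })
  rows <- lapply(seq_len(nrow(vals)), function(i) {
    s <- vals[i, ]
    pts <- crossprod(p, s)
    best <- NULL
    best_obj <- Inf
    for (sup in supports) {
      ks <- length(sup)
      # minimise |s - P_S w|^2 with sum(w) = 1 via the KKT system
      kkt <- rbind(cbind(2 * gram[sup, sup, drop = FALSE], 1),
                   c(rep(1, ks), 0))
      sol <- tryCatch(solve(kkt, c(2 * pts[sup], 1)), error = function(e) NULL)
      if (is.null(sol)) next
      w_s <- sol[seq_len(ks)]
      if (any(w_s < -1e-9)) next
      w <- numeric(k)
      w[sup] <- pmax(w_s, 0)
      w <- w / sum(w)
      obj <- sum((s - as.numeric(p %*% w))^2)
      if (obj < best_obj - 1e-15) {
        best_obj <- obj
        best <- w
      }
    }
    res <- sqrt(best_obj)
    out <- c(as.list(stats::setNames(best, components)), residual = res)
    as_tibble(out)
  })
  dplyr::bind_cols(
    tibble(sample_id = x$sample_id),
    dplyr::bind_rows(rows)
  )
}
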
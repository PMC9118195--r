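test_that("PCA finds a 1-D structure and matches the eigen oracle", {
  # points exactly on a line in 3-D
  edges <- c(600, 600.1, 600.2)
  t_line <- seq(-1, 1, length.out = 8)
  vals <- outer(t_line, c(1, 2, -1)) + 5
  fm <- feature_matrix(pmax(vals, 0), edges,
                       tibble::tibble(sample_id = sprintf("s%d", 1:8)))
  pc <- fit_pca(fm, 3)
  expect_equal(pc$explained_variance_ratio[[1]], 1)
  expect_equal(pc$explained_variance_ratio[2:3], c(0, 0), tolerance = 1e-12)

  # loadings orthonormality
  g <- crossprod(pc$loadings)
  expect_equal(g, diag(3), tolerance = 1e-8, ignore_attr = TRUE)

  # reconstruction with all components reproduces the input
  sc <- as.matrix(pca_scores(pc, fm)[, -1])
  rec <- sweep(sc %*% t(pc$loadings), 2, pc$mean, `+`)
  expect_equal(unname(rec), unname(fm_values(fm)), tolerance = 1e-8)
})

test_that("PCA component variances equal the covariance eigenvalues", {
  withr::with_seed(21, vals <- matrix(rexp(20 * 5), nrow = 20))
  fm <- feature_matrix(vals, seq(600, 600.4, by = 0.1),
                       tibble::tibble(sample_id = sprintf("s%d", 1:20)))
  pc <- fit_pca(fm, 5)
  ev <- eigen(stats::cov(vals), symmetric = TRUE)$values
  expect_equal(pc$explained_variance_ratio, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  expect_error(fit_pca(fm, 6), "exceeds")
})

test_that("PCA sign convention makes the largest loading element positive", {
  withr::with_seed(2, vals <- matrix(runif(60), nrow = 12))
  fm <- feature_matrix(vals, seq(600, 600.4, by = 0.1),
                       tibble::tibble(sample_id = sprintf("s%d", 1:12)))
  pc <- fit_pca(fm, 4)
  for (j in 1:4) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("PCA-LDA separates disjoint-bin classes perfectly", {
  fm <- separable_fm(12, 12)
  fit <- fit_pca_lda(fm, n_pc = 5)
  pred <- predict(fit, fm)
  expect_equal(pred$.pred_class, fm$class_label)
  expect_equal(rowSums(as.matrix(pred[, c(".score_A", ".score_B")])),
               rep(1, 24), tolerance = 1e-12)
})

test_that("PCA-LDA enforces the discriminant dimension bound", {
  fm <- separable_fm(12, 12)
  expect_error(fit_pca_lda(fm, n_ld = 2), "n_classes - 1")
  expect_error(fit_pca_lda(fm[c(1, 13:24), ], n_pc = 3), ">= 2 samples")
  one_class <- fm
  one_class$class_label <- "A"
  expect_error(fit_pca_lda(one_class), "two classes")
})

test_that("prediction ties go to the lexicographically first class", {
  p <- disjoint_profiles()
  fm <- feature_matrix(
    rbind(p$a, p$a * 0.98 + p$b * 0.02, p$b, p$b * 0.98 + p$a * 0.02),
    p$edges,
    tibble::tibble(sample_id = sprintf("s%d", 1:4),
                   class_label = c("A", "A", "B", "B"))
  )
  fit <- fit_pca_lda(fm, n_pc = 2)
  # exact midpoint of the two centroids projects equidistantly
  mid <- feature_matrix(rbind((p$a + p$b) / 2), p$edges,
                        tibble::tibble(sample_id = "mid"))
  expect_message(pred <- predict(fit, mid), "equidistant")
  expect_equal(pred$.pred_class, "A")
})

test_that("label-shuffled training stays near chance on held-out groups", {
  fm <- separable_fm(100, 100, n_groups = 5, seed = 9)
  accs <- vapply(1:3, function(r) {
    fm$class_label <- withr::with_seed(10 + r, sample(fm$class_label))
    cross_validate_logo(fm, n_pc = 5)$accuracy
  }, numeric(1))
  # binomial 99% band around 0.5 for n = 200 (averaging over three
  # permutations damps the per-cluster majority-tracking inflation)
  half_width <- 2.576 * sqrt(0.25 / 200)
  expect_gt(mean(accs), 0.5 - half_width)
  expect_lt(mean(accs), 0.5 + half_width)
})

test_that("LOGO-CV matches running the folds by hand", {
  fm <- separable_fm(9, 9, n_groups = 3, noise = 0.01, seed = 5)
  cv <- cross_validate_logo(fm, n_pc = 4)
  manual <- lapply(sort(unique(fm$group_id)), function(g) {
    fit <- fit_pca_lda(fm[fm$group_id != g, ], n_pc = 4)
    p <- predict(fit, fm[fm$group_id == g, ])
    p$actual <- fm$class_label[fm$group_id == g]
    p
  })
  manual <- dplyr::bind_rows(manual)
  man_conf <- unclass(table(
    actual = factor(manual$actual, c("A", "B")),
    predicted = factor(manual$.pred_class, c("A", "B"))
  ))
  expect_identical(cv$confusion, man_conf)
  expect_equal(cv$accuracy, confusion_accuracy(man_conf))
})

test_that("LOGO-CV with singleton groups equals leave-one-sample-out", {
  fm <- separable_fm(8, 8, n_groups = 4, seed = 6)
  fm$group_id <- fm$sample_id
  cv <- cross_validate_logo(fm, n_pc = 4)
  expect_length(cv$per_fold, 16)
  expect_true(all(lengths(cv$per_fold) == 1))
  expect_equal(cv$accuracy, 1)
})

test_that("a fold that would drop a class is reported as an error", {
  fm <- separable_fm(6, 6, n_groups = 3, seed = 8)
  # put every class-A sample into group g1
  fm$group_id <- c(rep("g1", 6), rep(c("g2", "g3"), 3))
  expect_error(cross_validate_logo(fm, n_pc = 3), "class 'A'")
})

test_that("confusion accuracy equals an explicit loop count", {
  expect_equal(confusion_accuracy(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(confusion_accuracy(matrix(c(8, 3, 2, 7), 2)), 0.75)
  withr::with_seed(13, m <- matrix(rpois(25, 4), 5))
  acc <- confusion_accuracy(m)
  correct <- 0
  for (i in 1:5) for (j in 1:5) if (i == j) correct <- correct + m[i, j]
  expect_equal(acc, correct / sum(m))
  expect_error(confusion_accuracy(matrix(0, 2, 2)), "no counts")
  expect_error(confusion_accuracy(matrix(1, 2, 3)), "square")
})

test_that("CV accuracy is invariant under a consistent class relabelling", {
  fm <- separable_fm(9, 9, n_groups = 3, seed = 14)
  cv1 <- cross_validate_logo(fm, n_pc = 4)
  fm2 <- fm
  fm2$class_label <- c(A = "zz", B = "aa")[fm$class_label]
  cv2 <- cross_validate_logo(fm2, n_pc = 4)
  expect_equal(cv2$accuracy, cv1$accuracy)
  expect_equal(rowSums(cv1$confusion),
               unname(table(fm$class_label)), ignore_attr = TRUE)
})

test_that("bin harmonization restricts to the common axis and renormalizes", {
  withr::with_seed(15, {
    a_vals <- matrix(rexp(3 * 20), nrow = 3)
    b_vals <- matrix(rexp(3 * 10), nrow = 3)
  })
  a <- feature_matrix(a_vals, seq(600, 601.9, by = 0.1),
                      tibble::tibble(sample_id = sprintf("a%d", 1:3)))
  b <- feature_matrix(b_vals, seq(601, 601.9, by = 0.1),
                      tibble::tibble(sample_id = sprintf("b%d", 1:3)))
  h <- harmonize_bins(a, b)
  expect_equal(bin_edges(h$a), bin_edges(h$b))
  expect_equal(bin_edges(h$a), seq(601, 601.9, by = 0.1), tolerance = 1e-9)
  expect_equal(unname(rowSums(fm_values(h$a))), rep(1, 3))
  expect_equal(unname(rowSums(fm_values(h$b))), rep(1, 3))

  # identical axes pass through (up to renormalization of rows)
  h2 <- harmonize_bins(a, a)
  expect_equal(bin_edges(h2$a), bin_edges(a))

  c_fm <- feature_matrix(b_vals, seq(700, 700.9, by = 0.1),
                         tibble::tibble(sample_id = sprintf("c%d", 1:3)))
  expect_error(harmonize_bins(a, c_fm), "overlap")
})

test_that("tidy and glance summarise fitted models", {
  fm <- separable_fm(8, 8)
  pc <- fit_pca(fm, 3)
  td <- tidy(pc)
  expect_equal(nrow(td), 3)
  expect_equal(td$component[[1]], "PC1")
  expect_equal(glance(pc)$n_pc, 3)

  fit <- fit_pca_lda(fm, n_pc = 4)
  expect_equal(tidy(fit)$class, c("A", "B"))
  expect_equal(glance(fit)$n_ld, 1)

  cv <- cross_validate_logo(fm, n_pc = 4)
  expect_equal(nrow(tidy(cv)), 16)
  expect_equal(glance(cv)$n_folds, 5)
})
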
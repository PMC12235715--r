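test_that("winsorization matches an order-statistic oracle and its invariants", {
  # column of 99 ones and a single 1000: type-7 Q98 interpolates order stats
  x <- c(rep(1, 99), 1000)
  m <- matrix(x, ncol = 1)
  # oracle: h = (n-1)*0.98 + 1 = 98.02 -> between x_(98)=1 and x_(99)=1
  sorted <- sort(x)
  h <- (length(x) - 1) * 0.98 + 1
  q98 <- sorted[floor(h)] + (h - floor(h)) * (sorted[floor(h) + 1] - sorted[floor(h)])
  expect_equal(q98, 1)
  w <- winsorize(m)
  expect_equal(sum(w != m), 1)          # only the extreme entry clipped
  expect_equal(max(w), 2 * q98)

  set.seed(8)
  r <- matrix(rexp(300 * 20) + 0.5, 300, 20)
  r <- inject_outliers(r, 0.002, 40, seed = 1)
  wr <- winsorize(r)
  expect_true(all(wr <= r))             # never increases
  thr <- 2 * apply(r, 2, quantile, 0.98, names = FALSE)
  below <- sweep(r, 2, thr, "<=")
  expect_true(all(wr[below] == r[below]))  # untouched below threshold
  expect_equal(winsorize(wr), wr)          # idempotent
})

test_that("log2 transform is exact and rejects non-positive values", {
  m <- matrix(c(1, 1024, 2^12.5, 8), 2, 2)
  expect_equal(log2_transform(m), log2(m))
  expect_equal(log2_transform(matrix(1))[1], 0)
  x <- matrix(2^runif(20, -5, 5), 4, 5)
  expect_equal(2^log2_transform(x), x, tolerance = 1e-12)
  bad <- m; bad[2, 1] <- -1
  expect_error(log2_transform(bad), "row 2, column 1")
})

test_that("reference curves recover linear and quadratic signals", {
  set.seed(21)
  ga <- runif(60, 12, 34)
  mask <- rep(TRUE, 60)
  y_lin <- 2 + 0.3 * ga
  fit <- fit_reference_curve(y_lin, ga, mask)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_equal(predict(fit, ga), y_lin, tolerance = 1e-6)

  y_quad <- 1 + 0.5 * ga - 0.02 * ga^2
  fitq <- fit_reference_curve(y_quad, ga, mask)
  grid <- seq(min(ga), max(ga), length.out = 50)
  expect_equal(predict(fitq, grid), 1 + 0.5 * grid - 0.02 * grid^2,
               tolerance = 1e-3)
  expect_true(fitq$k %in% 3:6)
})

test_that("constant abundance gives a constant curve with r-squared zero", {
  ga <- seq(12, 34, length.out = 20)
  fit <- fit_reference_curve(rep(5, 20), ga, rep(TRUE, 20))
  expect_equal(fit$r_squared, 0)
  expect_equal(predict(fit, c(10, 20, 40)), rep(5, 3))
})

test_that("too few distinct reference ages falls back to a line with warning", {
  ga <- c(12, 15, 18, 21, 24)
  y <- 1 + 2 * ga
  expect_warning(fit <- fit_reference_curve(y, ga, rep(TRUE, 5)), "least-squares line")
  expect_equal(predict(fit, c(13, 30)), 1 + 2 * c(13, 30), tolerance = 1e-8)
})

test_that("extrapolation beyond the reference range is linear from the boundary", {
  set.seed(4)
  ga <- runif(50, 15, 30)
  y <- 3 + 0.2 * ga + 0.01 * ga^2 + rnorm(50, 0, 0.05)
  fit <- fit_reference_curve(y, ga, rep(TRUE, 50))
  b <- fit$fit_range
  lo <- predict(fit, c(b[1] - 1, b[1] - 2))
  expect_equal(lo[2] - lo[1], -(fit$boundary$lo_slope), tolerance = 1e-9)
  hi <- predict(fit, c(b[2] + 1, b[2] + 3))
  expect_equal((hi[2] - hi[1]) / 2, fit$boundary$hi_slope, tolerance = 1e-9)
})

test_that("MoM values are zero on-curve, mean-zero on reference samples, and shift-equivariant", {
  co <- small_cohort(seed = 10, n_proteins = 6, outlier_rate = 0)
  lg <- log2_transform(co$rfu)
  aga <- co$samples$group == "AGA"
  fits <- fit_reference_curves(lg, co$samples$gestational_age, aga)

  # a synthetic protein lying exactly on its fitted curve has MoM = 0
  on_curve <- vapply(names(fits), function(pr) {
    predict(fits[[pr]], co$samples$gestational_age)
  }, numeric(nrow(lg)))
  mom0 <- compute_mom(on_curve, fits, co$samples$gestational_age)
  expect_lt(max(abs(mom0)), 1e-8)

  mom <- compute_mom(lg, fits, co$samples$gestational_age)
  # residuals on the fit's own training points average to zero
  expect_lt(max(abs(colMeans(mom[aga, ]))), 1e-8)

  # +1 shift of a protein's log2 values shifts the refit curve, not the MoM
  lg2 <- lg
  lg2[, 1] <- lg[, 1] + 1
  fits2 <- fit_reference_curves(lg2, co$samples$gestational_age, aga)
  mom2 <- compute_mom(lg2, fits2, co$samples$gestational_age)
  expect_equal(mom2[, 1], mom[, 1], tolerance = 1e-6)

  expect_error(compute_mom(lg, fits[-1], co$samples$gestational_age), "PROT0001")
})

test_that("detrending removes the gestational-age trend", {
  co <- generate_cohort(cohort_config(n_proteins = 40, n_diff_lga = 0,
                                      n_diff_sga = 0, outlier_rate = 0,
                                      trend_linear_sd = 0.6, seed = 31))
  pp <- preprocess_cohort(co$rfu, co$samples)
  aga <- co$samples$group == "AGA"
  r_raw <- vapply(seq_len(40), function(j) {
    cor(pp$log2[aga, j], co$samples$gestational_age[aga])
  }, numeric(1))
  r_mom <- vapply(seq_len(40), function(j) {
    cor(pp$mom[aga, j], co$samples$gestational_age[aga])
  }, numeric(1))
  expect_gt(mean(abs(r_raw)), 0.3)      # trend is present before detrending
  expect_lt(abs(mean(r_mom)), 0.02)     # and gone after
})

test_that("the preprocessing order winsorize-log2-fit-MoM is not interchangeable", {
  co <- small_cohort(seed = 12, n_proteins = 10, outlier_rate = 0.01,
                     outlier_factor = 30)
  canonical <- preprocess_cohort(co$rfu, co$samples)
  # deliberately wrong order: log2 first, then clip on the log scale
  wrong_lg <- winsorize(log2_transform(co$rfu))
  fits_w <- fit_reference_curves(wrong_lg, co$samples$gestational_age,
                                 co$samples$group == "AGA")
  mom_w <- compute_mom(wrong_lg, fits_w, co$samples$gestational_age)
  expect_gt(max(abs(mom_w - canonical$mom)), 0.01)
})

test_that("per-visit PCA is centered, variance-ordered and equivariant", {
  co <- small_cohort(seed = 14, n_proteins = 12)
  pp <- preprocess_cohort(co$rfu, co$samples)
  pca <- pca_by_visit(pp$mom, co$samples, visit = 2)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-9)

  # rank-1 matrix: first component explains (almost) everything
  u <- rnorm(20); v <- rnorm(12)
  m1 <- outer(u, v)
  rownames(m1) <- sprintf("s%d", 1:20)
  sam <- data.frame(visit = rep(2, 20))
  p1 <- pca_by_visit(m1, sam, 2)
  expect_gt(p1$explained_variance[1], 0.999)

  # scores preserve pairwise distances of the centered data
  idx <- which(co$samples$visit == 2)
  centered <- scale(pp$mom[idx, ], center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(pca$scores)), as.matrix(dist(centered)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # permuting samples permutes scores identically
  perm <- sample(nrow(m1))
  p2 <- pca_by_visit(m1[perm, , drop = FALSE], sam, 2)
  flip <- sign(diag(cor(p1$scores[perm, 1:3], p2$scores[, 1:3])))
  expect_equal(p2$scores[, 1:3] %*% diag(flip), p1$scores[perm, 1:3],
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pca_by_visit(m1[1:2, ], sam[1:2, , drop = FALSE], 2), "at least 3")
})
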
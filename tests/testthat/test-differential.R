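test_that("per-protein OLS matches the closed-form normal equations", {
  x <- c(0.5, 1.2, 1.9, 2.4, 3.1, 4.0)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.2, 6.1)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_linear_models(matrix(y, ncol = 1, dimnames = list(NULL, "p1")), X)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients[1, ]), as.numeric(beta_oracle), tolerance = 1e-10)
  res <- y - X %*% beta_oracle
  expect_equal(unname(fit$s2), sum(res^2) / 4, tolerance = 1e-10)
  expect_equal(fit$df_residual, 4)
  expect_equal(unname(fit$unscaled_var), unname(diag(solve(t(X) %*% X))),
               tolerance = 1e-10)

  # coherent row permutation leaves everything unchanged
  perm <- c(3, 1, 6, 2, 5, 4)
  fit_p <- fit_linear_models(matrix(y[perm], ncol = 1, dimnames = list(NULL, "p1")),
                             X[perm, ])
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(fit_p$s2, fit$s2, tolerance = 1e-12)
})

test_that("rank-deficient designs and zero-residual proteins are flagged", {
  X <- cbind(intercept = 1, a = 1:6, b = 2 * (1:6))
  expect_error(fit_linear_models(matrix(rnorm(6)), X), "collinear")
  X2 <- cbind(intercept = 1, x = c(0, 0, 0, 1, 1, 1))
  y_exact <- 2 + 3 * X2[, "x"]
  m <- cbind(exact = y_exact, noisy = y_exact + rnorm(6, 0, 0.1))
  fit <- fit_linear_models(m, X2)
  expect_true(fit$zero_residual[["exact"]])
  expect_false(fit$zero_residual[["noisy"]])
})

test_that("moderation with identical variances returns the common value and d0 = Inf", {
  mod <- empirical_bayes_moderation(rep(0.5, 50), d = 10)
  expect_equal(mod$d0, Inf)
  expect_equal(mod$s2_post, rep(0.5, 50))
})

test_that("d0 = 0 moderation reduces to the classical t-test exactly", {
  sim <- sim_two_group(n1 = 8, n2 = 8, p = 30, seed = 2)
  X <- case_design(sim$y)
  fit <- fit_linear_models(sim$x, X)
  tab <- moderated_t_table(fit, "case",
                           moderation = list(d0 = 0, s0_2 = NA, s2_post = fit$s2))
  # classical t from the same OLS quantities
  t_classical <- fit$coefficients[, "case"] / sqrt(fit$s2 * fit$unscaled_var["case"])
  expect_equal(tab$t, unname(t_classical), tolerance = 1e-10)
  expect_equal(tab$p, unname(2 * pt(-abs(t_classical), fit$df_residual)),
               tolerance = 1e-10)
})

test_that("posterior variance is the df-weighted convex combination", {
  set.seed(3)
  s2 <- exp(rnorm(200, -1, 0.8))
  d <- 12
  mod <- empirical_bayes_moderation(s2, d)
  expect_true(is.finite(mod$d0) && mod$d0 > 0)
  w <- d / (mod$d0 + d)
  expect_equal(mod$s2_post, w * s2 + (1 - w) * mod$s0_2, tolerance = 1e-12)
  expect_true(all(mod$s2_post >= pmin(s2, mod$s0_2) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(s2, mod$s0_2) + 1e-12))
})

test_that("moderation recovers a known scaled inverse-chi-square prior", {
  d0_true <- 4; s0_true <- 0.05; d <- 60
  est <- t(vapply(1:10, function(seed) {
    set.seed(seed)
    sigma2 <- s0_true * d0_true / rchisq(2000, d0_true)
    s2 <- sigma2 * rchisq(2000, d) / d
    mod <- empirical_bayes_moderation(s2, d)
    c(mod$d0, mod$s0_2)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - d0_true) / d0_true, 0.15)
  expect_lt(abs(mean(est[, 2]) - s0_true) / s0_true, 0.15)
})

test_that("moderated statistics agree with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  sim <- sim_two_group(n1 = 10, n2 = 12, p = 150, n_effect = 15, effect = 1.2,
                       noise_sd = 0.7, seed = 9)
  X <- case_design(sim$y)
  fit <- fit_linear_models(sim$x, X)
  mod <- empirical_bayes_moderation(fit$s2, fit$df_residual)
  tab <- moderated_t_table(fit, "case")

  lfit <- limma::lmFit(t(sim$x), X)
  efit <- limma::eBayes(lfit)
  expect_equal(mod$d0, efit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_2, efit$s2.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, unname(efit$s2.post), tolerance = 1e-8)
  expect_equal(tab$t, unname(efit$t[, "case"]), tolerance = 1e-8)
  expect_equal(tab$p, unname(efit$p.value[, "case"]), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # oracle: q_i = min over j >= i of p_(j) * m / j
  set.seed(12)
  p <- runif(40)
  m <- length(p)
  q_direct <- numeric(m)
  psort <- sort(p)
  for (i in seq_len(m)) q_direct[i] <- min(1, min(psort[i:m] * m / (i:m)))
  expect_equal(sort(bh_adjust(p)), q_direct, tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("contrast direction flips the sign of log2FC but not p", {
  sim <- sim_two_group(n1 = 10, n2 = 10, p = 40, n_effect = 5, effect = 1, seed = 4)
  fit_a <- fit_linear_models(sim$x, case_design(sim$y))
  fit_b <- fit_linear_models(sim$x, case_design(1 - sim$y))
  tab_a <- moderated_t_table(fit_a, "case")
  tab_b <- moderated_t_table(fit_b, "case")
  expect_equal(tab_a$log2FC, -tab_b$log2FC, tolerance = 1e-10)
  expect_equal(tab_a$p, tab_b$p, tolerance = 1e-10)
})

test_that("spiked group effects are recovered and the null is controlled", {
  med_fc <- vapply(1:25, function(seed) {
    co <- generate_cohort(cohort_config(n_proteins = 150, n_diff_lga = 20,
                                        n_diff_sga = 0, effect_size = 1.0,
                                        outlier_rate = 0, seed = seed))
    tab <- differential_abundance(log2(co$rfu), co$samples, visit = 1, case = "LGA")
    spiked <- co$truth$proteins$protein[co$truth$proteins$diff_lga]
    median(tab$log2FC[match(spiked, tab$protein)])
  }, numeric(1))
  expect_gt(median(med_fc), 0.8)
  expect_lt(median(med_fc), 1.2)

  # global null: rarely any q < 0.05
  any_hit <- vapply(1:40, function(seed) {
    co <- generate_cohort(cohort_config(n_proteins = 150, n_diff_lga = 0,
                                        n_diff_sga = 0, outlier_rate = 0,
                                        seed = 1000 + seed))
    tab <- differential_abundance(log2(co$rfu), co$samples, visit = 1, case = "LGA")
    any(tab$significant)
  }, logical(1))
  expect_gte(mean(!any_hit), 0.95)
})

test_that("only-positive spiked effects yield only positive significant log2FC", {
  co <- generate_cohort(cohort_config(n_proteins = 200, n_diff_lga = 30,
                                      n_diff_sga = 0, effect_size = 1.2,
                                      outlier_rate = 0, seed = 77))
  pp <- preprocess_cohort(co$rfu, co$samples)
  tab <- differential_abundance(pp$mom, co$samples, visit = 2, case = "LGA")
  sig <- tab[tab$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$log2FC > 0))
})

test_that("z-score association recovers a constructed slope and respects permutation", {
  co <- small_cohort(seed = 21, n_proteins = 40, outlier_rate = 0)
  lg <- log2(co$rfu)
  idx1 <- co$samples$visit == 1
  # construct a protein as 0.5 * z + noise
  set.seed(1)
  lg[, 1] <- 0.5 * co$samples$birth_weight_z + rnorm(nrow(lg), 0, 0.2)
  tab <- associate_with_zscore(lg, co$samples, visit = 1)
  slope <- tab$slope[tab$protein == "PROT0001"]
  # CI half-width from the OLS standard error is well under 0.2 at n = 70
  expect_lt(abs(slope - 0.5), 0.2)
  expect_lt(tab$q[tab$protein == "PROT0001"], 0.05)

  # noise-free strictly increasing function of z has rho = 1
  lg[, 2] <- exp(co$samples$birth_weight_z / 3)
  tab2 <- associate_with_zscore(lg, co$samples, visit = 1)
  expect_equal(tab2$rho[tab2$protein == "PROT0002"], 1)

  # permuting z (with its covariates) kills the associations
  frac_sig <- mean(vapply(1:20, function(seed) {
    set.seed(seed)
    sp <- co$samples
    part <- unique(sp$participant_id)
    newz <- setNames(sample(sp$birth_weight_z[match(part, sp$participant_id)]), part)
    sp$birth_weight_z <- unname(newz[sp$participant_id])
    sp$group <- classify_birth_weight(sp$birth_weight_z)
    tabp <- associate_with_zscore(log2(co$rfu), sp, visit = 1)
    mean(tabp$q < 0.05)
  }, numeric(1)))
  expect_lt(frac_sig, 0.01)
})

test_that("cross-visit overlap counts match direct set algebra", {
  disjoint <- cross_visit_overlap(list(v1 = "A", v2 = "B", v3 = "C"))
  expect_equal(unname(disjoint[c("v1_v2", "v1_v3", "v2_v3", "v1_v2_v3")]), rep(0L, 4),
               ignore_attr = TRUE)
  expect_equal(disjoint[["total"]], 3L)

  same <- cross_visit_overlap(list(c("A", "B"), c("A", "B"), c("A", "B")))
  expect_equal(same[["v1_v2_v3"]], 2L)
  expect_equal(sum(same[1:6]), 0L)

  mixed <- cross_visit_overlap(list(c("A", "B"), c("B", "C"), "B"))
  # brute force over the membership lattice
  universe <- c("A", "B", "C")
  member <- cbind(universe %in% c("A", "B"), universe %in% c("B", "C"),
                  universe %in% "B")
  expect_equal(mixed[["v1_v2_v3"]], sum(member[, 1] & member[, 2] & member[, 3]))
  expect_equal(mixed[["v1_only"]], sum(member[, 1] & !member[, 2] & !member[, 3]))
  expect_equal(mixed[["v2_only"]], sum(!member[, 1] & member[, 2] & !member[, 3]))
  expect_equal(mixed[["total"]], 3L)
})
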
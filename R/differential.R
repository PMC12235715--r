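## Per-protein moderated linear models: OLS across proteins, empirical-Bayes
## variance shrinkage (scaled inverse-chi-square prior fitted by moment
## matching on log s^2), moderated t, BH-FDR.

#' Build a per-visit design matrix
#'
#' Columns: intercept, the variable of interest (a case-group indicator for a
#' pairwise contrast, or the birth-weight z-score), BMI (kg/m2, unscaled) and
#' a 0/1 nulliparity indicator.
#'
#' @param samples Sample table rows for one visit (already subset to the two
#'   groups for a contrast, if any).
#' @param term `"group"` with `case` naming the non-reference group, or
#'   `"zscore"`.
#' @param case Case group label when `term = "group"` (reference is the other
#'   group present, typically AGA).
#' @param adjust Include BMI and nulliparity covariates.
#' @return Numeric design matrix with named columns; full rank is required
#'   downstream.
#' @export
build_design <- function(samples, term = c("group", "zscore"), case = "LGA",
                         adjust = TRUE) {
  term <- match.arg(term)
  x <- if (term == "group") as.numeric(samples$group == case) else samples$birth_weight_z
  X <- cbind(intercept = 1, x)
  colnames(X)[2] <- if (term == "group") paste0("group", case) else "zscore"
  if (adjust) {
    X <- cbind(X, bmi = samples$bmi, nulliparous = as.numeric(samples$nulliparous))
  }
  X
}

#' Ordinary least squares for every protein
#'
#' Fits the same design to each protein column and returns, per protein, the
#' coefficient estimates, the unscaled coefficient variances (diagonal of
#' `(X'X)^-1`), the residual variance `s^2` and the residual degrees of
#' freedom `d = n - ncol(X)`. Proteins with (numerically) zero residual
#' variance are flagged and excluded from moderation.
#'
#' @param mom Samples x proteins matrix (MoM or log2 values).
#' @param design Full-rank design matrix aligned with the rows of `mom`.
#' @return Object of class `protein_lm`: list with `coefficients` (proteins x
#'   coefficients), `unscaled_var`, `s2`, `df_residual`, `zero_residual`
#'   (logical), `design_colnames`.
#' @export
fit_linear_models <- function(mom, design) {
  X <- as.matrix(design)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(mom) != n) stop("matrix rows and design rows differ", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n < p + 2L) stop("need at least ncol(design) + 2 samples", call. = FALSE)
  beta <- qr.coef(qrX, mom)                      # p x proteins
  fitted <- X %*% beta
  res <- mom - fitted
  d <- n - p
  rss <- colSums(res^2)
  s2 <- rss / d
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  v <- diag(XtXinv)
  names(v) <- colnames(X)
  scale2 <- mean(mom^2)
  zero <- s2 <= 1e-12 * max(scale2, 1)
  structure(list(coefficients = t(beta),
                 unscaled_var = v,
                 s2 = s2,
                 df_residual = d,
                 zero_residual = zero,
                 design_colnames = colnames(X)),
            class = "protein_lm")
}

## Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:100) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) return(y)
  }
  stop("trigamma inversion did not converge", call. = FALSE)
}

#' Empirical-Bayes variance moderation
#'
#' Fits a scaled inverse-chi-square prior (`d0`, `s0^2`) to the per-protein
#' residual variances by moment matching on `log(s^2)`: the mean and variance
#' of `log(s^2)` are equated to their digamma/trigamma expressions under the
#' model `s^2 | sigma^2 ~ sigma^2 * chi^2_d / d`, `sigma^2 ~ s0^2 d0 /
#' chi^2_{d0}`, with the trigamma equation inverted by monotone Newton
#' iteration. Posterior (moderated) variances are the degrees-of-freedom
#' weighted combination `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`.
#'
#' @param s2 Vector of positive residual variances (>= 10 finite values).
#' @param d Common residual degrees of freedom (>= 1).
#' @return List with `d0` (prior df, may be `Inf`), `s0_2` (prior variance)
#'   and `s2_post` (moderated variances).
#' @export
empirical_bayes_moderation <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) stop("need >= 10 finite positive variances", call. = FALSE)
  if (d < 1) stop("residual df must be >= 1", call. = FALSE)
  z <- log(s2[ok])
  if (max(z) - min(z) < 1e-12) {
    s0_2 <- s2[which(ok)[1]]
    out <- rep(s0_2, length(s2))
    out[!ok] <- NA_real_
    return(list(d0 = Inf, s0_2 = s0_2, s2_post = out))
  }
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- var(e)
  excess <- evar - trigamma(d / 2)
  if (excess <= 0) {
    # no excess dispersion over chi-square sampling noise: infinite prior df,
    # common prior variance estimated by the arithmetic mean
    d0 <- Inf
    s0_2 <- mean(s2[ok])
    s2_post <- rep(s0_2, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  s2_post[!ok] <- NA_real_
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity (delegates to
#' [stats::p.adjust()] after validation).
#'
#' @param p Vector of p-values in `[0, 1]` (NAs propagate).
#' @return q-values in `[0, 1]`, monotone in p.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Moderated t-tests for one coefficient
#'
#' Combines the per-protein OLS fits with empirical-Bayes moderated
#' variances: `t = beta / (s_tilde * sqrt(v))` on `d0 + d` degrees of
#' freedom, two-sided p, BH q-values. Zero-residual proteins are reported
#' with NA statistics and excluded from the BH denominator.
#'
#' @param fit A `protein_lm` from [fit_linear_models()].
#' @param coefficient Name (or index) of the tested design column.
#' @param moderation Optional precomputed result of
#'   [empirical_bayes_moderation()]; computed from `fit` if missing. Pass
#'   `d0 = 0` semantics by supplying `list(d0 = 0, s0_2 = NA, s2_post = fit$s2)`.
#' @param visit,contrast Optional annotations copied into the table.
#' @return data.frame of class `diff_table`: protein, log2FC (the
#'   coefficient), t, p, q, significant (q < 0.05), plus annotations.
#' @export
moderated_t_table <- function(fit, coefficient = 2L, moderation = NULL,
                              visit = NA_integer_, contrast = NA_character_) {
  if (is.character(coefficient)) coefficient <- match(coefficient, fit$design_colnames)
  beta <- fit$coefficients[, coefficient]
  v <- fit$unscaled_var[coefficient]
  usable <- !fit$zero_residual
  if (is.null(moderation)) {
    s2_in <- fit$s2
    s2_in[!usable] <- NA_real_
    moderation <- empirical_bayes_moderation(s2_in, fit$df_residual)
  }
  # total df capped at the pooled residual df across proteins (the moderated
  # statistic cannot be better-determined than the pooled variance estimate)
  df_total <- min(moderation$d0 + fit$df_residual,
                  fit$df_residual * sum(!fit$zero_residual))
  t <- beta / sqrt(moderation$s2_post * v)
  p <- 2 * pt(-abs(t), df_total)
  t[!usable] <- NA_real_
  p[!usable] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[usable] <- bh_adjust(p[usable])
  out <- data.frame(protein = rownames(fit$coefficients) %||% seq_along(beta),
                    visit = visit, contrast = contrast,
                    log2FC = unname(beta), t = unname(t), p = unname(p),
                    q = unname(q),
                    significant = !is.na(q) & q < 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Differential abundance between a case group and AGA at one visit
#'
#' Subsets the samples to the two groups at the requested visit, builds the
#' adjusted design (case indicator + BMI + nulliparity), fits per-protein
#' OLS, moderates the variances and returns the moderated-t table.
#'
#' @param mom MoM matrix (all samples).
#' @param samples Aligned sample table.
#' @param visit Visit number.
#' @param case `"LGA"` or `"SGA"` (reference AGA).
#' @param adjust Adjust for BMI and nulliparity.
#' @return A `diff_table`.
#' @export
differential_abundance <- function(mom, samples, visit, case = c("LGA", "SGA"),
                                   adjust = TRUE) {
  case <- match.arg(case)
  idx <- which(samples$visit == visit & samples$group %in% c(case, "AGA"))
  sub <- samples[idx, , drop = FALSE]
  X <- build_design(sub, "group", case = case, adjust = adjust)
  fit <- fit_linear_models(mom[idx, , drop = FALSE], X)
  moderated_t_table(fit, paste0("group", case), visit = visit,
                    contrast = paste0(case, "-AGA"))
}

#' Association between protein abundance and birth-weight z-score
#'
#' Per-protein moderated regression of MoM on the birth-weight z-score at
#' one visit, adjusted for BMI and nulliparity, plus the unadjusted Spearman
#' correlation between MoM and z.
#'
#' @param mom MoM matrix (all samples).
#' @param samples Aligned sample table.
#' @param visit Visit number.
#' @param adjust Adjust for BMI and nulliparity.
#' @return data.frame: protein, visit, slope (per z-score unit), t, p, q,
#'   significant, rho.
#' @export
associate_with_zscore <- function(mom, samples, visit, adjust = TRUE) {
  idx <- which(samples$visit == visit)
  sub <- samples[idx, , drop = FALSE]
  X <- build_design(sub, "zscore", adjust = adjust)
  fit <- fit_linear_models(mom[idx, , drop = FALSE], X)
  tab <- moderated_t_table(fit, "zscore", visit = visit, contrast = "zscore")
  names(tab)[names(tab) == "log2FC"] <- "slope"
  tab$contrast <- NULL
  tab$rho <- vapply(seq_len(ncol(mom)), function(j) {
    spearman_corr(mom[idx, j], sub$birth_weight_z)$rho
  }, numeric(1))
  tab
}

#' Overlap of per-visit significant protein sets (Venn regions)
#'
#' @param sets Named list of 3 character vectors (significant proteins at
#'   visits 1-3).
#' @return Named integer vector with the 7 Venn region counts (`v1_only`,
#'   `v2_only`, `v3_only`, `v1_v2`, `v1_v3`, `v2_v3`, `v1_v2_v3`) and
#'   `total` (size of the union).
#' @export
cross_visit_overlap <- function(sets) {
  stopifnot(length(sets) == 3L)
  s1 <- unique(sets[[1]]); s2 <- unique(sets[[2]]); s3 <- unique(sets[[3]])
  all_ids <- union(union(s1, s2), s3)
  in1 <- all_ids %in% s1; in2 <- all_ids %in% s2; in3 <- all_ids %in% s3
  c(v1_only = sum(in1 & !in2 & !in3),
    v2_only = sum(!in1 & in2 & !in3),
    v3_only = sum(!in1 & !in2 & in3),
    v1_v2 = sum(in1 & in2 & !in3),
    v1_v3 = sum(in1 & !in2 & in3),
    v2_v3 = sum(!in1 & in2 & in3),
    v1_v2_v3 = sum(in1 & in2 & in3),
    total = length(all_ids))
}
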
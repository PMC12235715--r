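## Preprocessing: winsorization, log2 transform, gestational-age reference
## curves fitted on AGA samples, MoM detrending, per-visit PCA.

#' Winsorize an RFU matrix at 2 x the per-protein 98th percentile
#'
#' For each protein (column), values exceeding twice that protein's 98th
#' percentile (linear-interpolation quantile, computed on the original
#' values, pooled across all samples and visits) are set to exactly twice
#' the percentile; all other values are unchanged. Idempotent whenever
#' extreme values are rarer than the top 2% per protein, i.e. whenever the
#' clipped entries do not themselves enter the percentile interpolation.
#'
#' @param matrix Numeric samples x proteins matrix of positive values.
#' @return Winsorized matrix of the same shape.
#' @export
winsorize <- function(matrix) {
  if (nrow(matrix) < 2L) {
    warning("fewer than 2 samples; winsorization skipped")
    return(matrix)
  }
  thr <- 2 * apply(matrix, 2, quantile, probs = 0.98, names = FALSE, type = 7)
  pmin(matrix, rep(thr, each = nrow(matrix)))
}

#' Elementwise log2 transform
#' @param matrix Numeric matrix of strictly positive values.
#' @return Matrix of log2 values.
#' @export
log2_transform <- function(matrix) {
  bad <- which(!is.finite(matrix) | matrix <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive value at row %d, column %d: cannot log2-transform",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  log2(matrix)
}

#' Fit a gestational-age reference curve for one protein
#'
#' Fits penalized B-spline (P-spline) smooths of log2 abundance on
#' gestational age using the reference (AGA) samples only, one fit per
#' candidate basis dimension k in `{3, 4, 5, 6}`, and keeps the k with the
#' highest r-squared on the reference points (ties broken toward smaller k;
#' constant response gives r-squared 0 by convention). Predictions outside
#' the reference gestational-age range continue linearly with the boundary
#' slope.
#'
#' @param log_values Numeric vector of log2 abundances (all samples).
#' @param gestational_ages Gestational ages (weeks), same length.
#' @param aga_mask Logical vector marking the reference samples.
#' @param candidate_k Candidate spline basis dimensions.
#' @param protein_id Optional identifier carried in the result.
#' @return Object of class `gam_fit` with elements `protein_id`, `k`,
#'   `coefficients`, `smoothing_parameter`, `r_squared`, `fit_range`, and the
#'   underlying model for prediction.
#' @export
fit_reference_curve <- function(log_values, gestational_ages, aga_mask,
                                candidate_k = c(3, 4, 5, 6),
                                protein_id = NA_character_) {
  y <- log_values[aga_mask]
  ga <- gestational_ages[aga_mask]
  if (length(y) < 2L) stop("need at least 2 reference samples", call. = FALSE)
  rng <- range(ga)
  if (diff(rng) <= 0) stop("degenerate gestational-age range in reference samples", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  n_distinct <- length(unique(ga))

  if (tss == 0) {
    # constant response: constant curve, r^2 = 0 by the zero-variance convention
    fit <- list(type = "constant", value = y[1])
    return(finish_gam_fit(fit, NA_integer_, 0, rng, protein_id))
  }
  if (n_distinct < max(candidate_k) + 2L) {
    warning("too few distinct reference gestational ages; falling back to a least-squares line")
    lmfit <- lm(y ~ ga, data = data.frame(y = y, ga = ga))
    r2 <- 1 - sum(residuals(lmfit)^2) / tss
    fit <- list(type = "lm", model = lmfit)
    return(finish_gam_fit(fit, NA_integer_, r2, rng, protein_id))
  }

  best <- NULL
  for (k in sort(candidate_k)) {
    # penalized B-spline smooth with a difference penalty; a basis dimension
    # of 3 only supports quadratic (order-3) B-splines
    spline_order <- if (k <= 3) c(1, 2) else c(2, 2)
    m <- mgcv::gam(y ~ s(ga, k = k, bs = "ps", m = spline_order),
                   data = data.frame(y = y, ga = ga), method = "GCV.Cp")
    r2 <- 1 - sum(residuals(m)^2) / tss
    if (is.null(best) || r2 > best$r2 + 1e-12) best <- list(k = k, model = m, r2 = r2)
  }
  fit <- list(type = "gam", model = best$model)
  finish_gam_fit(fit, best$k, best$r2, rng, protein_id)
}

finish_gam_fit <- function(fit, k, r2, rng, protein_id) {
  eval_inner <- function(ga) {
    switch(fit$type,
           constant = rep(fit$value, length(ga)),
           lm = unname(predict(fit$model, newdata = data.frame(ga = ga))),
           gam = unname(predict(fit$model, newdata = data.frame(ga = ga))))
  }
  h <- 1e-3 * diff(rng)
  b_lo <- eval_inner(c(rng[1], rng[1] + h))
  b_hi <- eval_inner(c(rng[2] - h, rng[2]))
  structure(list(
    protein_id = protein_id,
    k = k,
    coefficients = if (fit$type == "constant") fit$value else coef(fit$model),
    smoothing_parameter = if (fit$type == "gam") unname(fit$model$sp) else NA_real_,
    r_squared = r2,
    fit_range = rng,
    boundary = list(lo_value = b_lo[1], lo_slope = (b_lo[2] - b_lo[1]) / h,
                    hi_value = b_hi[2], hi_slope = (b_hi[2] - b_hi[1]) / h),
    eval_inner = eval_inner
  ), class = "gam_fit")
}

#' Evaluate a fitted reference curve
#'
#' Inside the reference fit range the spline is evaluated directly; outside,
#' the curve continues linearly from the boundary with the boundary slope.
#'
#' @param object A `gam_fit`.
#' @param gestational_ages Gestational ages (weeks) to evaluate at.
#' @param ... Unused.
#' @return Numeric vector of fitted log2 values.
#' @export
predict.gam_fit <- function(object, gestational_ages, ...) {
  ga <- gestational_ages
  out <- numeric(length(ga))
  lo <- ga < object$fit_range[1]
  hi <- ga > object$fit_range[2]
  mid <- !lo & !hi
  if (any(mid)) out[mid] <- object$eval_inner(ga[mid])
  b <- object$boundary
  if (any(lo)) out[lo] <- b$lo_value + b$lo_slope * (ga[lo] - object$fit_range[1])
  if (any(hi)) out[hi] <- b$hi_value + b$hi_slope * (ga[hi] - object$fit_range[2])
  out
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("Reference curve%s: k = %s, r^2 = %.4f, GA range [%.1f, %.1f]\n",
              if (is.na(x$protein_id)) "" else paste0(" for ", x$protein_id),
              ifelse(is.na(x$k), "line/constant", x$k), x$r_squared,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Fit reference curves for every protein of a log2 matrix
#'
#' @param log_matrix Samples x proteins matrix of log2 abundances.
#' @param gestational_ages Per-sample gestational ages.
#' @param aga_mask Logical reference-sample mask.
#' @param candidate_k Candidate basis dimensions.
#' @return Named list of `gam_fit` objects (one per protein).
#' @export
fit_reference_curves <- function(log_matrix, gestational_ages, aga_mask,
                                 candidate_k = c(3, 4, 5, 6)) {
  prot <- colnames(log_matrix)
  fits <- lapply(seq_along(prot), function(j) {
    fit_reference_curve(log_matrix[, j], gestational_ages, aga_mask,
                        candidate_k, protein_id = prot[j])
  })
  names(fits) <- prot
  fits
}

#' Compute MoM values against fitted reference curves
#'
#' MoM (multiples of the mean, log2 scale) is the observed log2 abundance
#' minus the reference-curve value at the sample's gestational age, for all
#' samples including SGA and LGA.
#'
#' @param log_matrix Samples x proteins log2 matrix.
#' @param fits Named list of `gam_fit` objects covering every column.
#' @param gestational_ages Per-sample gestational ages.
#' @return MoM matrix of the same shape.
#' @export
compute_mom <- function(log_matrix, fits, gestational_ages) {
  prot <- colnames(log_matrix)
  missing <- setdiff(prot, names(fits))
  if (length(missing)) {
    stop("missing reference fit for protein(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mom <- log_matrix
  for (j in seq_along(prot)) {
    mom[, j] <- log_matrix[, j] - predict(fits[[prot[j]]], gestational_ages)
  }
  mom
}

#' Full preprocessing pipeline
#'
#' Applies winsorization, log2 transform, AGA reference-curve fitting and
#' MoM detrending in that fixed order.
#'
#' @param rfu Samples x proteins RFU matrix.
#' @param samples Sample table aligned with the matrix rows.
#' @param candidate_k Candidate spline basis dimensions.
#' @return List with `winsorized`, `log2`, `fits`, `mom` and a `fit_summary`
#'   data.frame (protein, chosen k, r-squared, fit range).
#' @export
preprocess_cohort <- function(rfu, samples, candidate_k = c(3, 4, 5, 6)) {
  stopifnot(nrow(rfu) == nrow(samples))
  win <- winsorize(rfu)
  lg <- log2_transform(win)
  fits <- fit_reference_curves(lg, samples$gestational_age,
                               samples$group == "AGA", candidate_k)
  mom <- compute_mom(lg, fits, samples$gestational_age)
  fit_summary <- data.frame(
    protein = names(fits),
    k = vapply(fits, function(f) as.integer(f$k %||% NA_integer_), integer(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    ga_min = vapply(fits, function(f) f$fit_range[1], numeric(1)),
    ga_max = vapply(fits, function(f) f$fit_range[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(fit_summary) <- NULL
  list(winsorized = win, log2 = lg, fits = fits, mom = mom,
       fit_summary = fit_summary)
}

#' Principal component analysis of MoM values at one visit
#'
#' Column-centered (unscaled) PCA of the visit's MoM submatrix; MoM values
#' already share a common log2 deviation scale so no variance scaling is
#' applied.
#'
#' @param mom MoM matrix (all samples).
#' @param samples Sample table aligned with the matrix rows.
#' @param visit Visit number (1, 2 or 3).
#' @return Object of class `pca_result` with `visit`, `scores`, `loadings`
#'   and `explained_variance` (fractions, non-increasing).
#' @export
pca_by_visit <- function(mom, samples, visit) {
  idx <- which(samples$visit == visit)
  if (length(idx) < 3L) stop("need at least 3 samples at the visit", call. = FALSE)
  sub <- mom[idx, , drop = FALSE]
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(visit = visit,
                 scores = pc$x,
                 loadings = pc$rotation,
                 explained_variance = ev,
                 sample_ids = rownames(mom)[idx],
                 groups = samples$group[idx]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA at visit %d: %d samples, PC1 %.1f%%, PC2 %.1f%% variance\n",
              x$visit, nrow(x$scores), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' @importFrom stats prcomp residuals
NULL
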
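#' Configuration for the synthetic three-visit cohort
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' Defaults emulate the design of a 70-participant longitudinal pregnancy
#' cohort with three sampling visits and birth-weight groups defined by
#' z-score cutoffs at +/- 1.3 (SGA below, LGA above, AGA between): 7 SGA,
#' 58 AGA and 5 LGA participants, visits in gestational windows 12-19,
#' 21-27 and 28-34 weeks.
#'
#' @param n_sga,n_aga,n_lga Participant counts per birth-weight group.
#' @param visit_windows List of 3 length-2 numeric vectors: the gestational-age
#'   interval (weeks) of each visit. Must be increasing and non-overlapping.
#' @param ga_mean_sd List of 3 length-2 vectors `c(mean, sd)` of gestational
#'   age at each visit (weeks); draws are truncated to the visit window.
#' @param n_proteins Number of simulated proteins.
#' @param n_diff_lga,n_diff_sga Number of proteins carrying a true group
#'   effect for the LGA-vs-AGA and SGA-vs-AGA contrasts (disjoint sets).
#' @param effect_size True group effect in log2 units; either a scalar
#'   (constant across visits) or a length-3 vector (per-visit effect).
#' @param zscore_params Named list (`sga`, `aga`, `lga`) of `c(mean, sd)` for
#'   the birth-weight z-score; sampling is truncated to the group's defining
#'   interval so labels are consistent by construction.
#' @param bmi_params `c(mean, sd)` of maternal BMI (kg/m2).
#' @param nullip_prob Probability of nulliparity (first pregnancy).
#' @param sex_prob Probability of female fetal sex.
#' @param random_intercept_sd SD of the participant-level random intercept
#'   (log2 units), shared across all proteins of a participant.
#' @param noise_sd Residual SD per measurement (log2 units).
#' @param baseline_mean,baseline_sd Mean/SD of per-protein baseline log2
#'   abundance (log2 RFU).
#' @param trend_linear_sd,trend_quad_sd SDs of the random linear and quadratic
#'   trend coefficients on the scaled gestational-age axis.
#' @param sin_amplitude Upper bound of the per-protein sinusoidal trend
#'   amplitude (log2 units); 0 disables the sinusoidal component.
#' @param outlier_rate Fraction of matrix entries multiplied by
#'   `outlier_factor` to emulate heavy-tailed assay outliers.
#' @param outlier_factor Multiplicative outlier magnitude (> 1).
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_sga = 7, n_aga = 58, n_lga = 5,
                          visit_windows = list(c(12, 19), c(21, 27), c(28, 34)),
                          ga_mean_sd = list(c(15.7, 1.2), c(23.4, 1.0), c(31.3, 0.97)),
                          n_proteins = 500,
                          n_diff_lga = 16, n_diff_sga = 4,
                          effect_size = 0.5,
                          zscore_params = list(sga = c(-1.9, 0.35),
                                               aga = c(-0.12, 0.58),
                                               lga = c(1.7, 0.30)),
                          bmi_params = c(24.1, 2.8),
                          nullip_prob = 0.5, sex_prob = 0.5,
                          random_intercept_sd = 0.3, noise_sd = 0.25,
                          baseline_mean = 10, baseline_sd = 1.5,
                          trend_linear_sd = 0.4, trend_quad_sd = 0.25,
                          sin_amplitude = 0.1,
                          outlier_rate = 0.002, outlier_factor = 8,
                          seed = 1L) {
  cfg <- list(n_sga = n_sga, n_aga = n_aga, n_lga = n_lga,
              visit_windows = visit_windows, ga_mean_sd = ga_mean_sd,
              n_proteins = n_proteins, n_diff_lga = n_diff_lga,
              n_diff_sga = n_diff_sga, effect_size = effect_size,
              zscore_params = zscore_params, bmi_params = bmi_params,
              nullip_prob = nullip_prob, sex_prob = sex_prob,
              random_intercept_sd = random_intercept_sd, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              trend_linear_sd = trend_linear_sd, trend_quad_sd = trend_quad_sd,
              sin_amplitude = sin_amplitude,
              outlier_rate = outlier_rate, outlier_factor = outlier_factor,
              seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_sga", "n_aga", "n_lga", "n_proteins", "n_diff_lga", "n_diff_sga")) {
    if (!is_count(cfg[[f]])) stop_config(f, "must be a non-negative integer")
  }
  if (cfg$n_diff_lga + cfg$n_diff_sga > cfg$n_proteins) {
    stop_config("n_diff_lga", "plus n_diff_sga exceeds n_proteins")
  }
  if (!is.list(cfg$visit_windows) || length(cfg$visit_windows) != 3L) {
    stop_config("visit_windows", "must be a list of 3 intervals")
  }
  prev_hi <- -Inf
  for (w in cfg$visit_windows) {
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2]) {
      stop_config("visit_windows", "intervals must be increasing pairs")
    }
    if (w[1] <= prev_hi) stop_config("visit_windows", "intervals must be non-overlapping and increasing")
    prev_hi <- w[2]
  }
  if (!is.list(cfg$ga_mean_sd) || length(cfg$ga_mean_sd) != 3L ||
      !all(vapply(cfg$ga_mean_sd, function(v) length(v) == 2L && v[2] > 0, logical(1)))) {
    stop_config("ga_mean_sd", "must be 3 c(mean, sd) pairs with sd > 0")
  }
  zp <- cfg$zscore_params
  if (!is.list(zp) || !all(c("sga", "aga", "lga") %in% names(zp)) ||
      !all(vapply(zp, function(v) length(v) == 2L && v[2] > 0, logical(1)))) {
    stop_config("zscore_params", "must name sga/aga/lga c(mean, sd) pairs with sd > 0")
  }
  if (length(cfg$bmi_params) != 2L || cfg$bmi_params[2] <= 0) {
    stop_config("bmi_params", "must be c(mean, sd) with sd > 0")
  }
  for (f in c("nullip_prob", "sex_prob", "outlier_rate")) {
    if (!is_prob(cfg[[f]])) stop_config(f, "must be a probability in [0, 1]")
  }
  for (f in c("random_intercept_sd", "noise_sd", "baseline_sd")) {
    if (!(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] > 0)) {
      stop_config(f, "must be a positive scalar")
    }
  }
  for (f in c("trend_linear_sd", "trend_quad_sd", "sin_amplitude")) {
    if (!(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] >= 0)) {
      stop_config(f, "must be a non-negative scalar")
    }
  }
  if (!(length(cfg$effect_size) %in% c(1L, 3L)) || !all(is.finite(cfg$effect_size))) {
    stop_config("effect_size", "must be a finite scalar or length-3 vector")
  }
  if (!(is.numeric(cfg$outlier_factor) && length(cfg$outlier_factor) == 1L &&
        cfg$outlier_factor > 1)) {
    stop_config("outlier_factor", "must be > 1")
  }
  if (!is_count(abs(cfg$seed))) stop_config("seed", "must be an integer")
  invisible(cfg)
}

## Per-protein smooth gestational trend: quadratic on a scaled axis plus an
## optional sinusoid. u in [-1, 1] over weeks 12-34.
trend_value <- function(ga, pars) {
  u <- (ga - 23) / 11
  pars$b1 * u + pars$b2 * u^2 +
    pars$amp * sin(2 * pi * ga / 20 + pars$phase)
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates the sample-annotation table, the raw protein abundance matrix
#' (relative fluorescence units) and a ground-truth record. Each participant
#' contributes one sample per visit. Log2 abundance is the sum of a protein
#' baseline, a smooth gestational trend, a participant random intercept, a
#' group effect on the configured protein subsets and Gaussian noise; RFU is
#' its antilog. A small fraction of entries is multiplied by a large factor
#' to emulate heavy-tailed assay outliers.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `samples`
#'   (data.frame, one row per participant-visit), `rfu` (samples x proteins
#'   numeric matrix, strictly positive) and `truth` (list with per-protein
#'   and per-participant ground truth).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  with_seed(config$seed, {
    n_part <- config$n_sga + config$n_aga + config$n_lga
    groups <- rep(c("SGA", "AGA", "LGA"), c(config$n_sga, config$n_aga, config$n_lga))
    pid <- sprintf("P%03d", seq_len(n_part))

    zp <- config$zscore_params
    z <- numeric(n_part)
    z[groups == "SGA"] <- rtruncnorm(sum(groups == "SGA"), zp$sga[1], zp$sga[2], upper = -1.3)
    z[groups == "AGA"] <- rtruncnorm(sum(groups == "AGA"), zp$aga[1], zp$aga[2], -1.3, 1.3)
    z[groups == "LGA"] <- rtruncnorm(sum(groups == "LGA"), zp$lga[1], zp$lga[2], lower = 1.3)

    bmi <- rnorm(n_part, config$bmi_params[1], config$bmi_params[2])
    nullip <- runif(n_part) < config$nullip_prob
    sex <- ifelse(runif(n_part) < config$sex_prob, "F", "M")
    u_part <- rnorm(n_part, 0, config$random_intercept_sd)

    ga <- matrix(0, n_part, 3)
    for (v in 1:3) {
      w <- config$visit_windows[[v]]
      ms <- config$ga_mean_sd[[v]]
      ga[, v] <- rtruncnorm(n_part, ms[1], ms[2], w[1], w[2])
    }

    samples <- data.frame(
      participant_id = rep(pid, each = 3),
      visit = rep(1:3, n_part),
      gestational_age = as.vector(t(ga)),
      group = rep(groups, each = 3),
      birth_weight_z = rep(z, each = 3),
      bmi = rep(bmi, each = 3),
      nulliparous = rep(nullip, each = 3),
      sex = rep(sex, each = 3),
      stringsAsFactors = FALSE
    )
    rownames(samples) <- NULL
    sample_id <- paste0(samples$participant_id, "_V", samples$visit)

    p <- config$n_proteins
    prot_id <- sprintf("PROT%04d", seq_len(p))
    baseline <- rnorm(p, config$baseline_mean, config$baseline_sd)
    b1 <- rnorm(p, 0, config$trend_linear_sd)
    b2 <- rnorm(p, 0, config$trend_quad_sd)
    amp <- runif(p, 0, config$sin_amplitude)
    phase <- runif(p, 0, 2 * pi)

    diff_lga <- seq_len(p) <= config$n_diff_lga
    diff_sga <- seq_len(p) > config$n_diff_lga &
      seq_len(p) <= config$n_diff_lga + config$n_diff_sga
    eff <- rep(config$effect_size, length.out = 3)  # per-visit effect

    ns <- nrow(samples)
    u_grid <- (samples$gestational_age - 23) / 11
    trend <- outer(u_grid, b1) + outer(u_grid^2, b2) +
      sin(outer(2 * pi * samples$gestational_age / 20, rep(1, p)) +
            matrix(phase, ns, p, byrow = TRUE)) *
      matrix(amp, ns, p, byrow = TRUE)

    log2ab <- matrix(baseline, ns, p, byrow = TRUE) + trend +
      matrix(rep(u_part, each = 3), ns, p) +
      matrix(rnorm(ns * p, 0, config$noise_sd), ns, p)

    eff_s <- eff[samples$visit]
    log2ab[, diff_lga] <- log2ab[, diff_lga] +
      (samples$group == "LGA") * eff_s
    log2ab[, diff_sga] <- log2ab[, diff_sga] +
      (samples$group == "SGA") * eff_s

    rfu <- 2^log2ab
    dimnames(rfu) <- list(sample_id, prot_id)
    if (config$outlier_rate > 0) {
      rfu <- inject_outliers(rfu, config$outlier_rate, config$outlier_factor,
                             seed = derive_seed(config$seed, 7L))
    }

    truth <- list(
      proteins = data.frame(
        protein = prot_id,
        diff_lga = diff_lga,
        diff_sga = diff_sga,
        lga_effect_v1 = ifelse(diff_lga, eff[1], 0),
        lga_effect_v2 = ifelse(diff_lga, eff[2], 0),
        lga_effect_v3 = ifelse(diff_lga, eff[3], 0),
        sga_effect_v1 = ifelse(diff_sga, eff[1], 0),
        sga_effect_v2 = ifelse(diff_sga, eff[2], 0),
        sga_effect_v3 = ifelse(diff_sga, eff[3], 0),
        baseline = baseline, trend_linear = b1, trend_quad = b2,
        sin_amplitude = amp, sin_phase = phase,
        stringsAsFactors = FALSE
      ),
      participants = data.frame(
        participant_id = pid, group = groups, random_intercept = u_part,
        stringsAsFactors = FALSE
      ),
      config = config
    )

    structure(list(samples = samples, rfu = rfu, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$truth$participants$group)
  cat(sprintf("Synthetic cohort: %d participants (SGA %d / AGA %d / LGA %d), %d samples, %d proteins\n",
              nrow(x$truth$participants), tab[["SGA"]], tab[["AGA"]], tab[["LGA"]],
              nrow(x$samples), ncol(x$rfu)))
  cat(sprintf("True differential proteins: %d (LGA contrast), %d (SGA contrast)\n",
              sum(x$truth$proteins$diff_lga), sum(x$truth$proteins$diff_sga)))
  invisible(x)
}

#' Multiply random matrix entries by an outlier factor
#'
#' Emulates heavy-tailed assay outliers: `floor(rate * n_entries)` entries,
#' chosen uniformly without replacement, are multiplied by `factor`; all other
#' entries are returned unchanged.
#'
#' @param matrix Numeric matrix (e.g. an RFU matrix).
#' @param rate Fraction of entries to perturb, in `[0, 1]`.
#' @param factor Multiplicative factor, `> 1`.
#' @param seed Optional integer seed.
#' @return A new matrix of the same shape.
#' @export
inject_outliers <- function(matrix, rate, factor, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop("rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1) {
    stop("factor must be > 1", call. = FALSE)
  }
  n_out <- floor(rate * length(matrix))
  if (n_out == 0L) return(matrix)
  with_seed(seed, {
    idx <- sample.int(length(matrix), n_out)
    matrix[idx] <- matrix[idx] * factor
    matrix
  })
}
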
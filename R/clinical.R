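## Clinical group comparisons: birth-weight classification, Welch t,
## Fisher exact by full enumeration (2xC, C <= 3), Spearman correlation.

#' Classify birth weight group from the z-score
#'
#' z > 1.3 (above the 90th percentile of the population reference) is LGA,
#' z < -1.3 (below the 10th percentile) is SGA, anything else including the
#' boundaries is AGA. Vectorized.
#'
#' @param z Numeric vector of birth-weight z-scores; must be finite.
#' @return Character vector in `{"SGA", "AGA", "LGA"}`.
#' @export
classify_birth_weight <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("birth-weight z-scores must be finite numbers", call. = FALSE)
  }
  ifelse(z > 1.3, "LGA", ifelse(z < -1.3, "SGA", "AGA"))
}

new_test_result <- function(statistic, df, p, test, groups = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p,
                 test = test, groups = groups),
            class = "gestprot_test")
}

#' @export
print.gestprot_test <- function(x, ...) {
  cat(x$test)
  if (!is.null(x$groups)) cat(" [", paste(x$groups, collapse = " vs "), "]", sep = "")
  parts <- character()
  if (!is.null(x$statistic) && !is.na(x$statistic)) {
    parts <- c(parts, sprintf("statistic = %.4g", x$statistic))
  }
  if (!is.null(x$df) && !is.na(x$df)) parts <- c(parts, sprintf("df = %.4g", x$df))
  parts <- c(parts, sprintf("p = %.4g", x$p_value))
  cat(":", paste(parts, collapse = ", "), "\n")
  invisible(x)
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t-test: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Operating
#' on summary statistics allows published group means/SDs/ns to be used as
#' inputs directly.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param groups Optional labels for printing.
#' @return A `gestprot_test` with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, groups = NULL) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(new_test_result(0, NA_real_, 1, "Welch two-sample t", groups))
    }
    stop("both variances are zero with unequal means: t undefined", call. = FALSE)
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  new_test_result(t, df, p, "Welch two-sample t", groups)
}

#' Welch's t-test from raw vectors
#' @param x,y Numeric vectors (length >= 2 each).
#' @param groups Optional labels.
#' @return A `gestprot_test`; reduces to [welch_t()] on the vectors'
#'   summary statistics.
#' @export
welch_t_vectors <- function(x, y, groups = NULL) {
  welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y), groups)
}

## Enumerate all 2xC tables with the observed margins; returns the log
## probability of each under the multivariate hypergeometric.
enumerate_2xc <- function(col_sums, r1) {
  C <- length(col_sums)
  grid <- expand.grid(lapply(col_sums, function(cj) 0:cj))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  N <- sum(col_sums)
  logp <- -lchoose(N, r1)
  for (j in seq_len(C)) logp <- logp + lchoose(col_sums[j], grid[[j]])
  list(tables = grid, logp = logp)
}

#' Fisher's exact test for 2 x C tables (C = 2 or 3) by full enumeration
#'
#' Enumerates every table with the observed margins, assigns each its
#' multivariate hypergeometric probability, and reports the two-sided
#' p-value as the total probability of tables no more likely than the
#' observed one (with relative tolerance `1 + 1e-7` on the comparison, the
#' convention needed to reproduce published values on knife-edge ties).
#'
#' @param table 2 x C matrix of non-negative integer counts, C in `{2, 3}`.
#' @param groups Optional labels.
#' @return A `gestprot_test` with `p_value` (no statistic).
#' @export
fisher_exact_rxc <- function(table, groups = NULL) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || !(ncol(table) %in% c(2L, 3L))) {
    stop("only 2x2 and 2x3 tables are supported", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  col_sums <- colSums(table)
  if (prod(col_sums + 1) > 1e7) stop("enumeration too large", call. = FALSE)
  r1 <- sum(table[1, ])
  if (r1 == 0 || sum(table[2, ]) == 0 || sum(table) == 0) {
    # only one attainable table given the margins
    return(new_test_result(NA_real_, NA_real_, 1, "Fisher exact (enumeration)", groups))
  }
  en <- enumerate_2xc(col_sums, r1)
  obs_logp <- -lchoose(sum(col_sums), r1) +
    sum(lchoose(col_sums, table[1, ]))
  p <- sum(exp(en$logp)[en$logp <= obs_logp + log(1 + 1e-7)])
  new_test_result(NA_real_, NA_real_, min(p, 1), "Fisher exact (enumeration)", groups)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); two-sided
#' p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df. An
#' exact permutation p-value is available for small n.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @param exact Use exhaustive permutation p (only for n <= 9).
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) stop("zero variance in ranks", call. = FALSE)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 9L) stop("exact permutation p only supported for n <= 9", call. = FALSE)
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(cor(rx, ry[perms[i, ]])) >= obs - 1e-12) cnt <- cnt + 1L
    }
    return(list(rho = rho, p = cnt / nrow(perms)))
  }
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2))
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Group comparison table of clinical variables
#'
#' Summarizes continuous clinical variables as per-group mean (SD) with
#' pairwise Welch t p-values, and categorical variables as counts with
#' pairwise Fisher exact p-values, for the pairs SGA-AGA, LGA-AGA and
#' SGA-LGA (one row per participant, taken from visit 1).
#'
#' @param samples Sample table (one row per participant-visit).
#' @param continuous,categorical Column names to summarize.
#' @return data.frame with one row per variable and p-value columns per pair.
#' @export
clinical_summary_table <- function(samples,
                                   continuous = c("birth_weight_z", "bmi"),
                                   categorical = c("nulliparous", "sex")) {
  part <- samples[samples$visit == 1, , drop = FALSE]
  pairs <- list(sga_aga = c("SGA", "AGA"), lga_aga = c("LGA", "AGA"),
                sga_lga = c("SGA", "LGA"))
  rows <- list()
  for (v in continuous) {
    r <- list(variable = v, type = "continuous")
    for (g in c("SGA", "AGA", "LGA")) {
      x <- part[[v]][part$group == g]
      r[[paste0(tolower(g), "_summary")]] <- sprintf("%.3g (%.3g)", mean(x), sd(x))
    }
    for (pn in names(pairs)) {
      g <- pairs[[pn]]
      r[[paste0("p_", pn)]] <- welch_t_vectors(part[[v]][part$group == g[1]],
                                               part[[v]][part$group == g[2]])$p_value
    }
    rows[[v]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    lev <- sort(unique(as.character(part[[v]])))
    r <- list(variable = v, type = "categorical")
    for (g in c("SGA", "AGA", "LGA")) {
      cnt <- table(factor(as.character(part[[v]])[part$group == g], levels = lev))
      r[[paste0(tolower(g), "_summary")]] <- paste(cnt, collapse = "/")
    }
    for (pn in names(pairs)) {
      g <- pairs[[pn]]
      tab <- rbind(table(factor(as.character(part[[v]])[part$group == g[1]], levels = lev)),
                   table(factor(as.character(part[[v]])[part$group == g[2]], levels = lev)))
      r[[paste0("p_", pn)]] <- fisher_exact_rxc(tab)$p_value
    }
    rows[[v]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
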
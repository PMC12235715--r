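## Per-group mean longitudinal abundance curves across gestation for
## selected proteins, sharing the reference-curve spline engine.

#' Fit per-group longitudinal trajectories for selected proteins
#'
#' For each requested protein and each birth-weight group, fits the same
#' penalized spline smooth of log2 abundance on gestational age used for
#' the MoM reference curves (basis dimension chosen among `{3,4,5,6}` by
#' highest r-squared) on that group's samples only, and samples the fitted
#' curve on a 100-point grid spanning the group's observed gestational-age
#' range. Curves are fitted on winsorized log2 RFU, not MoM. Groups with too
#' few samples for the spline fall back to a least-squares line with a
#' warning (inherited from the engine).
#'
#' @param log_matrix Samples x proteins winsorized log2 matrix.
#' @param samples Aligned sample table.
#' @param proteins Protein ids to fit.
#' @param groups Group labels to fit (default all three).
#' @param candidate_k Candidate basis dimensions.
#' @param grid_points Grid resolution (default 100).
#' @return data.frame of class `trajectory_fits`: protein, group, k,
#'   r_squared, gestational_age, fitted (log2 RFU), ordered by (protein,
#'   group, gestational_age).
#' @export
fit_group_trajectories <- function(log_matrix, samples, proteins,
                                   groups = c("SGA", "AGA", "LGA"),
                                   candidate_k = c(3, 4, 5, 6),
                                   grid_points = 100L) {
  missing <- setdiff(proteins, colnames(log_matrix))
  if (length(missing)) {
    stop("protein(s) not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (prot in proteins) {
    for (g in groups) {
      mask <- samples$group == g
      if (sum(mask) < 2L || length(unique(samples$gestational_age[mask])) < 2L) {
        warning(sprintf("group %s has too few samples; skipped for %s", g, prot))
        next
      }
      fit <- fit_reference_curve(log_matrix[, prot], samples$gestational_age,
                                 mask, candidate_k, protein_id = prot)
      grid <- seq(fit$fit_range[1], fit$fit_range[2], length.out = grid_points)
      out[[paste(prot, g)]] <- data.frame(
        protein = prot, group = g,
        k = fit$k, r_squared = fit$r_squared,
        gestational_age = grid, fitted = predict(fit, grid),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(protein = character(), group = character(), k = integer(),
                      r_squared = numeric(), gestational_age = numeric(),
                      fitted = numeric(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$protein, res$group, res$gestational_age), , drop = FALSE]
  }
  rownames(res) <- NULL
  class(res) <- c("trajectory_fits", "data.frame")
  res
}

#' Export trajectory fits as TSV
#'
#' Deterministic (protein, group, gestational age) row order.
#'
#' @param fits A `trajectory_fits` data.frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
export_trajectories <- function(fits, path) {
  write_results_table(fits, path, sort_by = c("protein", "group", "gestational_age"))
}
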
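## Shared fixtures: small cohorts, quick two-group matrices, toy gene sets.

small_cohort <- function(seed = 1, n_proteins = 60, ...) {
  generate_cohort(cohort_config(n_proteins = n_proteins,
                                n_diff_lga = min(6L, n_proteins %/% 4L),
                                n_diff_sga = min(2L, n_proteins %/% 8L),
                                seed = seed, ...))
}

## Plain two-group matrix simulation (no gestational structure): rows are
## samples (n1 cases first), columns proteins; effect added to the cases of
## the first `n_effect` proteins.
sim_two_group <- function(n1 = 30, n2 = 30, p = 100, n_effect = 0,
                          effect = 0, noise_sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm((n1 + n2) * p, 0, noise_sd), n1 + n2, p)
  colnames(m) <- sprintf("PR%04d", seq_len(p))
  rownames(m) <- sprintf("S%03d", seq_len(n1 + n2))
  y <- rep(c(1, 0), c(n1, n2))
  if (n_effect > 0) m[y == 1, seq_len(n_effect)] <- m[y == 1, seq_len(n_effect)] + effect
  list(x = m, y = y)
}

## Design with intercept + case indicator only.
case_design <- function(y) cbind(intercept = 1, case = as.numeric(y))

toy_collection <- function(background, n_sets = 20, set_size = 15, seed = 99) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    list(id = sprintf("SET%02d", i), description = sprintf("toy set %d", i),
         members = sample(background, set_size))
  })
  names(sets) <- vapply(sets, `[[`, "", "id")
  structure(sets, class = "gene_set_collection")
}

write_toy_gmt <- function(path, sets) {
  lines <- vapply(sets, function(s) {
    paste(c(s$id, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  path
}
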
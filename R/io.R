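## Tabular IO: sample tables, abundance matrices, GMT gene sets, results.
## Delimiter is sniffed from the file extension (.csv -> comma, else tab).

sniff_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

SAMPLE_COLS <- c("participant_id", "visit", "gestational_age", "group",
                 "birth_weight_z", "bmi", "nulliparous", "sex")

#' Validate a sample-annotation table
#'
#' Checks the invariants of the per-sample clinical/design metadata:
#' required columns present, unique (participant, visit) pairs, visit in
#' 1..3, gestational age within the declared visit window, and group label
#' consistent with the birth-weight z-score cutoffs at +/- 1.3.
#'
#' @param samples data.frame with columns `participant_id`, `visit`,
#'   `gestational_age`, `group`, `birth_weight_z`, `bmi`, `nulliparous`, `sex`.
#' @param visit_windows Declared gestational-age windows per visit.
#' @return The validated data.frame, invisibly.
#' @export
validate_sample_table <- function(samples,
                                  visit_windows = list(c(12, 19), c(21, 27), c(28, 34))) {
  missing <- setdiff(SAMPLE_COLS, names(samples))
  if (length(missing)) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("no samples in table", call. = FALSE)
  key <- paste(samples$participant_id, samples$visit)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, visit) pairs at rows: ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  if (!all(samples$visit %in% 1:3)) {
    stop("visit must be 1, 2 or 3; offending rows: ",
         paste(which(!samples$visit %in% 1:3), collapse = ", "), call. = FALSE)
  }
  for (v in 1:3) {
    w <- visit_windows[[v]]
    bad <- which(samples$visit == v &
                   (samples$gestational_age < w[1] | samples$gestational_age > w[2]))
    if (length(bad)) {
      stop(sprintf("gestational_age outside window [%g, %g] for visit %d at rows: %s",
                   w[1], w[2], v, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  expected <- classify_birth_weight(samples$birth_weight_z)
  bad <- which(expected != samples$group)
  if (length(bad)) {
    stop("group label inconsistent with birth_weight_z (cutoffs +/- 1.3) at rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(samples)
}

#' Read a sample-annotation table from CSV/TSV
#'
#' @param path Path to a CSV (comma) or TSV (tab) file with the columns of
#'   [validate_sample_table()].
#' @param visit_windows Declared gestational-age windows per visit.
#' @return Validated sample data.frame.
#' @export
read_sample_table <- function(path, visit_windows = list(c(12, 19), c(21, 27), c(28, 34))) {
  df <- read.csv(path, sep = sniff_sep(path), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path, call. = FALSE)
  if ("nulliparous" %in% names(df)) df$nulliparous <- as.logical(df$nulliparous)
  validate_sample_table(df, visit_windows)
  df
}

#' Write a sample-annotation table
#' @param samples Sample data.frame.
#' @param path Output CSV/TSV path.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = sniff_sep(path), row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a protein abundance matrix (samples x proteins)
#'
#' Expects a header row of protein identifiers (gene names) and a first
#' column of sample identifiers. Values must be finite and strictly positive
#' (relative fluorescence units). Duplicate protein identifiers are an error.
#'
#' @param path CSV/TSV path.
#' @return Numeric matrix with sample rownames and protein colnames.
#' @export
read_protein_matrix <- function(path) {
  df <- read.csv(path, sep = sniff_sep(path), stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) stop("empty or malformed matrix in ", path, call. = FALSE)
  prot <- colnames(df)[-1]
  if (anyDuplicated(prot)) {
    stop("duplicated protein id(s) in header: ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive or non-numeric value at row %d (sample '%s'), column '%s'",
                 bad[1, 1], rownames(m)[bad[1, 1]], prot[bad[1, 2]]), call. = FALSE)
  }
  m
}

#' Write a protein abundance matrix
#' @param matrix Numeric matrix, samples as rows.
#' @param path Output CSV/TSV path.
#' @param id_column Name of the leading sample-id column.
#' @export
write_protein_matrix <- function(matrix, path, id_column = "sample_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = sniff_sep(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `id <tab> description <tab> member1 <tab> member2 ...`.
#' Members are de-duplicated within each set; duplicate set ids and lines
#' with fewer than three fields are errors reported with line numbers.
#'
#' @param path GMT file path.
#' @return Named list of class `gene_set_collection`; each element has
#'   `id`, `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("line %d of %s has %d field(s); GMT requires id, description and >= 1 member",
                   i, path, length(f)), call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("line %d of %s has no members", i, path), call. = FALSE)
    ids[i] <- f[1]
    sets[[i]] <- list(id = f[1], description = f[2], members = members)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' Write a results table as TSV
#'
#' Writes a header + rows TSV with numeric columns at 6 significant digits
#' and a deterministic row order given by `sort_by` (default: ascending q,
#' then protein id, when those columns exist).
#'
#' @param rows data.frame of results.
#' @param path Output TSV path.
#' @param sort_by Character vector of sort-key columns; keys absent from
#'   `rows` are ignored.
#' @return The path, invisibly.
#' @export
write_results_table <- function(rows, path, sort_by = c("q", "protein")) {
  rows <- as.data.frame(rows)
  keys <- intersect(sort_by, names(rows))
  if (length(keys) && nrow(rows)) {
    rows <- rows[do.call(order, rows[keys]), , drop = FALSE]
  }
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  read.csv(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#' @param path YAML file; top-level keys are passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cohort_config, raw)
}

#' Write a resolved configuration as YAML
#' @param config A `cohort_config`.
#' @param path Output path.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @importFrom utils write.table
NULL
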
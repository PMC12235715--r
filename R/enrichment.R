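## Over-representation analysis against GMT gene sets with BH-FDR,
## minimum-overlap filtering and Jaccard-based redundancy reduction.

#' Upper-tail hypergeometric p-value for a gene-set overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing a hit list of size
#' `n` from a background of size `N` containing `K` set members. Computed on
#' the log-gamma scale via [stats::phyper()].
#'
#' @param k Observed overlap (hits in the set).
#' @param K Set size within the background.
#' @param n Hit-list size.
#' @param N Background size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Over-representation analysis of a hit list
#'
#' Tests every gene set with at least one background member by the
#' upper-tail hypergeometric test (set members intersected with the
#' background first), adjusts across all tested sets by Benjamini-Hochberg,
#' and retains sets with overlap `>= min_overlap` and `q < q_cut`.
#'
#' @param hits Character vector of hit proteins (must be a subset of
#'   `background`).
#' @param background Character vector: all measured proteins passing quality
#'   filtration.
#' @param collection A `gene_set_collection` from [read_gmt()] (or a named
#'   list with `members` per set).
#' @param min_overlap Minimum overlap to retain a set (default 3).
#' @param q_cut q-value cutoff for retention (default 0.2).
#' @return data.frame of class `enrichment_table`: set_id, description, k,
#'   K, n, N, p, q, overlap_genes (comma-separated), sorted by (p, set_id).
#'   Attribute `n_tested` records the BH denominator.
#' @export
run_ora <- function(hits, background, collection, min_overlap = 3, q_cut = 0.2) {
  background <- unique(background)
  hits <- unique(hits)
  outside <- setdiff(hits, background)
  if (length(outside)) {
    stop("hit(s) outside the background: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(), overlap_genes = character(),
                      stringsAsFactors = FALSE)
  if (!length(hits)) {
    warning("empty hit list; returning no enrichments")
    class(empty) <- c("enrichment_table", "data.frame")
    return(empty)
  }
  N <- length(background)
  n <- length(hits)
  rows <- lapply(collection, function(s) {
    raw <- if (is.list(s)) s$members else s
    members <- intersect(raw, background)
    if (!length(members)) return(NULL)
    ov <- intersect(hits, members)
    data.frame(set_id = if (is.list(s)) s$id %||% NA_character_ else NA_character_,
               description = if (is.list(s)) s$description %||% "" else "",
               k = length(ov), K = length(members), n = n, N = N,
               p = hypergeometric_p(length(ov), length(members), n, N),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  keep_idx <- !vapply(rows, is.null, logical(1))
  if (!any(keep_idx)) {
    class(empty) <- c("enrichment_table", "data.frame")
    return(empty)
  }
  tab <- do.call(rbind, rows[keep_idx])
  if (any(is.na(tab$set_id))) tab$set_id <- names(collection)[keep_idx]
  tab$q <- bh_adjust(tab$p)
  n_tested <- nrow(tab)
  tab <- tab[tab$k >= min_overlap & tab$q < q_cut, , drop = FALSE]
  tab <- tab[order(tab$p, tab$set_id), , drop = FALSE]
  tab <- tab[, c("set_id", "description", "k", "K", "n", "N", "p", "q", "overlap_genes")]
  rownames(tab) <- NULL
  attr(tab, "n_tested") <- n_tested
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

enrichment_member_lists <- function(table) {
  out <- strsplit(table$overlap_genes, ",", fixed = TRUE)
  names(out) <- table$set_id
  out
}

#' Greedy Jaccard redundancy reduction of enriched terms
#'
#' Rows are visited by ascending p (ties by set id); a row is kept iff the
#' Jaccard similarity of its overlap gene list with every already-kept row
#' is below the cutoff. A set-based analogue of ontology "simplify"
#' procedures; deterministic, never removes the global minimum-p row.
#'
#' @param table An `enrichment_table`.
#' @param jaccard_cutoff Similarity threshold (default 0.7).
#' @return The filtered `enrichment_table` (subset of the input rows).
#' @export
simplify_terms <- function(table, jaccard_cutoff = 0.7) {
  if (nrow(table) <= 1L) return(table)
  ord <- order(table$p, table$set_id)
  members <- enrichment_member_lists(table)
  kept <- integer(0)
  for (i in ord) {
    ok <- all(vapply(kept, function(j) jaccard(members[[i]], members[[j]]) < jaccard_cutoff,
                     logical(1)))
    if (ok) kept <- c(kept, i)
  }
  out <- table[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of enriched terms by Jaccard distance
#'
#' Average-linkage agglomeration on `1 - Jaccard` of the overlap gene
#' lists; flat cluster labels by cutting the tree at a configurable height.
#'
#' @param table An `enrichment_table` with >= 1 row.
#' @param cut_height Tree-cut height for flat labels (default 0.8).
#' @return List with `labels` (named integer vector), `tree` (`hclust`, NULL
#'   for a single row) and `newick` (character tree representation).
#' @export
cluster_terms <- function(table, cut_height = 0.8) {
  if (nrow(table) == 0L) stop("no terms to cluster", call. = FALSE)
  if (nrow(table) == 1L) {
    return(list(labels = setNames(1L, table$set_id), tree = NULL, newick = ""))
  }
  members <- enrichment_member_lists(table)
  nm <- table$set_id
  d <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j > i) d[i, j] <- d[j, i] <- 1 - jaccard(members[[i]], members[[j]])
    }
  }
  tree <- hclust(as.dist(d), method = "average")
  labels <- cutree(tree, h = cut_height)
  newick <- ape::write.tree(ape::as.phylo(tree))
  list(labels = labels, tree = tree, newick = newick)
}
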
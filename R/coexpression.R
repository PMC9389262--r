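#' Preprocess an expression matrix
#'
#' Averages replicate columns within groups, adds a pseudo-count, takes log2,
#' and discards the lowest `drop_fraction` quantile of genes by the sum of
#' processed values across samples (low-intensity filter; exactly
#' `floor(drop_fraction * n)` genes are dropped, ties broken by gene id for
#' determinism).
#'
#' @param values non-negative numeric matrix, genes x samples (TPM).
#' @param replicate_groups character vector assigning each column to a
#'   replicate group (e.g. a time point); one mean column is kept per group,
#'   in first-appearance order.
#' @param pseudo pseudo-count added before the log (default 1).
#' @param drop_fraction fraction of genes discarded (default 0.25).
#' @return list: `values` (processed matrix, genes x groups), `dropped`
#'   (character vector of discarded gene ids).
#' @export
preprocess_expression <- function(values, replicate_groups, pseudo = 1,
                                  drop_fraction = 0.25) {
  stopifnot(is.matrix(values), ncol(values) == length(replicate_groups))
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  groups <- unique(replicate_groups)
  if (length(groups) < 2) stop("at least 2 replicate groups (time points) required")
  avg <- vapply(groups, function(g)
    rowMeans(values[, replicate_groups == g, drop = FALSE]), numeric(nrow(values)))
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1, dimnames = list(rownames(values), groups))
  proc <- log2(avg + pseudo)
  sums <- rowSums(proc)
  ord <- order(sums, rownames(proc))
  n_drop <- floor(drop_fraction * nrow(proc))
  dropped <- rownames(proc)[ord][seq_len(n_drop)]
  keep <- setdiff(rownames(proc), dropped)
  list(values = proc[keep, , drop = FALSE], dropped = dropped)
}

#' Pearson correlation of every gene with a guide gene
#'
#' @param processed processed matrix from [preprocess_expression()]`$values`.
#' @param guide_gene_id row name of the guide gene (must have survived the
#'   low-intensity filter).
#' @return data frame `gene_id`, `R`; zero-variance genes get `NA` (excluded
#'   from downstream ranking, never NaN).
#' @export
correlate_with_guide <- function(processed, guide_gene_id) {
  if (!guide_gene_id %in% rownames(processed))
    stop("guide gene ", guide_gene_id, " absent from the processed matrix")
  g <- processed[guide_gene_id, ]
  if (stats::sd(g) == 0) stop("guide gene ", guide_gene_id, " has zero variance")
  sds <- apply(processed, 1, stats::sd)
  R <- rep(NA_real_, nrow(processed))
  ok <- sds > 0
  R[ok] <- as.numeric(stats::cor(t(processed[ok, , drop = FALSE]), g))
  data.frame(gene_id = rownames(processed), R = R, stringsAsFactors = FALSE)
}

#' Permutation null distribution of correlation coefficients
#'
#' Randomly selects `n_signals` genes, shuffles each selected gene's sample
#' order, correlates every shuffled signal against every unshuffled signal,
#' and pools all resulting R values — the empirical null against which real
#' guide correlations are judged.
#'
#' @param processed processed matrix ([preprocess_expression()]`$values`).
#' @param n_signals number of signals to shuffle (clipped with a warning if
#'   more than available).
#' @param seed optional integer seed.
#' @return sorted numeric vector of pooled null R values.
#' @export
permutation_null <- function(processed, n_signals = 1000L, seed = NULL) {
  sds <- apply(processed, 1, stats::sd)
  mat <- processed[sds > 0, , drop = FALSE]
  if (n_signals > nrow(mat)) {
    warning("n_signals clipped to ", nrow(mat))
    n_signals <- nrow(mat)
  }
  .with_seed(seed, {
    sel <- sample.int(nrow(mat), n_signals)
    shuf <- t(apply(mat[sel, , drop = FALSE], 1, sample))
    null_R <- as.numeric(stats::cor(t(shuf), t(mat)))
    sort(null_R[!is.na(null_R)])
  })
}

#' Right-tail empirical p-value from a permutation null
#'
#' `p(R) = #\{null >= R\} / #null` — one minus the empirical cdf with a
#' right-continuous step convention, so the maximum pooled null R gets
#' `1/#null`, not 0.
#'
#' @param R numeric vector of observed correlations.
#' @param null_R sorted pooled null from [permutation_null()].
#' @return numeric vector of p-values, non-increasing in `R`.
#' @export
empirical_pvalue <- function(R, null_R) {
  n <- length(null_R)
  stopifnot(n >= 1)
  p <- (n - findInterval(R, null_R, left.open = TRUE)) / n
  p[is.na(R)] <- NA_real_
  p
}

#' Overlap enrichment between two gene sets
#'
#' Observed intersection against the hypergeometric expectation
#' `|A| * |B| / |U|` within a common universe.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list: `observed`, `expected`, `fold`, `p_value` (upper
#'   hypergeometric tail via [hypergeom_tail()]).
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("both sets must be subsets of the universe")
  observed <- length(intersect(setA, setB))
  expected <- length(setA) * length(setB) / length(universe)
  list(
    observed = observed, expected = expected,
    fold = if (expected > 0) observed / expected else NA_real_,
    p_value = hypergeom_tail(length(universe), length(setA), length(setB), observed)
  )
}

#' Build and prune a guide-gene co-expression network
#'
#' Takes a primary gene's `n_guides` top-ranked co-expression partners as
#' guide genes, links each guide to its own `n_neighbors` top-ranked
#' partners, and (optionally) removes in a single pass every newly added node
#' (neither primary nor guide) connected by only one edge.
#'
#' @param ranked_lists named list: for each gene, a character vector of
#'   partners ordered by co-expression rank (ties in the source table broken
#'   by gene id upstream).
#' @param primary_gene the primary gene of interest.
#' @param n_guides number of guide genes (default 5).
#' @param n_neighbors partners linked per guide (default 50).
#' @param prune drop degree-1 newly added nodes (default `TRUE`).
#' @return an `igraph` graph; node attribute `role` is one of
#'   `"primary"`, `"guide"`, `"neighbor"`.
#' @export
guide_network <- function(ranked_lists, primary_gene, n_guides = 5L,
                          n_neighbors = 50L, prune = TRUE) {
  if (is.null(ranked_lists[[primary_gene]]))
    stop("no ranked list for primary gene ", primary_gene)
  ranks <- setdiff(ranked_lists[[primary_gene]], primary_gene)
  if (length(ranks) < n_guides)
    stop("fewer than ", n_guides, " ranked partners available for ", primary_gene)
  guides <- ranks[seq_len(n_guides)]
  edges <- data.frame(from = primary_gene, to = guides, stringsAsFactors = FALSE)
  for (g in guides) {
    if (is.null(ranked_lists[[g]]))
      stop("no ranked list for guide gene ", g)
    nb <- setdiff(ranked_lists[[g]], g)
    nb <- nb[seq_len(min(n_neighbors, length(nb)))]
    edges <- rbind(edges, data.frame(from = g, to = nb, stringsAsFactors = FALSE))
  }
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  gr <- igraph::simplify(gr)
  role <- rep("neighbor", igraph::vcount(gr))
  names(role) <- igraph::V(gr)$name
  role[primary_gene] <- "primary"
  role[guides] <- "guide"
  igraph::V(gr)$role <- unname(role[igraph::V(gr)$name])
  if (prune) {
    new_nodes <- igraph::V(gr)$name[igraph::V(gr)$role == "neighbor"]
    deg <- igraph::degree(gr)
    drop <- new_nodes[deg[new_nodes] == 1]
    gr <- igraph::delete_vertices(gr, drop)
  }
  gr
}
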
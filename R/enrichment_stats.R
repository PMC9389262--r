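#' Hypergeometric probability of exactly m motif-positive genes
#'
#' Probability of drawing exactly `m` motif-positive genes in a sample of `n`
#' from a population of `N` genes of which `K` are motif-positive,
#' \eqn{C(K,m) C(N-K,n-m) / C(N,n)}, evaluated in log space.
#'
#' @param N population size (genes searched).
#' @param K motif-positive genes in the population.
#' @param n genes in the tested set.
#' @param m motif-positive genes in the tested set.
#' @return the probability mass; exactly 0 when `m > K` or `n - m > N - K`.
#' @export
hypergeom_pmf <- function(N, K, n, m) {
  .check_hyper_args(N, K, n, m)
  stats::dhyper(m, K, N - K, n)
}

#' Hypergeometric tail probability of m or more motif-positive genes
#'
#' \eqn{P(X \ge m) = 1 - \sum_{i=0}^{m-1} P(X = i)}; `m = 0` gives exactly 1.
#' Applied unconditionally (also in the depletion direction), matching how the
#' per-feature enrichment table is reported.
#'
#' @inheritParams hypergeom_pmf
#' @return upper-tail probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_tail(27414, 5540, 52, 30)  # ~3e-9
hypergeom_tail <- function(N, K, n, m) {
  .check_hyper_args(N, K, n, m)
  if (m == 0) return(1)
  stats::phyper(m - 1, K, N - K, n, lower.tail = FALSE)
}

.check_hyper_args <- function(N, K, n, m) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(m) == 1)
  v <- c(N, K, n, m)
  if (any(v < 0) || any(v != round(v))) stop("N, K, n, m must be non-negative integers")
  if (K > N) stop("K > N")
  if (n > N) stop("n > N")
  if (m > n) stop("m > n")
  invisible(TRUE)
}

#' Hypergeometric enrichment summary for a gene set
#'
#' Expectation `n*K/N`, fold enrichment `m/expected`, the upper-tail p-value
#' from [hypergeom_tail()], and the symmetric integer range around
#' `round(expected)` that holds at least `level` of the probability mass (the
#' printed "99.9% confidence range"; informational only — see the vignette).
#'
#' @inheritParams hypergeom_pmf
#' @param level probability mass the symmetric range must reach.
#' @return an `enrichment_result` (also a list): `N,K,n,m,expected,fold,
#'   p_value,conf_range`.
#' @export
enrichment_summary <- function(N, K, n, m, level = 0.999) {
  .check_hyper_args(N, K, n, m)
  expected <- n * K / N
  fold <- if (expected > 0) m / expected else NA_real_
  p <- hypergeom_tail(N, K, n, m)
  r <- round(expected)
  d <- 0L
  repeat {
    lo <- max(0L, r - d); hi <- min(n, r + d)
    if (sum(stats::dhyper(lo:hi, K, N - K, n)) >= level) break
    if (lo == 0L && hi == n) break
    d <- d + 1L
  }
  structure(
    list(N = N, K = K, n = n, m = m, expected = expected, fold = fold,
         p_value = p, conf_range = c(max(0L, r - d), r + d)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "hypergeometric enrichment: m=%d of n=%d (K=%d of N=%d)\n  expected %.1f [%d, %d], fold %.2f, p = %.3g\n",
    x$m, x$n, x$K, x$N, x$expected, x$conf_range[1], x$conf_range[2], x$fold, x$p_value))
  invisible(x)
}

#' Generate i.i.d. background sequences
#'
#' Pseudo-random sequences with per-base probabilities set by the GC content
#' (`C = G = gc/2`, `A = T = (1-gc)/2` unless `base_probs` overrides) — the
#' random-sequence control for motif-hit frequencies.
#'
#' @param count number of sequences.
#' @param length sequence length (nt).
#' @param gc GC content in (0, 1).
#' @param base_probs optional explicit `(A,C,G,T)` probabilities.
#' @param seed optional integer seed; the caller's RNG stream is preserved.
#' @return character vector of `count` sequences.
#' @export
generate_background <- function(count, length, gc = 0.332, base_probs = NULL,
                                seed = NULL) {
  stopifnot(count >= 1, length >= 1)
  p <- .base_probs(gc, base_probs)
  .with_seed(seed, {
    draws <- sample.int(4L, count * length, replace = TRUE, prob = p)
    codes <- matrix(c(65L, 67L, 71L, 84L)[draws], nrow = count)
    vapply(seq_len(count), function(i) intToUtf8(codes[i, ]), character(1))
  })
}

#' Shuffle sequences base-by-base
#'
#' Per-sequence mononucleotide permutation: composition of every sequence is
#' preserved exactly (the shuffled-promoter control behind the empirical FDR).
#'
#' @param seqs character vector of sequences.
#' @param seed optional integer seed.
#' @return character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(seqs, seed = NULL) {
  .with_seed(seed, {
    vapply(seqs, function(s) {
      v <- utf8ToInt(s)
      intToUtf8(v[sample.int(length(v))])
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Empirical false discovery rate from a shuffled-sequence null
#'
#' `FDR(t) = #\{p_null <= t\} / #\{p_real <= t\}` where `p_null` comes from
#' rerunning the identical enrichment computation on shuffled sequences.
#' Values above 1 are clipped to 1 (with a message); an empty denominator
#' gives `NA`.
#'
#' @param p_real p-values on the real data.
#' @param p_null p-values on the shuffled data (same computation).
#' @param t significance threshold.
#' @return the FDR estimate in \[0, 1\], or `NA` when no real calls are made.
#' @export
empirical_fdr <- function(p_real, p_null, t) {
  if (!length(p_real)) stop("p_real is empty")
  stopifnot(length(t) == 1, t >= 0, t <= 1)
  n_real <- sum(p_real <= t, na.rm = TRUE)
  n_null <- sum(p_null <= t, na.rm = TRUE)
  if (n_real == 0) return(NA_real_)
  fdr <- n_null / n_real
  if (fdr > 1) {
    message("empirical FDR ", signif(fdr, 3), " clipped to 1")
    fdr <- 1
  }
  fdr
}

#' Motif enrichment across orthologous upstream regions
#'
#' For every anchor gene, tests whether its ortholog set (anchor gene plus all
#' orthologs, counting polyploid multiplicity) carries more motif-positive
#' upstream regions than expected from the pooled multi-species universe:
#' `N` = all genes searched across all genomes, `K` = all motif-positive
#' genes, `n` = ortholog-set size, `m` = motif-positive members; p-value is
#' the upper hypergeometric tail.
#'
#' @param catalog an ortholog catalog from [read_orthologs()] (data frame with
#'   `anchor_gene_id`, `species_id`, `gene_id`; the anchor gene is a member).
#' @param hit_table per-gene hit table from [tabulate_hits()] over the pooled
#'   universe.
#' @return data frame with one row per anchor gene: `anchor_gene_id`, `n`,
#'   `m`, `expected`, `fold`, `p_value`.
#' @export
our_enrichment <- function(catalog, hit_table) {
  stopifnot(is.data.frame(catalog), is.data.frame(hit_table))
  missing_genes <- setdiff(catalog$gene_id, hit_table$gene_id)
  if (length(missing_genes))
    stop("ortholog set member(s) absent from hit table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  N <- nrow(hit_table)
  K <- sum(hit_table$has_hit)
  hit <- hit_table$has_hit
  names(hit) <- hit_table$gene_id
  sets <- split(catalog$gene_id, catalog$anchor_gene_id)
  res <- lapply(names(sets), function(a) {
    members <- sets[[a]]
    n <- length(members)
    m <- sum(hit[members])
    data.frame(anchor_gene_id = a, n = n, m = m,
               expected = n * K / N, fold = if (K > 0) m / (n * K / N) else NA_real_,
               p_value = hypergeom_tail(N, K, n, m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
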
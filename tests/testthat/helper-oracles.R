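# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Regex-based both-strand motif scan: returns a canonical set of
# (strand, offset_atg) hit keys for comparison with scan_region().
oracle_scan_keys <- function(seq, iupac = "CNTNGNNNNNNNCG", anchor_offset = -nchar(seq)) {
  iupac_re <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  rex <- paste0("(?=(", paste(iupac_re[strsplit(iupac, "")[[1]]], collapse = ""), "))")
  m <- nchar(iupac)
  starts_of <- function(s) {
    g <- gregexpr(rex, s, perl = TRUE)[[1]]
    if (g[1] == -1) integer(0) else as.integer(g)
  }
  L <- nchar(seq)
  fw <- starts_of(seq)
  rv <- starts_of(oracle_revcomp(seq))
  keys <- character(0)
  if (length(fw)) keys <- paste0("+", anchor_offset + fw - 1L)
  if (length(rv)) {
    left <- L - rv - m + 2L
    keys <- c(keys, paste0("-", anchor_offset + left - 1L))
  }
  sort(keys)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Exact hypergeometric pmf by enumeration over all C(N, n) draws (tiny N only).
oracle_hyper_pmf_enum <- function(N, K, n, m) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) == m)  # items 1..K are the "positive" genes
}

# AUC as the Mann-Whitney U statistic over all (positive, negative) pairs.
oracle_auc_pairs <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Closed-form null for random extended AW-box sites: identities are
# n_fixed + Binomial(n_var, q) with q the per-position coincidence
# probability under the background.
oracle_pair_null <- function(gc = 0.332, n_fixed = 5, n_var = 13, min_identity = 15) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  q <- sum(p^2)
  list(mean_identity = n_fixed + n_var * q,
       p_conserved = stats::pbinom(min_identity - n_fixed - 1, n_var, q,
                                   lower.tail = FALSE))
}

random_dna <- function(n, len, gc = 0.33) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""), character(1))
}
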
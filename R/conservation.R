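#' Ungapped identity between two extended motif sites
#'
#' Counts positions with equal bases between two equal-length extended sites
#' (default 18 nt: 14-nt core plus 2 flanking bases each side). An `N` equals
#' nothing, including another `N`.
#'
#' @param a,b extended site sequences, uppercase.
#' @param width required site length (default 18).
#' @return integer identity count in `0:width`.
#' @export
#' @examples
#' site_identity("AACATAGAAAAAAACGAA", "TTCATAGAAAAAAACGTT")  # 14
site_identity <- function(a, b, width = 18L) {
  stopifnot(length(a) == 1, length(b) == 1)
  if (nchar(a) != width || nchar(b) != width)
    stop("both sites must have length ", width)
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  sum(va == vb & va != 78L)  # 78 = N
}

# Vectorised identity of one site against many (all same width).
.site_identity_many <- function(a, bs, width = 18L) {
  va <- utf8ToInt(a)
  vapply(bs, function(b) {
    vb <- utf8ToInt(b)
    sum(va == vb & va != 78L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Call cross-species conservation of anchor-gene motif sites
#'
#' For each extended site of each anchor gene, a species is *conserving* if
#' any of its ortholog genes carries any site in the same gene-relative
#' orientation with at least `min_identity` of `width` identities. If at least
#' one conserving species exists the anchor species itself is counted as
#' conserved; the species conservation ratio is the conserved-species count
#' divided by `n_species_total` (not by the ortholog set size). Truncated
#' extended sites are never compared.
#'
#' @param hits pooled hit data frame ([scan_regions()]) covering anchor and
#'   ortholog genes (columns `gene_id`, `species_id`, `strand`,
#'   `extended_seq`, `truncated`, `offset_atg`).
#' @param catalog ortholog catalog ([read_orthologs()]).
#' @param anchor_species species id of the anchor genome.
#' @param n_species_total total species assessed (denominator; default 12).
#' @param min_identity identity threshold for a conservation relation
#'   (default 15 of 18, 83.3%).
#' @param width extended-site length.
#' @return list with `sites` (one row per non-truncated anchor site:
#'   `anchor_gene_id`, `offset_atg`, `strand`, `extended_seq`, `n_conserved`,
#'   `species_ratio`, `conserved_species` comma-separated) and `genes`
#'   (per anchor gene: `anchor_gene_id`, `max_ratio`, `n_sites`).
#' @export
conservation_call <- function(hits, catalog, anchor_species,
                              n_species_total = 12L, min_identity = 15L,
                              width = 18L) {
  stopifnot(is.data.frame(hits), is.data.frame(catalog))
  anchors <- unique(catalog$anchor_gene_id)
  usable <- hits[!hits$truncated & !is.na(hits$extended_seq), , drop = FALSE]
  n_skipped <- sum(hits$truncated | is.na(hits$extended_seq))
  if (n_skipped > 0)
    message(n_skipped, " truncated extended site(s) skipped in conservation calls")

  by_gene <- split(seq_len(nrow(usable)), usable$gene_id)
  cat_by_anchor <- split(catalog[, c("species_id", "gene_id")], catalog$anchor_gene_id)

  site_rows <- vector("list", length(anchors))
  gene_rows <- vector("list", length(anchors))
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    a_idx <- by_gene[[a]]
    a_sites <- if (is.null(a_idx)) usable[0, ] else usable[a_idx, , drop = FALSE]
    a_sites <- a_sites[a_sites$species_id == anchor_species, , drop = FALSE]
    members <- cat_by_anchor[[a]]
    members <- members[members$species_id != anchor_species, , drop = FALSE]
    if (nrow(a_sites) == 0) {
      gene_rows[[k]] <- data.frame(anchor_gene_id = a, max_ratio = 0,
                                   n_sites = 0L, stringsAsFactors = FALSE)
      next
    }
    # candidate ortholog sites grouped by species
    o_idx <- unlist(by_gene[intersect(members$gene_id, names(by_gene))], use.names = FALSE)
    o_sites <- if (length(o_idx)) usable[o_idx, , drop = FALSE] else usable[0, ]
    sp_of_gene <- members$species_id
    names(sp_of_gene) <- members$gene_id
    if (nrow(o_sites)) o_sites$.species <- sp_of_gene[o_sites$gene_id]

    res <- lapply(seq_len(nrow(a_sites)), function(i) {
      s <- a_sites[i, ]
      conserved_sp <- character(0)
      if (nrow(o_sites)) {
        same <- o_sites[o_sites$strand == s$strand, , drop = FALSE]
        if (nrow(same)) {
          ids <- .site_identity_many(s$extended_seq, same$extended_seq, width)
          conserved_sp <- unique(same$.species[ids >= min_identity])
        }
      }
      n_cons <- if (length(conserved_sp)) length(conserved_sp) + 1L else 0L
      data.frame(
        anchor_gene_id = a, offset_atg = s$offset_atg, strand = s$strand,
        extended_seq = s$extended_seq, n_conserved = n_cons,
        species_ratio = n_cons / n_species_total,
        conserved_species = if (n_cons)
          paste(c(anchor_species, sort(conserved_sp)), collapse = ",") else "",
        stringsAsFactors = FALSE
      )
    })
    srows <- do.call(rbind, res)
    site_rows[[k]] <- srows
    gene_rows[[k]] <- data.frame(anchor_gene_id = a,
                                 max_ratio = max(srows$species_ratio),
                                 n_sites = nrow(srows), stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  if (is.null(sites))
    sites <- data.frame(anchor_gene_id = character(0), offset_atg = integer(0),
                        strand = character(0), extended_seq = character(0),
                        n_conserved = integer(0), species_ratio = numeric(0),
                        conserved_species = character(0), stringsAsFactors = FALSE)
  genes <- do.call(rbind, gene_rows)
  rownames(sites) <- rownames(genes) <- NULL
  list(sites = sites, genes = genes)
}

#' By-chance conservation null for random motif sites
#'
#' Samples pairs of extended sites whose consensus (non-degenerate) pattern
#' positions are fixed and whose degenerate/flank positions are drawn i.i.d.
#' from the background base probabilities, and reports the mean pairwise
#' identity and the fraction of pairs reaching the conservation threshold —
#' the by-chance rate of calling two unrelated sites conserved.
#'
#' @param n_pairs number of site pairs (>= 1e4 for a stable tail estimate).
#' @param pattern extended-site pattern (default the 18-nt extended AW-box).
#' @param gc background GC content (default 0.332).
#' @param base_probs optional explicit `(A,C,G,T)` probabilities.
#' @param min_identity conservation threshold (default 15).
#' @param seed optional integer seed.
#' @return list: `mean_identity`, `p_conserved`, `n_pairs`, `n_fixed`
#'   (always-matching consensus positions).
#' @export
random_pair_null <- function(n_pairs, pattern = motif_pattern("NNCNTNGNNNNNNNCGNN"),
                             gc = 0.332, base_probs = NULL, min_identity = 15L,
                             seed = NULL) {
  stopifnot(n_pairs >= 1)
  p <- .base_probs(gc, base_probs)
  var_pos <- which(vapply(pattern$allowed, length, integer(1)) > 1)
  n_fixed <- pattern$length - length(var_pos)
  .with_seed(seed, {
    matches <- integer(n_pairs)
    chunk <- 250000L
    done <- 0L
    while (done < n_pairs) {
      nc <- min(chunk, n_pairs - done)
      mm <- integer(nc)
      for (j in var_pos) {
        pj <- p[pattern$allowed[[j]]]
        pj <- pj / sum(pj)
        a <- sample.int(length(pj), nc, replace = TRUE, prob = pj)
        b <- sample.int(length(pj), nc, replace = TRUE, prob = pj)
        mm <- mm + (a == b)
      }
      matches[(done + 1L):(done + nc)] <- mm
      done <- done + nc
    }
    ident <- n_fixed + matches
    list(mean_identity = mean(ident),
         p_conserved = mean(ident >= min_identity),
         n_pairs = n_pairs, n_fixed = n_fixed)
  })
}

#' Per-position base-frequency matrix of aligned sites
#'
#' @param sites character vector of equal-length sequences over `{A,C,G,T}`.
#' @return 4 x L numeric matrix (rows A, C, G, T), columns summing to 1;
#'   suitable for logo rendering or MEME-format export.
#' @export
site_frequency_matrix <- function(sites) {
  stopifnot(length(sites) >= 1)
  L <- unique(nchar(sites))
  if (length(L) != 1) stop("sites must have equal lengths")
  if (any(grepl("[^ACGT]", sites))) stop("sites must be over {A,C,G,T}")
  m <- do.call(rbind, strsplit(sites, ""))
  freq <- vapply(seq_len(L), function(j)
    table(factor(m[, j], levels = c("A", "C", "G", "T"))) / length(sites),
    numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  freq
}

#' Export a frequency matrix in MEME minimal motif format
#'
#' @param freq 4 x L frequency matrix from [site_frequency_matrix()].
#' @param path output file.
#' @param name motif name written into the file.
#' @param nsites number of contributing sites (annotation only).
#' @param background background `(A,C,G,T)` frequencies.
#' @return the path, invisibly.
#' @export
write_meme_motif <- function(freq, path, name = "motif",
                             nsites = 20L,
                             background = c(A = 0.334, C = 0.166, G = 0.166, T = 0.334)) {
  stopifnot(is.matrix(freq), nrow(freq) == 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f",
            background[1], background[2], background[3], background[4]), "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            ncol(freq), as.integer(nsites))
  ), con)
  writeLines(apply(freq, 2, function(col)
    sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])), con)
  invisible(path)
}
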
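#' Compile a degenerate IUPAC motif pattern
#'
#' Turns an IUPAC nucleotide string (default the 14-nt AW-box consensus
#' `CNTNG(N)7CG`) into a compiled pattern with per-position allowed base sets.
#' An `N` in a *scanned sequence* never matches any pattern position, including
#' pattern `N` — masked bases cannot produce hits.
#'
#' @param iupac a string over the IUPAC nucleotide alphabet.
#' @return an object of class `motif_pattern` with elements `iupac`, `length`
#'   and `allowed` (list of character vectors, one per position).
#' @export
#' @examples
#' motif_pattern()              # the AW-box
#' motif_pattern("GNTNGNNNNNNNCG")  # a documented non-canonical variant
motif_pattern <- function(iupac = "CNTNGNNNNNNNCG") {
  stopifnot(is.character(iupac), length(iupac) == 1, nchar(iupac) >= 1)
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  allowed <- .IUPAC[chars]
  structure(
    list(
      iupac = toupper(iupac),
      length = length(chars),
      allowed = allowed,
      allowed_int = lapply(allowed, function(b) .BASE_INT[b])
    ),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern:", x$iupac, "(", x$length, "nt )\n")
  invisible(x)
}

# Start positions (1-based) of pattern matches on the given strand of an
# integer-encoded sequence. N in the sequence matches nothing.
.match_starts <- function(seq_int, pattern) {
  L <- length(seq_int)
  m <- pattern$length
  if (L < m) return(integer(0))
  ns <- L - m + 1L
  ok <- rep(TRUE, ns)
  for (j in seq_len(m)) {
    ok <- ok & (seq_int[j:(j + ns - 1L)] %in% pattern$allowed_int[[j]])
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Scan one region sequence for motif hits on both strands
#'
#' Reports every match of `pattern` on the gene-sense strand and its reverse
#' complement, including overlapping and mutually reverse-complementary
#' matches. Each hit carries the matched core sequence, the extended site
#' (core plus `flank` bases on each side, read on the matched strand) and the
#' position of its 5'-most core base relative to the A of the start codon in
#' gene orientation (`offset_atg`). Hits whose extended site would run off the
#' region are kept but flagged `truncated` (their `extended_seq` is `NA`).
#'
#' @param region a one-row data frame (or list) with at least `sequence` and
#'   `anchor_offset`; `gene_id`, `species_id`, `window_label` are carried
#'   through when present.
#' @param pattern a [motif_pattern()].
#' @param flank flanking bases captured on each side of the core (default 2,
#'   giving 18-nt extended sites for the 14-nt AW-box).
#' @return a data frame with columns `gene_id`, `species_id`, `strand`
#'   (`"+"` gene-sense, `"-"` antisense), `offset_atg`, `core_seq`,
#'   `extended_seq`, `truncated`.
#' @export
scan_region <- function(region, pattern = motif_pattern(), flank = 2L) {
  seq <- as.character(region$sequence)
  stopifnot(length(seq) == 1, !is.na(seq))
  if (grepl("[^ACGTN]", seq)) stop("region sequence must be uppercase over {A,C,G,T,N}")
  anchor_offset <- as.integer(region$anchor_offset)
  gene_id <- if (!is.null(region$gene_id)) as.character(region$gene_id) else NA_character_
  species_id <- if (!is.null(region$species_id)) as.character(region$species_id) else NA_character_

  L <- nchar(seq)
  m <- pattern$length
  fwd <- .seq_to_int(seq)
  starts_f <- .match_starts(fwd, pattern)
  rc <- revcomp(seq)
  rci <- .seq_to_int(rc)
  starts_r <- .match_starts(rci, pattern)

  ext_at <- function(src, i) {
    if (i - flank >= 1L && i + m - 1L + flank <= L)
      substr(src, i - flank, i + m - 1L + flank)
    else NA_character_
  }

  rows <- list()
  if (length(starts_f)) {
    rows[[1]] <- data.frame(
      gene_id = gene_id, species_id = species_id, strand = "+",
      offset_atg = anchor_offset + starts_f - 1L,
      core_seq = substring(seq, starts_f, starts_f + m - 1L),
      extended_seq = vapply(starts_f, function(i) ext_at(seq, i), character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (length(starts_r)) {
    # match at rc position q covers gene-orientation positions (L-q-m+2)..(L-q+1)
    left <- L - starts_r - m + 2L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, species_id = species_id, strand = "-",
      offset_atg = anchor_offset + left - 1L,
      core_seq = substring(rc, starts_r, starts_r + m - 1L),
      extended_seq = vapply(starts_r, function(i) ext_at(rc, i), character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    out <- data.frame(
      gene_id = character(0), species_id = character(0), strand = character(0),
      offset_atg = integer(0), core_seq = character(0),
      extended_seq = character(0), truncated = logical(0),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  out <- do.call(rbind, rows)
  out$truncated <- is.na(out$extended_seq)
  out <- out[order(out$offset_atg, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many regions
#'
#' @param regions data frame of region sequences as returned by
#'   [extract_regions()] (columns `gene_id`, `species_id`, `sequence`,
#'   `anchor_offset`).
#' @inheritParams scan_region
#' @return one hit data frame, rows in region order.
#' @export
scan_regions <- function(regions, pattern = motif_pattern(), flank = 2L) {
  stopifnot(is.data.frame(regions))
  n <- nrow(regions)
  acc <- vector("list", n)
  m <- pattern$length
  for (i in seq_len(n)) {
    seq <- regions$sequence[i]
    L <- nchar(seq)
    ao <- regions$anchor_offset[i]
    fwd <- .seq_to_int(seq)
    starts_f <- .match_starts(fwd, pattern)
    rc <- revcomp(seq)
    starts_r <- .match_starts(.seq_to_int(rc), pattern)
    if (!length(starts_f) && !length(starts_r)) next
    strand <- c(rep("+", length(starts_f)), rep("-", length(starts_r)))
    src_start <- c(starts_f, starts_r)
    left <- c(starts_f, L - starts_r - m + 2L)
    src <- c(rep(seq, length(starts_f)), rep(rc, length(starts_r)))
    full <- src_start - flank >= 1L & src_start + m - 1L + flank <= L
    ext <- rep(NA_character_, length(src_start))
    ext[full] <- substring(src[full], src_start[full] - flank,
                           src_start[full] + m - 1L + flank)
    acc[[i]] <- data.frame(
      gene_id = regions$gene_id[i], species_id = regions$species_id[i],
      strand = strand, offset_atg = ao + left - 1L,
      core_seq = substring(src, src_start, src_start + m - 1L),
      extended_seq = ext, truncated = !full, stringsAsFactors = FALSE
    )
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) {
    return(data.frame(
      gene_id = character(0), species_id = character(0), strand = character(0),
      offset_atg = integer(0), core_seq = character(0),
      extended_seq = character(0), truncated = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Signed motif distance to the transcription start site
#'
#' The distance is measured from whichever motif
#' end (first or last core base) lies closer to the TSS; ties go to the first
#' base. All offsets are in gene orientation relative to the A of the start
#' codon (upstream negative).
#'
#' @param offset_atg start-codon-relative offset of the 5'-most core base.
#' @param tss_offset_atg start-codon-relative offset of the TSS; `NA` if
#'   unknown (the distance is then `NA`, never 0).
#' @param motif_length core motif length (default 14).
#' @return integer vector of signed TSS distances.
#' @export
#' @examples
#' site_position(-5, 0)   # spans TSS-relative [-5, +8] -> -5
#' site_position(-60, -103)  # BCCP1-style site: first base at +43
site_position <- function(offset_atg, tss_offset_atg, motif_length = 14L) {
  first <- offset_atg - tss_offset_atg
  last <- offset_atg + motif_length - 1L - tss_offset_atg
  pick_last <- abs(last) < abs(first)
  out <- ifelse(pick_last, last, first)
  out[is.na(tss_offset_atg)] <- NA_integer_
  as.integer(out)
}

#' Tabulate motif hits over a gene universe
#'
#' @param hits hit data frame from [scan_regions()].
#' @param gene_universe character vector of all searched gene ids, including
#'   zero-hit genes.
#' @return data frame with one row per universe gene: `gene_id`, `n_hits`,
#'   `has_hit`; the universe size is `nrow()`.
#' @export
tabulate_hits <- function(hits, gene_universe) {
  stopifnot(is.character(gene_universe), !anyDuplicated(gene_universe))
  outside <- setdiff(hits$gene_id, gene_universe)
  if (length(outside))
    stop("hits reference gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  counts <- table(factor(hits$gene_id, levels = gene_universe))
  data.frame(
    gene_id = gene_universe,
    n_hits = as.integer(counts),
    has_hit = as.integer(counts) >= 1L,
    stringsAsFactors = FALSE
  )
}
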
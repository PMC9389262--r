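#' Read gene models from a genome FASTA and GFF3 annotation
#'
#' Builds one representative gene model per protein-coding gene: chromosome,
#' strand, start-codon position (first base of the ATG in transcription
#' orientation), stop-codon end, and a TSS with provenance. TSS evidence is
#' taken from a TSS summit table when available (`tss_source = "tss_peak"`,
#' highest-scoring summit per gene), otherwise from the mRNA feature start
#' (`"mrna_start"`); genes with neither get `"none"`.
#'
#' @param fasta_path genome FASTA (sequence ids must match GFF seqids).
#' @param gff_path GFF3 annotation, 1-based inclusive coordinates, with
#'   `gene` features and `mRNA`/`CDS` children.
#' @param tss_table_path optional TSV with columns
#'   `gene_id, chrom, summit, score`.
#' @param model_policy representative-model policy; `"first_mrna"` (default)
#'   takes the first-listed mRNA per gene.
#' @param representative_ids optional character vector of mRNA ids that
#'   overrides the policy where present.
#' @param species_id species label stamped on every model.
#' @return data frame of gene models: `gene_id`, `species_id`, `chrom_id`,
#'   `strand`, `start_codon_pos`, `stop_codon_end`, `tss_pos`, `tss_source`,
#'   and `tss_offset_atg` (TSS position relative to the A of ATG in gene
#'   orientation, negative upstream).
#' @export
read_genome_annotation <- function(fasta_path, gff_path, tss_table_path = NULL,
                                   model_policy = "first_mrna",
                                   representative_ids = NULL,
                                   species_id = NA_character_) {
  model_policy <- match.arg(model_policy)
  .validate_gff_lines(gff_path)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  typ <- as.character(gff$type)
  genes <- gff[typ == "gene"]
  mrnas <- gff[typ == "mRNA"]
  cdss <- gff[typ == "CDS"]
  if (!length(genes)) stop("no gene features in ", gff_path)

  first_parent <- function(p) vapply(p, function(x)
    if (length(x)) x[[1]] else NA_character_, character(1))
  mrna_parent <- first_parent(mrnas$Parent)
  cds_parent <- first_parent(cdss$Parent)

  tss_tab <- NULL
  if (!is.null(tss_table_path)) {
    tss_tab <- utils::read.delim(tss_table_path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "summit", "score")
    if (!all(need %in% names(tss_tab)))
      stop("TSS table must have columns: ", paste(need, collapse = ", "))
  }

  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    gid <- g$ID
    chrom <- as.character(GenomicRanges::seqnames(g))
    if (!chrom %in% names(genome)) {
      warning("gene ", gid, " on unknown chromosome ", chrom, "; skipped")
      return(NULL)
    }
    strand <- as.character(GenomicRanges::strand(g))
    if (!strand %in% c("+", "-")) {
      warning("gene ", gid, " without strand; skipped")
      return(NULL)
    }
    g_mrnas <- mrnas[!is.na(mrna_parent) & mrna_parent == gid]
    model_id <- NULL
    if (length(g_mrnas)) {
      model_id <- g_mrnas$ID[1]
      if (!is.null(representative_ids)) {
        hit <- intersect(representative_ids, g_mrnas$ID)
        if (length(hit)) model_id <- hit[1]
      }
      model_cds <- cdss[!is.na(cds_parent) & cds_parent == model_id]
    } else {
      # CDS attached directly to the gene
      model_cds <- cdss[!is.na(cds_parent) & cds_parent == gid]
    }
    if (!length(model_cds)) {
      warning("gene ", gid, " has no CDS; skipped")
      return(NULL)
    }
    if (strand == "+") {
      start_codon <- min(GenomicRanges::start(model_cds))
      stop_end <- max(GenomicRanges::end(model_cds))
    } else {
      start_codon <- max(GenomicRanges::end(model_cds))
      stop_end <- min(GenomicRanges::start(model_cds))
    }

    tss_pos <- NA_integer_
    tss_source <- "none"
    if (!is.null(tss_tab) && gid %in% tss_tab$gene_id) {
      cand <- tss_tab[tss_tab$gene_id == gid & tss_tab$chrom == chrom, , drop = FALSE]
      if (nrow(cand)) {
        tss_pos <- as.integer(cand$summit[which.max(cand$score)])
        tss_source <- "tss_peak"
      }
    }
    if (tss_source == "none" && length(g_mrnas)) {
      mr <- g_mrnas[1]
      tss_pos <- if (strand == "+") GenomicRanges::start(mr) else GenomicRanges::end(mr)
      tss_source <- "mrna_start"
    }
    data.frame(
      gene_id = gid, species_id = species_id, chrom_id = chrom, strand = strand,
      start_codon_pos = as.integer(start_codon),
      stop_codon_end = as.integer(stop_end),
      tss_pos = as.integer(tss_pos), tss_source = tss_source,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable gene models in ", gff_path)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in annotation")
  out$tss_offset_atg <- ifelse(
    out$strand == "+", out$tss_pos - out$start_codon_pos,
    out$start_codon_pos - out$tss_pos
  )
  rownames(out) <- NULL
  out
}

.validate_gff_lines <- function(gff_path) {
  lines <- readLines(gff_path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf != 9L]
  if (length(bad))
    stop("malformed GFF line ", bad[1], " in ", gff_path,
         " (expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1]], ")")
  invisible(TRUE)
}

#' Extract sequence windows relative to the start or stop codon
#'
#' Returns each gene's window read 5'->3' in transcription orientation
#' (reverse-complemented for minus-strand genes). Window coordinates are
#' signed offsets in gene orientation where 0 is the anchor base (the A of
#' ATG, or the last base of the stop codon): the standard upstream window is
#' `c(-500, -1)`. Windows are truncated at chromosome ends; the reported
#' `anchor_offset` (offset of the window's first returned base) stays honest.
#'
#' @param genome a `DNAStringSet` or FASTA path.
#' @param gene_models data frame from [read_genome_annotation()].
#' @param window signed `c(from, to)` range in gene orientation, `from <= to`.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param window_label label stamped on the rows; derived from the window if
#'   `NULL` (e.g. `"upstream_500"`).
#' @return data frame of region sequences: `gene_id`, `species_id`,
#'   `window_label`, `sequence` (uppercase `{A,C,G,T,N}`), `anchor_offset`.
#' @export
extract_regions <- function(genome, gene_models, window = c(-500L, -1L),
                            anchor = c("start_codon", "stop_codon"),
                            window_label = NULL) {
  anchor <- match.arg(anchor)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  stopifnot(length(window) == 2, window[1] <= window[2])
  from <- as.integer(window[1]); to <- as.integer(window[2])
  if (is.null(window_label)) {
    window_label <- if (anchor == "start_codon" && to == -1L) {
      paste0("upstream_", -from)
    } else if (from >= 1L) {
      paste0("downstream_", if (anchor == "start_codon") "start_" else "stop_", to)
    } else sprintf("%s_%d_%d", anchor, from, to)
  }
  missing_chrom <- setdiff(unique(gene_models$chrom_id), names(genome))
  if (length(missing_chrom)) {
    off <- gene_models$gene_id[gene_models$chrom_id %in% missing_chrom]
    stop("gene(s) absent from genome: ", paste(utils::head(off, 5), collapse = ", "))
  }
  chrom_len <- Biostrings::width(genome)
  names(chrom_len) <- names(genome)

  rows <- lapply(seq_len(nrow(gene_models)), function(i) {
    gm <- gene_models[i, ]
    a <- if (anchor == "start_codon") gm$start_codon_pos else gm$stop_codon_end
    len <- chrom_len[[gm$chrom_id]]
    if (gm$strand == "+") {
      s <- a + from; e <- a + to
      s2 <- max(1L, s); e2 <- min(len, e)
      if (s2 > e2) {
        warning("window entirely off chromosome for ", gm$gene_id, "; skipped")
        return(NULL)
      }
      seq <- as.character(Biostrings::subseq(genome[[gm$chrom_id]], s2, e2))
      offset <- s2 - a
      if (s2 != s || e2 != e) message("window truncated for ", gm$gene_id)
    } else {
      s <- a - to; e <- a - from
      s2 <- max(1L, s); e2 <- min(len, e)
      if (s2 > e2) {
        warning("window entirely off chromosome for ", gm$gene_id, "; skipped")
        return(NULL)
      }
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[gm$chrom_id]], s2, e2)))
      offset <- a - e2
      if (s2 != s || e2 != e) message("window truncated for ", gm$gene_id)
    }
    data.frame(
      gene_id = gm$gene_id, species_id = gm$species_id,
      window_label = window_label, sequence = .clean_seq(seq),
      anchor_offset = as.integer(offset), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read extracted regions as FASTA
#'
#' Headers encode `gene_id|species_id|window_label|anchor_offset` so that a
#' write/read round trip reproduces the region table exactly.
#'
#' @param regions region data frame from [extract_regions()].
#' @param path FASTA file path.
#' @return `regions_to_fasta`: the path, invisibly. `read_regions_fasta`:
#'   a region data frame.
#' @export
regions_to_fasta <- function(regions, path) {
  headers <- sprintf(">%s|%s|%s|%d", regions$gene_id, regions$species_id,
                     regions$window_label, regions$anchor_offset)
  writeLines(as.vector(rbind(headers, regions$sequence)), path)
  invisible(path)
}

#' @rdname regions_to_fasta
#' @export
read_regions_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad)) stop("malformed region FASTA header at record ", bad[1])
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    species_id = vapply(parts, `[`, "", 2),
    window_label = vapply(parts, `[`, "", 3),
    sequence = unname(as.character(seqs)),
    anchor_offset = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read an ortholog pair table into an ortholog catalog
#'
#' Consumes SynOrths-style output: a TSV of
#' `(anchor_gene_id, species_id, ortholog_gene_id)` pairs. Pairs are
#' deduplicated and aggregated into ortholog sets keyed by the anchor gene;
#' polyploid species may contribute several genes to one set (multiplicity is
#' preserved). When `anchor_species` is given, the anchor gene itself is added
#' as a member of its own set.
#'
#' @param path pair-table TSV with a header row.
#' @param species optional declared species list; rows naming an unknown
#'   species are an error.
#' @param anchor_species optional species id of the anchor genome.
#' @return catalog data frame: `anchor_gene_id`, `species_id`, `gene_id`.
#' @export
read_orthologs <- function(path, species = NULL, anchor_species = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("anchor_gene_id", "species_id", "ortholog_gene_id")
  if (!all(need %in% names(tab)))
    stop("ortholog table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(species)) {
    bad <- setdiff(unique(tab$species_id), species)
    if (length(bad)) stop("unknown species id(s) in ortholog table: ",
                          paste(bad, collapse = ", "))
  }
  tab <- unique(tab[, need])
  out <- data.frame(anchor_gene_id = tab$anchor_gene_id,
                    species_id = tab$species_id,
                    gene_id = tab$ortholog_gene_id, stringsAsFactors = FALSE)
  if (!is.null(anchor_species)) {
    anchors <- unique(out$anchor_gene_id)
    out <- rbind(data.frame(anchor_gene_id = anchors, species_id = anchor_species,
                            gene_id = anchors, stringsAsFactors = FALSE), out)
    out <- unique(out)
  }
  rownames(out) <- NULL
  out
}

#' Read an expression matrix with a replicate-group header row
#'
#' Expected format: line 1 `gene_id<TAB>sample labels...`; line 2
#' `replicate_group<TAB>group labels...`; then one row per gene of
#' non-negative expression values (TPM).
#'
#' @param path TSV file.
#' @return list with `values` (numeric matrix, genes x samples) and
#'   `replicate_groups` (character vector, one group label per column).
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 2L)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  grp <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (grp[1] != "replicate_group")
    stop("second line must be the replicate-group header row")
  if (length(grp) != length(hdr))
    stop("replicate-group row length does not match the sample header")
  tab <- utils::read.delim(path, skip = 2L, header = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- tab[[1]]
  colnames(values) <- hdr[-1]
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  list(values = values, replicate_groups = stats::setNames(grp[-1], hdr[-1]))
}

#' Read a binding-affinity table
#'
#' TSV with columns `fragment_id, fragment_seq, site_start, site_strand,
#' kd_nM, non_binding`; `kd_nM` is a positive dissociation constant in nM or
#' empty/NA for fragments flagged `non_binding`. Rows with non-positive kD are
#' rejected with a message. The site sequence (`site_len` bases from
#' `site_start` on `site_strand`) is extracted from the fragment.
#'
#' @param path TSV file.
#' @param site_len site length within the fragment (default 18).
#' @return data frame with the input columns plus `site_seq`.
#' @export
read_binding_table <- function(path, site_len = 18L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("fragment_id", "fragment_seq", "site_start", "site_strand",
            "kd_nM", "non_binding")
  if (!all(need %in% names(tab)))
    stop("binding table must have columns: ", paste(need, collapse = ", "))
  tab$kd_nM <- suppressWarnings(as.numeric(tab$kd_nM))
  tab$non_binding <- as.logical(tab$non_binding)
  bad <- which(!is.na(tab$kd_nM) & tab$kd_nM <= 0)
  if (length(bad)) {
    message("rejecting ", length(bad), " row(s) with non-positive kD: ",
            paste(tab$fragment_id[utils::head(bad, 5)], collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
  }
  if (any(tab$non_binding & !is.na(tab$kd_nM)))
    stop("rows flagged non_binding must not carry a kD value")
  site <- substr(tab$fragment_seq, tab$site_start, tab$site_start + site_len - 1L)
  flip <- tab$site_strand == "-"
  site[flip] <- revcomp(site[flip])
  tab$site_seq <- toupper(site)
  rownames(tab) <- NULL
  tab
}
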
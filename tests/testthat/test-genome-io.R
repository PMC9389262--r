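test_that("gene models take start codons strand-aware and rank TSS evidence", {
  toy <- write_toy_genome()
  models <- read_genome_annotation(toy$fasta, toy$gff, toy$tss,
                                   species_id = "toy")
  g1 <- models[models$gene_id == "gene1", ]
  expect_equal(g1$start_codon_pos, 1001L)
  expect_equal(g1$strand, "+")
  # summit 950 (score 12) beats summit 930 and the mRNA start 940
  expect_equal(g1$tss_pos, 950L)
  expect_equal(g1$tss_source, "tss_peak")
  expect_equal(g1$tss_offset_atg, -51L)

  g2 <- models[models$gene_id == "gene2", ]
  expect_equal(g2$strand, "-")
  expect_equal(g2$start_codon_pos, 2000L)  # first base of ATG, transcription sense
  expect_equal(g2$stop_codon_end, 1400L)
  expect_equal(g2$tss_source, "mrna_start")
  expect_equal(g2$tss_pos, 2050L)
  expect_equal(g2$tss_offset_atg, -50L)

  # without the TSS table gene1 falls back to its mRNA start
  m2 <- read_genome_annotation(toy$fasta, toy$gff, species_id = "toy")
  expect_equal(m2$tss_source[m2$gene_id == "gene1"], "mrna_start")
  expect_equal(m2$tss_pos[m2$gene_id == "gene1"], 940L)
})

test_that("malformed GFF lines are rejected with their line number", {
  toy <- write_toy_genome()
  bad <- file.path(toy$dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t100\t200\t.\t+\t.\tID=g",
               "chr1\ttoy\tgene\t100"), bad)
  expect_error(read_genome_annotation(toy$fasta, bad), "line 3")
})

test_that("genes on unknown chromosomes are skipped with a warning", {
  toy <- write_toy_genome()
  gff2 <- file.path(toy$dir, "extra.gff3")
  writeLines(c(readLines(toy$gff),
               "chrX\ttoy\tgene\t10\t90\t.\t+\t.\tID=gene3",
               "chrX\ttoy\tmRNA\t10\t90\t.\t+\t.\tID=mRNA3;Parent=gene3",
               "chrX\ttoy\tCDS\t10\t90\t.\t+\t0\tID=cds3;Parent=mRNA3"), gff2)
  expect_warning(models <- read_genome_annotation(toy$fasta, gff2),
                 "unknown chromosome")
  expect_setequal(models$gene_id, c("gene1", "gene2"))
})

test_that("upstream windows come back 5'->3' in gene orientation", {
  toy <- write_toy_genome()
  models <- read_genome_annotation(toy$fasta, toy$gff, species_id = "toy")
  regions <- extract_regions(toy$fasta, models, window = c(-500L, -1L))
  r1 <- regions[regions$gene_id == "gene1", ]
  expect_equal(r1$sequence, substr(toy$chr1, 501, 1000))
  expect_equal(r1$anchor_offset, -500L)
  expect_equal(r1$window_label, "upstream_500")
  r2 <- regions[regions$gene_id == "gene2", ]
  expect_equal(r2$sequence, oracle_revcomp(substr(toy$chr1, 2001, 2500)))
  expect_equal(nchar(r2$sequence), 500L)
})

test_that("windows truncate at chromosome edges with honest anchor offsets", {
  toy <- write_toy_genome()
  models <- data.frame(gene_id = "edge", species_id = "toy", chrom_id = "chr1",
                       strand = "+", start_codon_pos = 101L,
                       stop_codon_end = 400L, tss_pos = NA_integer_,
                       tss_source = "none", tss_offset_atg = NA_integer_,
                       stringsAsFactors = FALSE)
  expect_message(r <- extract_regions(toy$fasta, models), "truncated")
  expect_equal(nchar(r$sequence), 100L)
  expect_equal(r$anchor_offset, -100L)
  expect_equal(r$sequence, substr(toy$chr1, 1, 100))
  # unknown chromosome errors with the gene id
  models$chrom_id <- "chrZ"
  expect_error(extract_regions(toy$fasta, models), "edge")
})

test_that("downstream-of-stop windows anchor on the stop codon", {
  toy <- write_toy_genome()
  models <- read_genome_annotation(toy$fasta, toy$gff, species_id = "toy")
  regions <- extract_regions(toy$fasta, models, window = c(1L, 500L),
                             anchor = "stop_codon")
  r1 <- regions[regions$gene_id == "gene1", ]
  expect_equal(r1$sequence, substr(toy$chr1, 1601, 2100))
  expect_equal(r1$anchor_offset, 1L)
  r2 <- regions[regions$gene_id == "gene2", ]
  expect_equal(r2$sequence, oracle_revcomp(substr(toy$chr1, 900, 1399)))
})

test_that("region FASTA round-trips sequences and labels exactly", {
  toy <- write_toy_genome()
  models <- read_genome_annotation(toy$fasta, toy$gff, species_id = "toy")
  regions <- extract_regions(toy$fasta, models)
  path <- withr::local_tempfile(fileext = ".fa")
  regions_to_fasta(regions, path)
  back <- read_regions_fasta(path)
  expect_identical(back, regions)
})

test_that("strand extraction is consistent with mirroring the chromosome", {
  toy <- write_toy_genome()
  chr_rc <- oracle_revcomp(toy$chr1)
  len <- nchar(toy$chr1)
  dir <- withr::local_tempdir()
  fa2 <- file.path(dir, "mirror.fa")
  writeLines(c(">chr1", chr_rc), fa2)
  fwd <- data.frame(gene_id = "g", species_id = "toy", chrom_id = "chr1",
                    strand = "+", start_codon_pos = 1001L, stop_codon_end = 1600L,
                    tss_pos = NA_integer_, tss_source = "none",
                    tss_offset_atg = NA_integer_, stringsAsFactors = FALSE)
  mir <- fwd
  mir$strand <- "-"
  mir$start_codon_pos <- len - 1001L + 1L
  mir$stop_codon_end <- len - 1600L + 1L
  r_fwd <- extract_regions(toy$fasta, fwd)
  r_mir <- extract_regions(fa2, mir)
  expect_equal(r_fwd$sequence, r_mir$sequence)
  expect_equal(r_fwd$anchor_offset, r_mir$anchor_offset)
})

test_that("ortholog pair tables deduplicate and validate species", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "orth.tsv")
  writeLines(c("anchor_gene_id\tspecies_id\tortholog_gene_id",
               "g1\tspB\tb1", "g1\tspC\tc1", "g1\tspC\tc1",
               "g1\tspC\tc2", "g1\tspC\tc3"), path)
  cat1 <- read_orthologs(path)
  expect_equal(nrow(cat1), 4L)  # duplicate row collapsed
  expect_equal(sum(cat1$species_id == "spC"), 3L)  # polyploid multiplicity kept
  expect_equal(length(unique(cat1$species_id)), 2L)
  cat2 <- read_orthologs(path, anchor_species = "spA")
  expect_true(any(cat2$gene_id == "g1" & cat2$species_id == "spA"))
  expect_error(read_orthologs(path, species = c("spA", "spB")), "spC")
})

test_that("expression and binding tables parse with their validation rules", {
  dir <- withr::local_tempdir()
  expr_path <- file.path(dir, "expr.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "replicate_group\tT1\tT1\tT2\tT2",
               "gA\t1\t3\t0\t2",
               "gB\t0\t0\t5\t5"), expr_path)
  ex <- read_expression(expr_path)
  expect_equal(dim(ex$values), c(2L, 4L))
  expect_equal(unname(ex$replicate_groups), c("T1", "T1", "T2", "T2"))
  expect_equal(ex$values["gA", "s2"], 3)

  bind_path <- file.path(dir, "kd.tsv")
  frag <- paste0("GATTACA", "AACCTTGAAAAAAACGAA", "TTGGCCA")
  writeLines(c("fragment_id\tfragment_seq\tsite_start\tsite_strand\tkd_nM\tnon_binding",
               paste("f1", frag, 8, "+", 12.5, "FALSE", sep = "\t"),
               paste("f2", frag, 8, "-", "", "TRUE", sep = "\t"),
               paste("f3", frag, 8, "+", -1, "FALSE", sep = "\t")), bind_path)
  expect_message(bt <- read_binding_table(bind_path), "non-positive kD")
  expect_equal(nrow(bt), 2L)
  expect_equal(bt$site_seq[1], "AACCTTGAAAAAAACGAA")
  expect_equal(bt$site_seq[2], oracle_revcomp("AACCTTGAAAAAAACGAA"))
  expect_true(is.na(bt$kd_nM[2]) && bt$non_binding[2])
})
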
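# In-code fixtures: a tiny two-gene genome written to temp files, and the
# twelve experimentally established fatty-acid-synthesis reference targets
# with all four evidence layers (TSS distance of the best site, best kD,
# conservation ratio, guide correlation). Where a gene has two measured sites
# the closer / stronger one is entered, per the per-gene aggregation rule.

high_confidence_records <- function() {
  data.frame(
    gene_id = c("BADC1", "BADC2", "BADC3", "BC", "BCCP1", "BCCP2",
                "CTalpha", "KASI", "KASIII", "PII", "PKp_beta1", "SUS2"),
    tss_distance = c(-53, 26, 73, 62, 43, 19, 9, 44, 55, -42, 2, 144),
    kd_nM = c(0.6, 5.7, 9.5, 0.2, 62.2, 0.7, 70.2, 1.7, 45.3, 9.6, 2.5, 12.6),
    species_ratio = c(0.83, 0.67, 0.58, 0.50, 0.92, 1.00,
                      1.00, 1.00, 0.83, 1.00, 1.00, 0.75),
    R = c(0.92, 0.98, 0.94, 0.98, 0.93, 0.99, 0.94, 0.98, 0.96, 0.98, 0.95, 0.75),
    stringsAsFactors = FALSE
  )
}

write_toy_genome <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  set.seed(101)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE,
                       prob = c(0.334, 0.166, 0.166, 0.334)), collapse = "")
  # gene1: + strand, ATG at 1001; gene2: - strand, ATG (first base) at 2000
  substr(chr1, 1001, 1003) <- "ATG"
  substr(chr1, 1998, 2000) <- "CAT"  # reverse complement of ATG
  fasta <- file.path(dir, "genome.fa")
  writeLines(c(">chr1 toy", chr1), fasta)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1001\t1600\t.\t+\t.\tID=gene1",
    "chr1\ttoy\tmRNA\t940\t1600\t.\t+\t.\tID=mRNA1;Parent=gene1",
    "chr1\ttoy\tCDS\t1001\t1600\t.\t+\t0\tID=cds1;Parent=mRNA1",
    "chr1\ttoy\tgene\t1400\t2000\t.\t-\t.\tID=gene2",
    "chr1\ttoy\tmRNA\t1400\t2050\t.\t-\t.\tID=mRNA2;Parent=gene2",
    "chr1\ttoy\tCDS\t1400\t2000\t.\t-\t0\tID=cds2;Parent=mRNA2"
  ), gff)
  tss <- file.path(dir, "tss.tsv")
  writeLines(c(
    "gene_id\tchrom\tsummit\tscore",
    "gene1\tchr1\t950\t12",
    "gene1\tchr1\t930\t5"
  ), tss)
  list(dir = dir, fasta = fasta, gff = gff, tss = tss, chr1 = chr1)
}
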
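test_that("site identity counts positions, N matches nothing, symmetric", {
  a <- "AACCTTGAAAAAAACGAA"
  expect_equal(site_identity(a, a), 18L)
  b <- a; substr(b, 1, 1) <- "T"
  expect_equal(site_identity(a, b), 17L)
  expect_equal(site_identity("AACATAGAAAAAAACGAA", "TTCATAGAAAAAAACGTT"), 14L)
  withN <- a; substr(withN, 5, 5) <- "N"
  n2 <- withN
  expect_equal(site_identity(withN, n2), 17L)  # N != N
  expect_error(site_identity("ACGT", a), "length")
  # symmetry and the triangle-style bound on random sites
  set.seed(13)
  for (i in 1:25) {
    x <- random_dna(3, 18, 0.33)
    expect_equal(site_identity(x[1], x[2]), site_identity(x[2], x[1]))
    expect_gte(site_identity(x[1], x[3]),
               site_identity(x[1], x[2]) + site_identity(x[2], x[3]) - 18L)
  }
})

make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], species_id = r[[2]], strand = r[[3]],
               offset_atg = as.integer(r[[4]]), core_seq = substr(r[[5]], 3, 16),
               extended_seq = r[[5]], truncated = FALSE, stringsAsFactors = FALSE)))
}

test_that("species conservation ratio counts the anchor once a relation exists", {
  site <- "AACCTTGAAAAAAACGAA"
  near <- site; substr(near, 1, 2) <- "TT"         # 16/18: conserved
  far <- "TTCGTAGCCCTTTTTCGG"                       # low identity
  catalog <- data.frame(
    anchor_gene_id = "gA",
    species_id = c("sp01", sprintf("sp%02d", 2:12)),
    gene_id = c("gA", sprintf("o%02d", 2:12)), stringsAsFactors = FALSE
  )
  # anchor site conserved in 8 non-anchor species -> (8+1)/12 = 0.75
  hits <- do.call(make_hits, c(
    list(list("gA", "sp01", "+", -120, site)),
    lapply(2:9, function(i) list(sprintf("o%02d", i), sprintf("sp%02d", i), "+", -100, near)),
    lapply(10:12, function(i) list(sprintf("o%02d", i), sprintf("sp%02d", i), "+", -100, far))
  ))
  cc <- conservation_call(hits, catalog, anchor_species = "sp01")
  expect_equal(cc$sites$n_conserved, 9L)
  expect_equal(cc$sites$species_ratio, 0.75)
  expect_equal(cc$genes$max_ratio, 0.75)

  # relations reaching all species -> 1.00
  hits_all <- do.call(make_hits, c(
    list(list("gA", "sp01", "+", -120, site)),
    lapply(2:12, function(i) list(sprintf("o%02d", i), sprintf("sp%02d", i), "+", -100, site))
  ))
  expect_equal(conservation_call(hits_all, catalog, "sp01")$genes$max_ratio, 1)

  # no relation anywhere -> ratio 0 (anchor not counted)
  hits_none <- make_hits(list("gA", "sp01", "+", -120, site))
  cc0 <- conservation_call(hits_none, catalog, "sp01")
  expect_equal(cc0$sites$species_ratio, 0)
  expect_equal(cc0$sites$conserved_species, "")
})

test_that("conservation requires matching gene-relative orientation", {
  site <- "AACCTTGAAAAAAACGAA"
  catalog <- data.frame(anchor_gene_id = "gA", species_id = c("sp01", "sp02"),
                        gene_id = c("gA", "oB"), stringsAsFactors = FALSE)
  opp <- make_hits(list("gA", "sp01", "+", -120, site),
                   list("oB", "sp02", "-", -100, site))
  expect_equal(conservation_call(opp, catalog, "sp01")$sites$species_ratio, 0)
})

test_that("polyploid species count once and adding sites never lowers a ratio", {
  site <- "AACCTTGAAAAAAACGAA"
  catalog <- data.frame(anchor_gene_id = "gA",
                        species_id = c("sp01", "sp02", "sp02", "sp02"),
                        gene_id = c("gA", "oB1", "oB2", "oB3"),
                        stringsAsFactors = FALSE)
  h <- make_hits(list("gA", "sp01", "+", -120, site),
                 list("oB1", "sp02", "+", -100, site),
                 list("oB2", "sp02", "+", -90, site))
  cc <- conservation_call(h, catalog, "sp01")
  expect_equal(cc$sites$n_conserved, 2L)  # anchor + sp02, genes collapse to species
  # monotonicity under additional ortholog sites
  h2 <- rbind(h, make_hits(list("oB3", "sp02", "+", -80, site)))
  expect_gte(conservation_call(h2, catalog, "sp01")$genes$max_ratio,
             cc$genes$max_ratio)
})

test_that("truncated extended sites are skipped, never compared", {
  site <- "AACCTTGAAAAAAACGAA"
  catalog <- data.frame(anchor_gene_id = "gA", species_id = c("sp01", "sp02"),
                        gene_id = c("gA", "oB"), stringsAsFactors = FALSE)
  h <- make_hits(list("gA", "sp01", "+", -120, site),
                 list("oB", "sp02", "+", -100, site))
  h$truncated[2] <- TRUE
  h$extended_seq[2] <- NA_character_
  expect_message(cc <- conservation_call(h, catalog, "sp01"), "truncated")
  expect_equal(cc$sites$species_ratio, 0)
})

test_that("random-site null matches the closed-form binomial oracle", {
  oracle <- oracle_pair_null(gc = 0.332)
  nn <- random_pair_null(1e6, gc = 0.332, seed = 17)
  # Monte-Carlo standard errors: sd(identity)/sqrt(n) and binomial tail se
  q <- sum(c(0.334, 0.166, 0.166, 0.334)^2)
  se_mean <- sqrt(13 * q * (1 - q) / 1e6)
  expect_lt(abs(nn$mean_identity - oracle$mean_identity), 3 * se_mean)
  se_tail <- sqrt(oracle$p_conserved * (1 - oracle$p_conserved) / 1e6)
  expect_lt(abs(nn$p_conserved - oracle$p_conserved), 3 * se_tail)
  expect_equal(nn$n_fixed, 5L)
})

test_that("degenerate background collapses the null to certain conservation", {
  nn <- random_pair_null(5e3, base_probs = c(1, 0, 0, 0), seed = 2)
  expect_equal(nn$mean_identity, 18)
  expect_equal(nn$p_conserved, 1)
})

test_that("planted-site recovery degrades monotonically with divergence", {
  cfg0 <- sim_config(n_anchor_genes = 60L, fraction_targets = 0.5)
  ratios <- vapply(c(0.1, 0.3, 0.5, 0.7), function(d) {
    cfg <- sim_config(n_anchor_genes = 60L, fraction_targets = 0.5,
                      divergence = rep(d, 11), site_retention = 0)
    cat_sim <- simulate_catalog(cfg, seed = 5)
    up <- simulate_upstream(cfg, cat_sim, seed = 6)
    hits <- scan_regions(up$regions)
    cc <- conservation_call(hits, cat_sim$catalog, "sp01")
    mean(cc$genes$max_ratio[cc$genes$anchor_gene_id %in% up$truth$targets])
  }, numeric(1))
  expect_true(all(diff(ratios) <= 0))
  expect_gt(ratios[1], ratios[4])
})

test_that("frequency matrices tabulate columns that sum to one", {
  f1 <- site_frequency_matrix("ACGT")
  expect_equal(unname(f1[, 1]), c(1, 0, 0, 0))
  f2 <- site_frequency_matrix(c("AAAA", "AAAT"))
  expect_equal(unname(f2["A", 4]), 0.5)
  expect_equal(unname(f2["T", 4]), 0.5)
  set.seed(19)
  sites <- random_dna(10, 18, 0.33)
  f <- site_frequency_matrix(sites)
  expect_equal(unname(colSums(f)), rep(1, 18))
  chars <- do.call(rbind, strsplit(sites, ""))
  expect_equal(unname(f["G", 7]), mean(chars[, 7] == "G"))
  expect_error(site_frequency_matrix(c("ACGT", "ACG")), "equal lengths")
})

test_that("MEME minimal export round-trips the frequency matrix", {
  f <- site_frequency_matrix(c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAT"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motif(f, path, name = "aw_extended", nsites = 2)
  lines <- readLines(path)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("MOTIF aw_extended", lines)))
  mat_start <- grep("letter-probability matrix", lines) + 1
  vals <- do.call(rbind, lapply(lines[mat_start:(mat_start + 17)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  expect_equal(unname(t(vals)), unname(f), tolerance = 1e-5)
})
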
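#' Configuration for the synthetic footprinting study
#'
#' Defines every parameter of the synthetic inputs: a 12-species ortholog
#' catalog with four polyploid species, 500-bp upstream regions at 33.2% GC
#' with conserved motif sites planted near the TSS, correlated expression
#' time courses (7 time points x 3 replicates), and binding affinities
#' log-linear in the true PWM score. Defaults are the study conditions; see
#' the package vignette for the rationale behind each value.
#'
#' @param n_species total species including the anchor (default 12).
#' @param species_ids species labels; the first is the anchor genome.
#' @param ploidy mean genes contributed per ortholog set and species; the
#'   anchor must be 1. Defaults: eight diploids at 1 and four polyploids at
#'   1.77, 2.75, 3.66 and 4.17.
#' @param n_anchor_genes anchor genes / ortholog sets (default 1000).
#' @param fraction_targets fraction of anchor genes that are true targets
#'   (default 0.05).
#' @param gc background GC content (default 0.332).
#' @param divergence per-base substitution probability from the anchor for
#'   each non-anchor species; the default grid spans pairwise upstream
#'   identities of roughly 0.5-0.7.
#' @param site_retention probability an ortholog retains the planted site
#'   intact (default 0.9); non-retained copies drift with the background.
#' @param window_length upstream window length in bp (default 500).
#' @param tss_range TSS offset range relative to the A of ATG (default
#'   uniform over -250..-1).
#' @param site_jitter planted site start is TSS + U(-jitter, jitter), clamped
#'   inside the window (default 60 bp).
#' @param time_points,n_replicates expression design (default 7 x 3).
#' @param guide_profile guide-gene mean log2 shape over the time points.
#' @param target_R population correlation of targets with the guide
#'   (default 0.9).
#' @param profile_amp log2 amplitude of expression profiles (default 2).
#' @param replicate_sd log2-scale replicate noise (default 0.25).
#' @param base_range,target_base_range log2 baseline expression ranges for
#'   background genes and targets.
#' @param kd_alpha,kd_beta,kd_sigma affinity model
#'   `log kD = alpha - beta * score + N(0, sigma)` with `beta > 0`.
#' @param kd_floor,kd_ceiling kD clipping bounds in nM (assay span,
#'   default 0.03-6250).
#' @param kd_score_floor sites scoring below this are emitted as non-binding.
#' @param motif_favored probability mass of the favored base (A) at
#'   degenerate truth-motif positions (default 0.8).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 12L,
                       species_ids = sprintf("sp%02d", seq_len(n_species)),
                       ploidy = c(rep(1, 8), 1.77, 2.75, 3.66, 4.17),
                       n_anchor_genes = 1000L,
                       fraction_targets = 0.05,
                       gc = 0.332,
                       divergence = seq(0.42, 0.68, length.out = n_species - 1L),
                       site_retention = 0.9,
                       window_length = 500L,
                       tss_range = c(-250L, -1L),
                       site_jitter = 60L,
                       time_points = 7L,
                       n_replicates = 3L,
                       guide_profile = c(3, 5, 7, 8, 7, 5, 3),
                       target_R = 0.9,
                       profile_amp = 2,
                       replicate_sd = 0.25,
                       base_range = c(3, 9),
                       target_base_range = c(5, 9),
                       kd_alpha = 8.5, kd_beta = 0.45, kd_sigma = 1,
                       kd_floor = 0.03, kd_ceiling = 6250,
                       kd_score_floor = -4,
                       motif_favored = 0.8) {
  stopifnot(
    n_species >= 2, length(species_ids) == n_species,
    length(ploidy) == n_species, ploidy[1] == 1, all(ploidy >= 1),
    fraction_targets >= 0, fraction_targets <= 1,
    gc > 0, gc < 1,
    length(divergence) == n_species - 1L,
    all(divergence >= 0), all(divergence <= 1),
    site_retention >= 0, site_retention <= 1,
    target_R >= 0, target_R <= 1,
    kd_beta > 0, kd_floor > 0, kd_ceiling > kd_floor,
    length(guide_profile) == time_points,
    motif_favored > 0.25, motif_favored < 1
  )
  structure(as.list(environment()), class = "sim_config")
}

# Truth motif: extended AW-box consensus with deterministic fixed positions
# and the degenerate positions favoring A at `favored`.
.truth_freq <- function(pattern = motif_pattern("NNCNTNGNNNNNNNCGNN"),
                        favored = 0.8) {
  L <- pattern$length
  freq <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) {
    allowed <- pattern$allowed[[j]]
    if (length(allowed) == 1) {
      freq[allowed, j] <- 1
    } else {
      rest <- (1 - favored) / 3
      freq[, j] <- rest
      freq["A", j] <- favored
    }
  }
  freq
}

#' Simulate an ortholog catalog with polyploidy
#'
#' Each anchor gene heads one ortholog set. The anchor species contributes the
#' anchor gene itself; species `s` contributes `1 + Poisson(ploidy_s - 1)`
#' genes, so the mean contribution equals the configured ploidy and every
#' species is represented at least once. Every gene receives a TSS offset
#' drawn uniformly from `tss_range`.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list: `catalog` (`anchor_gene_id`, `species_id`, `gene_id`,
#'   anchor genes included as members) and `models` (`gene_id`, `species_id`,
#'   `anchor_gene_id`, `tss_offset_atg`).
#' @export
simulate_catalog <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    anchors <- sprintf("g%04d", seq_len(config$n_anchor_genes))
    rows <- vector("list", config$n_species)
    rows[[1]] <- data.frame(anchor_gene_id = anchors,
                            species_id = config$species_ids[1],
                            gene_id = anchors, stringsAsFactors = FALSE)
    for (s in 2:config$n_species) {
      counts <- 1L + stats::rpois(length(anchors), config$ploidy[s] - 1)
      anchor_rep <- rep(anchors, counts)
      copy_idx <- sequence(counts)
      rows[[s]] <- data.frame(
        anchor_gene_id = anchor_rep,
        species_id = config$species_ids[s],
        gene_id = paste0(anchor_rep, "_", config$species_ids[s], "_", copy_idx),
        stringsAsFactors = FALSE
      )
    }
    catalog <- do.call(rbind, rows)
    rownames(catalog) <- NULL
    models <- data.frame(
      gene_id = catalog$gene_id, species_id = catalog$species_id,
      anchor_gene_id = catalog$anchor_gene_id,
      tss_offset_atg = sample(config$tss_range[1]:config$tss_range[2],
                              nrow(catalog), replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(catalog = catalog, models = models)
  })
}

#' Simulate upstream regions with planted conserved motif sites
#'
#' Per anchor gene an i.i.d. background window at the configured GC content;
#' each ortholog is derived from it by per-base substitution at the species'
#' divergence rate (replacement bases drawn from the stationary background,
#' so a substitution event may silently restore the same base). For target
#' genes an 18-nt site is sampled from the truth motif and planted near the
#' gene's TSS in a fixed gene-relative orientation shared across species;
#' each ortholog retains the intact site with probability `site_retention`
#' (otherwise its copy simply drifts with the rest of the window).
#'
#' @param config a [sim_config()].
#' @param sim_catalog output of [simulate_catalog()].
#' @param seed optional integer seed.
#' @return list: `regions` (region data frame consumable by
#'   [scan_regions()]) and `truth` (list with `targets`, `sites` per-anchor
#'   planted-site table, `retention` per-gene retention flags, `truth_freq`,
#'   `truth_pwm`).
#' @export
simulate_upstream <- function(config = sim_config(), sim_catalog, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    probs <- .base_probs(config$gc)
    base_int <- c(65L, 67L, 71L, 84L)
    W <- config$window_length
    anchors <- unique(sim_catalog$catalog$anchor_gene_id)
    n_targets <- round(config$fraction_targets * length(anchors))
    targets <- sort(sample(anchors, n_targets))
    is_target <- anchors %in% targets

    tfreq <- .truth_freq(favored = config$motif_favored)
    truth_pwm <- build_pwm_from_freq(tfreq)
    d_of <- c(0, config$divergence)
    names(d_of) <- config$species_ids
    tss <- sim_catalog$models$tss_offset_atg
    names(tss) <- sim_catalog$models$gene_id

    sample_site <- function() {
      paste(vapply(seq_len(ncol(tfreq)), function(j)
        c("A", "C", "G", "T")[sample.int(4, 1, prob = tfreq[, j])], character(1)),
        collapse = "")
    }
    mutate <- function(v, d) {
      if (d <= 0) return(v)
      hit <- stats::runif(length(v)) < d
      nh <- sum(hit)
      if (nh) v[hit] <- base_int[sample.int(4L, nh, replace = TRUE, prob = probs)]
      v
    }

    cat_split <- split(sim_catalog$catalog, sim_catalog$catalog$anchor_gene_id)
    site_rows <- vector("list", length(anchors))
    gene_ids_out <- character(0)
    species_out <- character(0)
    seq_out <- character(0)
    retained_ids <- character(0)
    retained_flag <- logical(0)

    res_genes <- vector("list", length(anchors))
    for (k in seq_along(anchors)) {
      a <- anchors[k]
      members <- cat_split[[a]]
      anc <- base_int[sample.int(4L, W, replace = TRUE, prob = probs)]
      site_seq <- NULL
      if (is_target[k]) {
        site_seq <- sample_site()
        strand <- sample(c("+", "-"), 1)
        t0 <- tss[[a]]
        a0 <- t0 + sample.int(2L * config$site_jitter + 1L, 1) - config$site_jitter - 1L
        a0 <- max(-(W - 2L), min(-16L, a0))  # extended site fully inside the window
        idx <- (a0 - 2L + W + 1L):(a0 + 15L + W + 1L)
        ins <- if (strand == "+") site_seq else revcomp(site_seq)
        anc[idx] <- utf8ToInt(ins)
        site_rows[[k]] <- data.frame(
          anchor_gene_id = a, offset_atg = a0, strand = strand,
          site_seq = site_seq, stringsAsFactors = FALSE
        )
      }
      gseqs <- character(nrow(members))
      gret <- rep(NA, nrow(members))
      for (i in seq_len(nrow(members))) {
        sp <- members$species_id[i]
        if (sp == config$species_ids[1]) {
          gseqs[i] <- intToUtf8(anc)
          gret[i] <- if (is_target[k]) TRUE else NA
          next
        }
        v <- mutate(anc, d_of[[sp]])
        if (is_target[k]) {
          keep <- stats::runif(1) < config$site_retention
          if (keep) v[idx] <- anc[idx]
          gret[i] <- keep
        }
        gseqs[i] <- intToUtf8(v)
      }
      res_genes[[k]] <- data.frame(
        gene_id = members$gene_id, species_id = members$species_id,
        window_label = "upstream_500", sequence = gseqs,
        anchor_offset = -W, retained = gret, stringsAsFactors = FALSE
      )
    }
    all_rows <- do.call(rbind, res_genes)
    regions <- all_rows[, c("gene_id", "species_id", "window_label",
                            "sequence", "anchor_offset")]
    rownames(regions) <- NULL
    sites <- do.call(rbind, site_rows)
    if (is.null(sites))
      sites <- data.frame(anchor_gene_id = character(0), offset_atg = integer(0),
                          strand = character(0), site_seq = character(0),
                          stringsAsFactors = FALSE)
    list(
      regions = regions,
      truth = list(
        targets = targets, sites = sites,
        retention = all_rows[, c("gene_id", "retained")],
        truth_freq = tfreq, truth_pwm = truth_pwm
      )
    )
  })
}

#' Build a PWM object directly from a frequency matrix
#'
#' Convenience for truth motifs and imported frequency matrices; same
#' log2-odds and pseudo-count conventions as [build_pwm()].
#'
#' @param freq 4 x L frequency matrix (rows A, C, G, T; columns sum to 1).
#' @inheritParams build_pwm
#' @return a `pwm` object.
#' @export
build_pwm_from_freq <- function(freq,
                                background = c(A = 0.334, C = 0.166, G = 0.166, T = 0.334),
                                pseudocount = 1e-4) {
  stopifnot(is.matrix(freq), nrow(freq) == 4)
  background <- background / sum(background)
  f <- freq
  f[f == 0] <- pseudocount
  structure(
    list(freq = freq, score = log2(f / background), background = background,
         pseudocount = pseudocount, length = ncol(freq)),
    class = "pwm"
  )
}

#' Simulate expression time courses correlated with a guide gene
#'
#' Target genes follow `base + amp * (R * guide + sqrt(1 - R^2) * noise)` on
#' the log2 scale (population correlation `target_R` with the standardized
#' guide shape); non-targets are independent of the guide. Three replicates
#' per time point are emitted on the TPM scale around each gene's time-point
#' mean.
#'
#' @param config a [sim_config()].
#' @param genes character vector of gene ids (the anchor-species genes).
#' @param targets subset of `genes` that are true guide targets.
#' @param guide_id row name for the guide gene (added to the matrix).
#' @param seed optional integer seed.
#' @return list: `values` (TPM matrix, (genes + guide) x (time points x
#'   replicates)), `replicate_groups`, `guide_id`.
#' @export
simulate_expression <- function(config = sim_config(), genes, targets,
                                guide_id = "guideTF", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$target_R == 1 && config$replicate_sd > 0)
    stop("target_R = 1 with nonzero noise is infeasible")
  .with_seed(seed, {
    tp <- config$time_points
    reps <- config$n_replicates
    gs <- as.numeric(scale(config$guide_profile))
    rho <- config$target_R
    profiles <- matrix(0, length(genes) + 1L, tp,
                       dimnames = list(c(genes, guide_id), NULL))
    is_tgt <- genes %in% targets
    for (i in seq_along(genes)) {
      if (is_tgt[i]) {
        base <- stats::runif(1, config$target_base_range[1], config$target_base_range[2])
        z <- stats::rnorm(tp)
        profiles[i, ] <- base + config$profile_amp * (rho * gs + sqrt(1 - rho^2) * z)
      } else {
        base <- stats::runif(1, config$base_range[1], config$base_range[2])
        profiles[i, ] <- base + config$profile_amp * stats::rnorm(tp)
      }
    }
    profiles[length(genes) + 1L, ] <- 8 + config$profile_amp * gs
    values <- matrix(0, nrow(profiles), tp * reps)
    rownames(values) <- rownames(profiles)
    colnames(values) <- paste0("T", rep(seq_len(tp), each = reps),
                               "_r", rep(seq_len(reps), tp))
    for (t in seq_len(tp)) {
      for (r in seq_len(reps)) {
        lg <- profiles[, t] + stats::rnorm(nrow(profiles), sd = config$replicate_sd)
        values[, (t - 1L) * reps + r] <- pmax(0, 2^lg - 1)
      }
    }
    groups <- stats::setNames(paste0("T", rep(seq_len(tp), each = reps)),
                              colnames(values))
    list(values = values, replicate_groups = groups, guide_id = guide_id)
  })
}

#' Simulate binding-affinity measurements from the truth motif
#'
#' Each site is scored against the truth PWM and assigned
#' `kD = exp(alpha - beta * score + eps)`, `eps ~ N(0, sigma)`, clipped to
#' the assay span; sites scoring below `kd_score_floor` are emitted as
#' non-binding. Fragments carry 7-nt random flanks so the table round-trips
#' through [read_binding_table()].
#'
#' @param config a [sim_config()].
#' @param sites character vector of 18-nt site sequences.
#' @param truth_pwm the truth `pwm` (from [simulate_upstream()]`$truth`).
#' @param seed optional integer seed.
#' @return data frame: `fragment_id`, `fragment_seq`, `site_start`,
#'   `site_strand`, `kd_nM`, `non_binding`, `site_seq`, `true_score`.
#' @export
simulate_binding <- function(config = sim_config(), sites, truth_pwm,
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(sites) >= 1)
  .with_seed(seed, {
    score <- pwm_score(truth_pwm, sites)
    eps <- stats::rnorm(length(sites), sd = config$kd_sigma)
    kd <- exp(config$kd_alpha - config$kd_beta * score + eps)
    kd <- pmin(pmax(kd, config$kd_floor), config$kd_ceiling)
    non_binding <- score < config$kd_score_floor
    kd[non_binding] <- NA_real_
    flanks <- generate_background(2L * length(sites), 7L, gc = config$gc)
    data.frame(
      fragment_id = sprintf("frag%05d", seq_along(sites)),
      fragment_seq = paste0(flanks[seq_along(sites)], sites,
                            flanks[length(sites) + seq_along(sites)]),
      site_start = 8L, site_strand = "+",
      kd_nM = kd, non_binding = non_binding,
      site_seq = sites, true_score = score,
      stringsAsFactors = FALSE
    )
  })
}
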
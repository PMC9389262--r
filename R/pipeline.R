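#' Run the full footprinting workflow on synthetic data
#'
#' Generates a complete synthetic study under `config` (ortholog catalog,
#' upstream regions with planted sites, expression time courses, affinity
#' table), then runs every analysis stage — both-strand motif scanning,
#' cross-species conservation calls, guide-gene co-expression, PWM scoring of
#' measured sites with a held-out ROC — and integrates the evidence layers
#' into the multi-criteria target call. Because the generating truth is
#' known, the result reports recovery of the planted targets.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @param thresholds a [criteria_thresholds()].
#' @param pattern core motif pattern scanned (default the AW-box).
#' @param n_train high-affinity sites held out to train the ROC PWM
#'   (default 25 of those with kD < `train_kd_max`).
#' @param train_kd_max affinity bound for PWM training sites (default 5 nM).
#' @return list: `calls` (ranked target table), `sensitivity`, `fdr`
#'   (both against the planted truth), `n_called`, `roc` (held-out
#'   `roc_result`), `conservation`, `coexpression`, `binding`, `truth`,
#'   `config`.
#' @export
run_synthetic_benchmark <- function(config = sim_config(), seed = 1L,
                                    thresholds = criteria_thresholds(),
                                    pattern = motif_pattern(),
                                    n_train = 25L, train_kd_max = 5) {
  seed <- as.integer(seed)
  anchor_sp <- config$species_ids[1]

  cat_sim <- simulate_catalog(config, seed = seed)
  up <- simulate_upstream(config, cat_sim, seed = seed + 1L)
  expr <- simulate_expression(config,
                              genes = unique(cat_sim$catalog$anchor_gene_id),
                              targets = up$truth$targets,
                              seed = seed + 2L)

  hits <- scan_regions(up$regions, pattern)
  cons <- conservation_call(hits, cat_sim$catalog, anchor_species = anchor_sp,
                            n_species_total = config$n_species)

  proc <- preprocess_expression(expr$values, expr$replicate_groups)
  coex <- correlate_with_guide(proc$values, expr$guide_id)

  anchors <- unique(cat_sim$catalog$anchor_gene_id)
  a_hits <- hits[hits$species_id == anchor_sp & !hits$truncated, , drop = FALSE]
  binding <- NULL
  best_kd <- numeric(0)
  roc <- NULL
  if (nrow(a_hits)) {
    binding <- simulate_binding(config, a_hits$extended_seq, up$truth$truth_pwm,
                                seed = seed + 3L)
    binding$gene_id <- a_hits$gene_id
    kd_by_gene <- tapply(binding$kd_nM, binding$gene_id,
                         function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    best_kd <- kd_by_gene

    # held-out ROC: PWM trained on high-affinity sites, scored on the rest
    train_pool <- which(!binding$non_binding & binding$kd_nM < train_kd_max)
    if (length(train_pool) > n_train) {
      train <- .with_seed(seed + 4L, sample(train_pool, n_train))
    } else train <- train_pool
    test <- setdiff(seq_len(nrow(binding)), train)
    if (length(train) >= 2 && length(test) >= 2) {
      fit <- build_pwm(binding$site_seq[train],
                       background = .base_probs(config$gc))
      test_scores <- pwm_score(fit, binding$site_seq[test])
      roc <- roc_classify(test_scores, binding$kd_nM[test],
                          binding$non_binding[test])
    }
  }

  # TSS distance of the closest anchor site per gene
  tss <- cat_sim$models$tss_offset_atg
  names(tss) <- cat_sim$models$gene_id
  a_all <- hits[hits$species_id == anchor_sp, , drop = FALSE]
  dist_by_gene <- numeric(0)
  if (nrow(a_all)) {
    d <- site_position(a_all$offset_atg, tss[a_all$gene_id],
                       motif_length = pattern$length)
    dist_by_gene <- tapply(seq_along(d), a_all$gene_id, function(i) {
      di <- d[i]
      di[which.min(abs(di))]
    })
  }

  candidates <- sort(unique(a_all$gene_id))
  if (!length(candidates)) stop("no anchor-species motif hits; nothing to call")
  ratio <- stats::setNames(cons$genes$max_ratio, cons$genes$anchor_gene_id)
  R <- stats::setNames(coex$R, coex$gene_id)
  records <- data.frame(
    gene_id = candidates,
    tss_distance = as.numeric(dist_by_gene[candidates]),
    kd_nM = as.numeric(best_kd[candidates]),
    species_ratio = as.numeric(ratio[candidates]),
    R = as.numeric(R[candidates]),
    stringsAsFactors = FALSE
  )
  calls <- call_targets(records, thresholds)
  called <- calls$gene_id[calls$called]
  truth_targets <- up$truth$targets
  sensitivity <- if (length(truth_targets))
    length(intersect(called, truth_targets)) / length(truth_targets) else NA_real_
  fdr <- if (length(called))
    length(setdiff(called, truth_targets)) / length(called) else NA_real_

  list(calls = calls, sensitivity = sensitivity, fdr = fdr,
       n_called = length(called), roc = roc,
       conservation = cons, coexpression = coex, binding = binding,
       truth = up$truth, config = config)
}
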
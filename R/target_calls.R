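#' Thresholds for the multi-criteria target call
#'
#' The four evidence criteria and their default cutoffs: motif within 200 bp
#' of the TSS, in vitro dissociation constant below 200 nM, species
#' conservation ratio of at least 0.75, and co-expression with the guide gene
#' above R = 0.681 (the R value matching an empirical p of 0.05 in the
#' reference time course). A gene is called a target when at least `min_pass`
#' criteria hold.
#'
#' @param max_tss_distance maximum absolute TSS distance in bp.
#' @param max_kd maximum dissociation constant in nM.
#' @param min_ratio minimum species conservation ratio.
#' @param min_R minimum guide correlation.
#' @param min_pass criteria required for a call (1-4).
#' @return a `criteria_thresholds` list.
#' @export
criteria_thresholds <- function(max_tss_distance = 200, max_kd = 200,
                                min_ratio = 0.75, min_R = 0.681, min_pass = 3L) {
  stopifnot(max_tss_distance > 0, max_kd > 0, min_ratio > 0, min_pass %in% 1:4)
  structure(list(max_tss_distance = max_tss_distance, max_kd = max_kd,
                 min_ratio = min_ratio, min_R = min_R,
                 min_pass = as.integer(min_pass)),
            class = "criteria_thresholds")
}

#' Call transcription-factor targets from integrated evidence layers
#'
#' Evaluates the four criteria per gene record — `|tss_distance| <
#' max_tss_distance`, `kd_nM < max_kd`, `species_ratio >= min_ratio`,
#' `R > min_R` — with a missing datum counting as a failed (not absent) flag,
#' and calls genes with at least `min_pass` passing flags. Records should
#' already be aggregated per gene (closest site for distance, minimum kD,
#' maximum ratio over sites).
#'
#' @param records data frame with columns `gene_id`, `tss_distance` (signed
#'   bp), `kd_nM`, `species_ratio`, `R` (any may be `NA`).
#' @param thresholds a [criteria_thresholds()] object.
#' @return `records` with added logical flags `pass_tss`, `pass_kd`,
#'   `pass_ratio`, `pass_R`, plus `n_pass` and `called`, sorted by
#'   (`n_pass` desc, `kd_nM` asc, `|tss_distance|` asc).
#' @export
call_targets <- function(records, thresholds = criteria_thresholds()) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) stop("empty record list")
  need <- c("gene_id", "tss_distance", "kd_nM", "species_ratio", "R")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  th <- thresholds
  flag <- function(x) ifelse(is.na(x), FALSE, x)
  records$pass_tss <- flag(abs(records$tss_distance) < th$max_tss_distance)
  records$pass_kd <- flag(records$kd_nM < th$max_kd)
  records$pass_ratio <- flag(records$species_ratio >= th$min_ratio)
  records$pass_R <- flag(records$R > th$min_R)
  records$n_pass <- records$pass_tss + records$pass_kd +
    records$pass_ratio + records$pass_R
  records$called <- records$n_pass >= th$min_pass
  ord <- order(-records$n_pass,
               ifelse(is.na(records$kd_nM), Inf, records$kd_nM),
               ifelse(is.na(records$tss_distance), Inf, abs(records$tss_distance)),
               records$gene_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
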
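#' Build a log2-odds position weight matrix from aligned binding sites
#'
#' Per-position base frequencies over the aligned sites are divided by the
#' background base probabilities and converted to log2. Zero frequencies are
#' *replaced* by the pseudo-count before taking the logarithm, so every score
#' is finite.
#'
#' @param aligned_sites character vector of equal-length sites over
#'   `{A,C,G,T}` (no N).
#' @param background `(A,C,G,T)` background probabilities; the default is the
#'   upstream-region composition `A = T = 0.334`, `C = G = 0.166`.
#' @param pseudocount replacement for zero frequencies (default 1e-4).
#' @return an object of class `pwm`: `freq` (4 x L, columns sum to 1),
#'   `score` (4 x L log2-odds), `background`, `pseudocount`, `length`.
#' @export
build_pwm <- function(aligned_sites,
                      background = c(A = 0.334, C = 0.166, G = 0.166, T = 0.334),
                      pseudocount = 1e-4) {
  stopifnot(length(aligned_sites) >= 1, all(background > 0))
  background <- background / sum(background)
  if (any(grepl("[^ACGT]", aligned_sites)))
    stop("aligned sites must be over {A,C,G,T} with no N")
  freq <- site_frequency_matrix(aligned_sites)
  f <- freq
  f[f == 0] <- pseudocount
  score <- log2(f / background)
  structure(
    list(freq = freq, score = score, background = background,
         pseudocount = pseudocount, length = ncol(freq)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm: length", x$length, "| background A/C/G/T =",
      paste(signif(x$background, 3), collapse = "/"), "\n")
  cat("consensus:", paste(rownames(x$score)[apply(x$score, 2, which.max)],
                          collapse = ""), "\n")
  invisible(x)
}

#' Score sequences against a PWM
#'
#' The score of a sequence is the sum over positions of the log2-odds entry
#' of its base — strictly additive per position.
#'
#' @param pwm a [build_pwm()] object.
#' @param seq character vector of sequences, each of length `pwm$length`,
#'   over `{A,C,G,T}`.
#' @return numeric vector of scores.
#' @export
pwm_score <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"))
  vapply(seq, function(s) {
    if (nchar(s) != pwm$length)
      stop("sequence length ", nchar(s), " does not match PWM length ", pwm$length)
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(idx)) stop("sequence must be over {A,C,G,T}")
    sum(pwm$score[cbind(idx, seq_len(pwm$length))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' ROC classification of binding from PWM scores
#'
#' Sweeps a descending threshold over the distinct scores (tied scores share
#' one threshold point, so a block of ties produces a diagonal step — the
#' Mann-Whitney identity holds), classifying `score >= threshold` as
#' predicted binding. Truth is `kD < kd_binding_threshold` and not flagged
#' non-binding. AUC is the trapezoid area; `chosen_threshold` is the
#' highest-sensitivity threshold whose FPR does not exceed `max_fpr`.
#'
#' @param scores numeric PWM scores, one per measurement.
#' @param kd_nM dissociation constants in nM (`NA` for non-binding rows).
#' @param non_binding logical flag per measurement (default all `FALSE`).
#' @param kd_binding_threshold truth cutoff in nM (default 200).
#' @param max_fpr optional FPR bound for threshold selection.
#' @return an object of class `roc_result`: `thresholds` (descending),
#'   `fpr`, `tpr` (with (0,0) and (1,1) endpoints), `auc`
#'   (`NA` for single-class truth), `chosen_threshold`, `n_pos`, `n_neg`.
#' @export
roc_classify <- function(scores, kd_nM, non_binding = NULL,
                         kd_binding_threshold = 200, max_fpr = NULL) {
  stopifnot(length(scores) == length(kd_nM))
  if (is.null(non_binding)) non_binding <- rep(FALSE, length(scores))
  truth <- !non_binding & !is.na(kd_nM) & kd_nM < kd_binding_threshold
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    return(structure(list(thresholds = numeric(0), fpr = c(0, 1), tpr = c(0, 1),
                          auc = NA_real_, chosen_threshold = NA_real_,
                          n_pos = n_pos, n_neg = n_neg), class = "roc_result"))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truth & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!truth & scores >= t) / n_neg, numeric(1))
  fpr_c <- c(0, fpr, 1)
  tpr_c <- c(0, tpr, 1)
  auc <- sum(diff(fpr_c) * (utils::head(tpr_c, -1) + utils::tail(tpr_c, -1)) / 2)
  chosen <- NA_real_
  if (!is.null(max_fpr)) {
    ok <- which(fpr <= max_fpr)
    if (length(ok)) chosen <- thr[ok[which.max(tpr[ok])]]
  }
  structure(
    list(thresholds = thr, fpr = fpr_c, tpr = tpr_c, auc = auc,
         chosen_threshold = chosen, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d binding vs %d non-binding; AUC = %s\n",
              x$n_pos, x$n_neg,
              if (is.na(x$auc)) "undefined (single-class truth)" else sprintf("%.3f", x$auc)))
  if (!is.na(x$chosen_threshold))
    cat("chosen threshold:", signif(x$chosen_threshold, 4), "\n")
  invisible(x)
}
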
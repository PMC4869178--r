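# True-Target / False-Target label construction from a perturbation
# experiment's differential-expression table, and experiment eligibility.

#' Label-construction configuration
#'
#' Two labeling modes are supported.  In `"fdr"` mode (the training
#' definition) True Targets are predicted targets significantly repressed
#' (log2 fold-change < 0, FDR < `fdr_tt`) and False Targets are predicted
#' targets clearly unchanged (FDR > `fdr_ft`, irrespective of direction);
#' both inequalities are strict.  In `"topk"` mode (used when comparing
#' heterogeneous platforms) True Targets are the `k` most down-regulated
#' measured predictions (smallest t, requiring t < 0) and False Targets
#' the `k` with |t| < `t_null` closest to zero.
#'
#' @param mode `"fdr"` or `"topk"`.
#' @param fdr_tt FDR ceiling for True Targets (default 0.1).
#' @param fdr_ft FDR floor for False Targets (default 0.2); must satisfy
#'   `0 < fdr_tt <= fdr_ft <= 1`.
#' @param k Number of transcripts per class in top-k mode (default 250).
#' @param t_null |t| ceiling defining "non-changing" in top-k mode
#'   (default 1).
#' @return A `te_label_config` list.
#' @export
label_config <- function(mode = c("fdr", "topk"), fdr_tt = 0.1, fdr_ft = 0.2,
                         k = 250L, t_null = 1.0) {
  mode <- match.arg(mode)
  if (!(fdr_tt > 0 && fdr_tt <= fdr_ft && fdr_ft <= 1)) {
    stop("need 0 < fdr_tt <= fdr_ft <= 1")
  }
  if (k < 1L) stop("k must be >= 1")
  structure(list(mode = mode, fdr_tt = fdr_tt, fdr_ft = fdr_ft,
                 k = as.integer(k), t_null = t_null),
            class = "te_label_config")
}

.new_labels <- function(tt, ft, unlabeled) {
  structure(list(tt = sort(tt), ft = sort(ft), unlabeled = sort(unlabeled)),
            class = "te_labels")
}

#' @export
print.te_labels <- function(x, ...) {
  cat("Labels: ", length(x$tt), " TT, ", length(x$ft), " FT, ",
      length(x$unlabeled), " unlabeled\n", sep = "")
  invisible(x)
}

#' Assign TT/FT labels by FDR bands
#'
#' Only predicted targets that were measured in the experiment are
#' considered; predicted-but-unmeasured transcripts are excluded entirely.
#' Within those, `TT = log2fc < 0 & fdr < fdr_tt`,
#' `FT = fdr > fdr_ft` (any direction), and everything in between is
#' unlabeled.  The three sets partition the predicted-and-measured pool.
#'
#' @param diff `data.frame` as returned by [read_diffexpr()].
#' @param predicted Character vector of predicted target transcript ids.
#' @param cfg A [label_config()] with `mode = "fdr"`.
#' @return A `te_labels` object with components `tt`, `ft`, `unlabeled`.
#' @export
assign_labels_fdr <- function(diff, predicted, cfg = label_config("fdr")) {
  stopifnot(inherits(cfg, "te_label_config"))
  if (cfg$mode != "fdr") stop("cfg$mode must be 'fdr'")
  if (length(predicted) == 0L) stop("empty predicted target set")
  pool <- diff[diff$transcript_id %in% predicted, , drop = FALSE]
  is_tt <- pool$log2fc < 0 & pool$fdr < cfg$fdr_tt
  is_ft <- pool$fdr > cfg$fdr_ft
  .new_labels(pool$transcript_id[is_tt],
              pool$transcript_id[is_ft & !is_tt],
              pool$transcript_id[!is_tt & !is_ft])
}

#' Assign TT/FT labels by top-k ranking on the t-statistic
#'
#' TT are the `k` most down-regulated measured predictions (ascending t,
#' requiring t < 0); FT are the `k` measured predictions with
#' `|t| < t_null` closest to t = 0, excluding any transcript already
#' labeled TT so the partition property holds.  Ties at the k-th value are
#' broken lexicographically on transcript id for reproducibility.  If a
#' side has fewer than `k` candidates, all available are used with a
#' warning.
#'
#' @inheritParams assign_labels_fdr
#' @param cfg A [label_config()] with `mode = "topk"`.
#' @return A `te_labels` object.
#' @export
assign_labels_topk <- function(diff, predicted, cfg = label_config("topk")) {
  stopifnot(inherits(cfg, "te_label_config"))
  if (cfg$mode != "topk") stop("cfg$mode must be 'topk'")
  if (length(predicted) == 0L) stop("empty predicted target set")
  pool <- diff[diff$transcript_id %in% predicted, , drop = FALSE]
  down <- pool[pool$t < 0, , drop = FALSE]
  down <- down[order(down$t, down$transcript_id), , drop = FALSE]
  if (nrow(down) < cfg$k) {
    warning("only ", nrow(down), " down-regulated candidates for k = ", cfg$k)
  }
  tt <- utils::head(down$transcript_id, cfg$k)
  null_pool <- pool[abs(pool$t) < cfg$t_null &
                      !(pool$transcript_id %in% tt), , drop = FALSE]
  null_pool <- null_pool[order(abs(null_pool$t), null_pool$transcript_id), ,
                         drop = FALSE]
  if (nrow(null_pool) < cfg$k) {
    warning("only ", nrow(null_pool), " non-changing candidates for k = ", cfg$k)
  }
  ft <- utils::head(null_pool$transcript_id, cfg$k)
  rest <- setdiff(pool$transcript_id, c(tt, ft))
  .new_labels(tt, ft, rest)
}

#' Is a perturbation experiment eligible for training?
#'
#' An experiment contributes an SVM member only if its differential
#' expression shows a genuine seed-enrichment signal (the QC gate) and it
#' yields at least `min_tt` True Targets; the boundary is inclusive.
#'
#' @param labels A `te_labels` object.
#' @param seed_qc_pass Logical: did the seed-enrichment QC gate pass?
#' @param min_tt Minimum True-Target count (default 20).
#' @return Logical scalar.
#' @export
experiment_eligible <- function(labels, seed_qc_pass, min_tt = 20L) {
  stopifnot(inherits(labels, "te_labels"), is.logical(seed_qc_pass))
  isTRUE(seed_qc_pass) && length(labels$tt) >= min_tt
}
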
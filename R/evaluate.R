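# ROC/AUC machinery, baseline predictors, experiment-level leave-one-out
# cross-validation, and paired method comparison.

#' ROC curve and AUC with Mann-Whitney tie handling
#'
#' The AUC is the probability that a randomly chosen positive scores
#' higher than a randomly chosen negative, with tied pairs counted 1/2
#' (the standard Mann-Whitney convention).  Curve points are computed at
#' every distinct threshold, classifying `score >= threshold` as
#' positive.  The operating point minimizes the Euclidean distance to the
#' top-left corner (sensitivity = 1, specificity = 1).  A 95% confidence
#' interval for the AUC is computed by DeLong's method.
#'
#' @param scores Named numeric vector of prediction scores.
#' @param labels Named vector of +1 (positive/TT) and -1 (negative/FT);
#'   names must match `scores`.
#' @param ci If `TRUE` (default) attach the DeLong 95% CI.
#' @return A `te_roc` object: list with `auc`, `points` (`data.frame`
#'   with `threshold`, `sensitivity`, `specificity`), `operating_point`
#'   and `ci95`.
#' @export
roc_auc <- function(scores, labels, ci = TRUE) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  labels <- labels[names(scores)]
  if (any(is.na(labels))) stop("every scored transcript needs a label")
  pos <- labels > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative label")
  }
  # Mann-Whitney via midranks: concordant + half of ties
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(thr))
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; p_sorted <- pos[ord]
  tp_cum <- cumsum(p_sorted); fp_cum <- cumsum(!p_sorted)
  # index of last score >= threshold, per distinct threshold
  for (i in seq_along(thr)) {
    k <- sum(s_sorted >= thr[i])
    tp <- if (k == 0L) 0L else tp_cum[k]
    fp <- if (k == 0L) 0L else fp_cum[k]
    sens[i] <- tp / n_pos
    spec[i] <- 1 - fp / n_neg
  }
  points <- data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec)
  op <- operating_point(points)
  ci95 <- if (ci) .delong_ci(scores[pos], scores[!pos], auc) else NULL
  structure(list(auc = auc, points = points, operating_point = op,
                 ci95 = ci95, n_pos = n_pos, n_neg = n_neg),
            class = "te_roc")
}

#' @export
print.te_roc <- function(x, ...) {
  cat("ROC: AUC = ", format(x$auc, digits = 4), sep = "")
  if (!is.null(x$ci95)) {
    cat(" (95% CI ", format(x$ci95[1], digits = 4), "-",
        format(x$ci95[2], digits = 4), ")", sep = "")
  }
  cat("; operating point sens = ",
      format(x$operating_point[["sensitivity"]], digits = 3), ", spec = ",
      format(x$operating_point[["specificity"]], digits = 3), "\n", sep = "")
  invisible(x)
}

# DeLong variance from placement values; CI clamped to [0, 1]
.delong_ci <- function(x_pos, x_neg, auc, level = 0.95) {
  m <- length(x_pos); n <- length(x_neg)
  if (m < 2L || n < 2L) return(NULL)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(x_pos, function(x) mean(psi(x, x_neg)), numeric(1))
  v01 <- vapply(x_neg, function(y) mean(psi(x_pos, y)), numeric(1))
  v <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
}

#' Operating point closest to perfect classification
#'
#' Among the supplied ROC points, returns the one minimizing
#' `sqrt((1 - sens)^2 + (1 - spec)^2)`; exact distance ties are broken in
#' favour of higher sensitivity.
#'
#' @param points `data.frame` with columns `sensitivity` and
#'   `specificity` (a `threshold` column is carried through if present).
#' @return Named numeric vector with elements `sensitivity`,
#'   `specificity` and, if available, `threshold`.
#' @export
operating_point <- function(points) {
  stopifnot(nrow(points) >= 1L)
  d <- sqrt((1 - points$sensitivity)^2 + (1 - points$specificity)^2)
  cand <- which(d <= min(d) + 1e-12)
  best <- cand[which.max(points$sensitivity[cand])]
  out <- c(sensitivity = points$sensitivity[best],
           specificity = points$specificity[best])
  if ("threshold" %in% names(points)) {
    out <- c(out, threshold = points$threshold[best])
  }
  out
}

#' Expression-intersect baseline
#'
#' The common quick fix for context specificity: keep only predicted
#' targets whose expression exceeds the median of the *whole* profile
#' (strictly greater; an even-length median is the midpoint of the two
#' central order statistics).  Retained targets keep their original
#' score; the rest are removed.
#'
#' @param scores Named numeric vector of target prediction scores.
#' @param expr A `te_profile` covering the profiled universe.
#' @return Named numeric vector restricted to above-median targets.
#' @export
intersect_baseline <- function(scores, expr) {
  stopifnot(inherits(expr, "te_profile"))
  if (length(expr$values) == 0L) stop("empty expression profile")
  med <- stats::median(expr$values)
  e <- expr$values[names(scores)]
  keep <- !is.na(e) & e > med
  if (!any(keep)) warning("no target lies above the profile median")
  scores[keep]
}

#' Summed-score baseline
#'
#' Per-transcript sum of selected rank-scaled score columns (e.g.
#' TargetScan + microT); neutral-imputed zeros contribute nothing.
#'
#' @param matrix A `te_matrix`.
#' @param methods Non-empty subset of [score_columns()].
#' @return Named numeric vector.
#' @export
sum_baseline <- function(matrix, methods) {
  stopifnot(inherits(matrix, "te_matrix"), length(methods) >= 1L)
  bad <- setdiff(methods, score_columns())
  if (length(bad) > 0L) stop("unknown score column(s): ",
                             paste(bad, collapse = ", "))
  stats::setNames(rowSums(matrix$x[, methods, drop = FALSE]), matrix$ids)
}

#' Define a method for cross-validated comparison
#'
#' @param type `"raw"` (sum of rank-scaled score columns),
#'   `"intersect"` (same, but targets at or below the median of the
#'   evaluation profile are demoted below every retained target), or
#'   `"svm"` (ensemble consensus restricted to the given score columns
#'   plus expression).
#' @param scores Subset of [score_columns()] used by the method.
#' @return A `te_method` list.
#' @export
cv_method <- function(type = c("raw", "intersect", "svm"),
                      scores = score_columns()) {
  type <- match.arg(type)
  bad <- setdiff(scores, score_columns())
  if (length(bad) > 0L) stop("unknown score column(s): ",
                             paste(bad, collapse = ", "))
  structure(list(type = type, scores = scores), class = "te_method")
}

#' The nine-method comparison grid
#'
#' For each of TargetScan (`ts`, Total Context+ alone), microT (`mt`) and
#' their sum (`sum`, Context+ plus miTG): the raw rank-scaled score, the
#' expression-intersect variant, and the SVM model restricted to those
#' scores plus expression (suffix `_x`).
#'
#' @return Named list of [cv_method()] specs.
#' @export
default_cv_methods <- function() {
  list(ts            = cv_method("raw",       "context_plus"),
       ts_intersect  = cv_method("intersect", "context_plus"),
       ts_x          = cv_method("svm",       "context_plus"),
       mt            = cv_method("raw",       "mitg"),
       mt_intersect  = cv_method("intersect", "mitg"),
       mt_x          = cv_method("svm",       "mitg"),
       sum           = cv_method("raw",       c("context_plus", "mitg")),
       sum_intersect = cv_method("intersect", c("context_plus", "mitg")),
       sum_x         = cv_method("svm",       c("context_plus", "mitg")))
}

.method_scores <- function(method, matrix, expr, train_matrices, cfg,
                           min_tt) {
  raw <- sum_baseline(matrix, method$scores)
  switch(method$type,
         raw = raw,
         intersect = {
           kept <- intersect_baseline(raw, expr)
           out <- stats::setNames(rep(min(raw) - 1, length(raw)), names(raw))
           out[names(kept)] <- kept
           out
         },
         svm = {
           exps <- lapply(train_matrices, function(m) {
             list(matrix = restrict_features(m, method$scores), qc = TRUE,
                  id = m$experiment)
           })
           ens <- train_ensemble(exps, cfg, min_tt = min_tt)
           predict_consensus(ens, restrict_features(matrix, method$scores))
         })
}

#' Leave-one-experiment-out cross-validation
#'
#' For every eligible experiment: hold it out, train the ensemble on the
#' remaining experiments, and compute the AUC of each requested method on
#' the held-out experiment's labeled transcripts.  Raw and intersect
#' baselines are evaluated on the held-out matrix directly; SVM variants
#' are re-trained per fold, so held-out rows never enter their training
#' matrices.
#'
#' @param experiments List of entries, each a list with `matrix` (labeled
#'   `te_matrix`), `expr` (the evaluation-context `te_profile`), `qc`
#'   (logical) and optionally `id`.
#' @param cfg A [svm_config()].
#' @param methods Named list of [cv_method()] specs (default
#'   [default_cv_methods()]).
#' @param min_tt Eligibility threshold on True-Target count (default 20).
#' @return A `te_cv_report`: `data.frame` with columns `experiment`,
#'   `method`, `auc`.
#' @export
loocv <- function(experiments, cfg = svm_config(),
                  methods = default_cv_methods(), min_tt = 20L) {
  stopifnot(length(methods) >= 1L, !is.null(names(methods)))
  ok <- vapply(experiments, function(ex) {
    isTRUE(ex$qc) && sum(ex$matrix$labels > 0) >= min_tt
  }, logical(1))
  experiments <- experiments[ok]
  if (length(experiments) < 2L) {
    stop("leave-one-out needs at least two eligible experiments")
  }
  rows <- list()
  for (i in seq_along(experiments)) {
    held <- experiments[[i]]
    id <- if (!is.null(held$id)) held$id else held$matrix$experiment
    train_matrices <- lapply(experiments[-i], `[[`, "matrix")
    for (mn in names(methods)) {
      s <- .method_scores(methods[[mn]], held$matrix, held$expr,
                          train_matrices, cfg, min_tt)
      auc <- roc_auc(s, held$matrix$labels, ci = FALSE)$auc
      rows[[length(rows) + 1L]] <- data.frame(experiment = id, method = mn,
                                              auc = auc,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("te_cv_report", class(out))
  out
}

#' Paired one-sided Wilcoxon signed-rank test
#'
#' Tests whether the paired values in `a` tend to exceed those in `b`
#' (alternative: A > B).  Zero differences are discarded; |differences|
#' are ranked with average ties and the exact null distribution of the
#' positive-rank sum is computed by convolution for up to 25 non-zero
#' pairs, so tied ranks are handled exactly.  Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param auc_a,auc_b Equal-length numeric vectors (>= 3 pairs), paired
#'   by experiment.
#' @return One-sided p-value.
#' @examples
#' paired_wilcoxon(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.8))  # 0.125
#' @export
paired_wilcoxon <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b), length(auc_a) >= 3L)
  d <- auc_a - auc_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; test is degenerate")
    return(1)
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25L) {
    # exact null distribution of the positive-rank sum: each |d| rank is
    # included with probability 1/2; doubled ranks keep sums integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    mass <- c(1, numeric(total))          # mass[s + 1] = P(2W = s)
    for (ri in r2) {
      shifted <- c(numeric(ri), mass[seq_len(total + 1L - ri)])
      mass <- (mass + shifted) / 2
    }
    w2 <- as.integer(round(2 * w))
    sum(mass[(w2 + 1L):(total + 1L)])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
}

#' Paired comparison of two methods in a cross-validation report
#'
#' @param report A `te_cv_report` from [loocv()].
#' @param a,b Method names; the alternative hypothesis is that `a`
#'   achieves higher AUC than `b`.
#' @return One-sided p-value from [paired_wilcoxon()].
#' @export
cv_compare <- function(report, a, b) {
  ra <- report[report$method == a, ]
  rb <- report[report$method == b, ]
  rb <- rb[match(ra$experiment, rb$experiment), ]
  if (nrow(ra) == 0L || any(is.na(rb$auc))) {
    stop("methods not paired across the same experiments")
  }
  paired_wilcoxon(ra$auc, rb$auc)
}
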
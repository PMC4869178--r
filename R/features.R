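# Rank + min-max feature scaling and construction of the 7-feature matrix
# consumed by the SVM members.

#' Rank-then-min-max scale a feature column to \[-1, +1\]
#'
#' Non-missing values are replaced by their average-tie ranks, which are
#' then affinely mapped so the smallest rank becomes -1 and the largest
#' +1.  Missing values map to the min-max centre 0, a neutral value for
#' the SVM; if all non-missing values are equal the column is
#' uninformative and maps entirely to 0.  Because only ranks enter, the
#' output is invariant under any strictly increasing transform of the
#' input — this is what lets expression values from microarray, RNA-Seq
#' or qPCR be used interchangeably.
#'
#' @param values Numeric vector, `NA` = missing; at least one value must
#'   be non-missing.
#' @return Numeric vector of the same length with entries in \[-1, +1\];
#'   missing entries are exactly 0.
#' @examples
#' rank_scale(c(5, 1, 3))        # +1, -1, 0
#' rank_scale(c(4, NA, 2))       # +1, 0, -1
#' @export
rank_scale <- function(values) {
  stopifnot(is.numeric(values))
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing: cannot rank-scale")
  out <- numeric(length(values))
  r <- rank(values[ok], ties.method = "average")
  rmin <- min(r); rmax <- max(r)
  out[ok] <- if (rmax > rmin) 2 * (r - rmin) / (rmax - rmin) - 1 else 0
  out
}

#' Default feature orientation
#'
#' Each feature is oriented so that a larger scaled value means stronger
#' predicted targeting before ranking.  Total Context+ is negated (more
#' negative raw score = stronger predicted repression); all other scores
#' and the expression value are used as-is.  Users who disagree can pass
#' their own named sign vector to [build_matrix()].
#'
#' @return Named numeric vector of +1/-1 over the seven feature names.
#' @export
default_orientation <- function() {
  stats::setNames(c(-1, 1, 1, 1, 1, 1, 1), feature_names())
}

#' Build the 7-feature matrix for one experiment or prediction context
#'
#' Rows are transcripts that carry at least one prediction score *and* an
#' expression value (expression is mandatory: a target that is absent
#' from the profile cannot be placed in the context).  When labels are
#' supplied (training mode) only labeled TT/FT transcripts are kept and a
#' +1/-1 label vector is attached.  Each of the seven columns is
#' rank-scaled independently within this matrix, after applying the
#' orientation signs; missing scores become the neutral centre 0.
#' Scaling is per-matrix by design — no training-time min/max is carried
#' over — so heterogeneous expression platforms remain comparable.
#'
#' @param preds Prediction `data.frame` as from [read_predictions()].
#' @param expr A `te_profile` expression profile.
#' @param labels Optional `te_labels`; if given, only TT/FT rows survive.
#' @param orientation Named sign vector as from [default_orientation()].
#' @param experiment Experiment id stored as provenance.
#' @return A `te_matrix` object: list with `ids`, `x` (n x 7 matrix in
#'   \[-1, +1\]), `imputed` (logical mask), `labels` (named +1/-1 vector or
#'   `NULL`) and `experiment`.
#' @export
build_matrix <- function(preds, expr, labels = NULL,
                         orientation = default_orientation(),
                         experiment = "context") {
  stopifnot(is.data.frame(preds), inherits(expr, "te_profile"))
  if (nrow(preds) == 0L) stop("no prediction rows supplied")
  stopifnot(all(feature_names() %in% names(orientation)))
  raw <- as.matrix(preds[score_columns()])
  rownames(raw) <- preds$transcript_id
  has_score <- rowSums(!is.na(raw)) > 0L
  raw <- raw[has_score, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no transcript has any prediction score")
  has_expr <- rownames(raw) %in% names(expr$values)
  raw <- raw[has_expr, , drop = FALSE]
  if (nrow(raw) == 0L) {
    stop("no predicted transcript has an expression value: ",
         "predictions and profile share no ids")
  }
  lab_vec <- NULL
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "te_labels"))
    keep <- rownames(raw) %in% c(labels$tt, labels$ft)
    raw <- raw[keep, , drop = FALSE]
    if (nrow(raw) == 0L) {
      stop("no predicted transcript carries a TT/FT label")
    }
    lab_vec <- stats::setNames(ifelse(rownames(raw) %in% labels$tt, 1, -1),
                               rownames(raw))
  }
  ids <- rownames(raw)
  full <- cbind(raw, expression = unname(expr$values[ids]))
  imputed <- is.na(full)
  x <- matrix(0, nrow(full), ncol(full), dimnames = dimnames(full))
  for (j in feature_names()) {
    # a method absent from the whole table stays neutral (all zeros)
    if (all(is.na(full[, j]))) next
    x[, j] <- rank_scale(orientation[[j]] * full[, j])
  }
  structure(list(ids = ids, x = x, imputed = imputed, labels = lab_vec,
                 experiment = experiment,
                 orientation = orientation[feature_names()]),
            class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat("Feature matrix '", x$experiment, "': ", length(x$ids),
      " transcripts x ", ncol(x$x), " features", sep = "")
  if (!is.null(x$labels)) {
    cat(" (", sum(x$labels > 0), " TT, ", sum(x$labels < 0), " FT)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Restrict a feature matrix to a subset of prediction methods
#'
#' Columns outside `keep` are set to the neutral value 0 (and flagged
#' imputed) rather than removed, so the matrix shape — and hence the SVM
#' kernel width — is unchanged.  This is how single-method model variants
#' (e.g. a TargetScan-only or microT-only ensemble) are produced.
#' Expression is always kept.
#'
#' @param matrix A `te_matrix`.
#' @param keep Character subset of [feature_names()]; must contain at
#'   least one score column.  `"expression"` is implied.
#' @return A `te_matrix` of identical shape.
#' @export
restrict_features <- function(matrix, keep) {
  stopifnot(inherits(matrix, "te_matrix"))
  keep <- union(keep, "expression")
  bad <- setdiff(keep, feature_names())
  if (length(bad) > 0L) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  if (length(intersect(keep, score_columns())) == 0L) {
    stop("keep must include at least one prediction score column")
  }
  drop <- setdiff(feature_names(), keep)
  matrix$x[, drop] <- 0
  matrix$imputed[, drop] <- TRUE
  matrix
}
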
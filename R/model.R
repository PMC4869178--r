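# The class-weighted radial-kernel SVM ensemble: one member per eligible
# perturbation experiment, summed decision values as the consensus score.

.ENSEMBLE_FORMAT_VERSION <- 1L

#' SVM configuration
#'
#' Defaults mirror the reference setup: radial kernel, `gamma = 1/7`
#' (one over the number of features — kept at 1/7 even for single-method
#' variants, which zero columns out rather than removing them),
#' `cost = 1`, and no internal scaling since the features are already
#' rank/min-max scaled to \[-1, +1\].
#'
#' @param gamma RBF kernel width parameter, > 0.
#' @param cost Soft-margin cost, > 0.  Per-class penalties are
#'   `cost * c1` (TT) and `cost * c2` (FT) with `c1`, `c2` from
#'   [class_weights()].
#' @param aggregate `"decision"` (default) sums signed continuous
#'   decision values across members; `"vote"` sums hard +1/-1 class
#'   votes.
#' @return A `te_svm_config` list.
#' @export
svm_config <- function(gamma = 1 / 7, cost = 1,
                       aggregate = c("decision", "vote")) {
  aggregate <- match.arg(aggregate)
  if (gamma <= 0 || cost <= 0) stop("gamma and cost must be positive")
  structure(list(gamma = gamma, cost = cost, kernel = "radial",
                 scale_inputs = FALSE, aggregate = aggregate),
            class = "te_svm_config")
}

#' Inverse-frequency class weights
#'
#' With `n1` True Targets and `n2` False Targets the per-class penalty
#' shares are `c1 = (1/n1) / (1/n1 + 1/n2)` and
#' `c2 = (1/n2) / (1/n1 + 1/n2)`, so `c1 + c2 = 1` and
#' `c1 * n1 = c2 * n2`: each class contributes equal total penalty mass,
#' which counteracts the strong FT excess typical of perturbation
#' experiments.
#'
#' @param n1 Number of True Targets (>= 1).
#' @param n2 Number of False Targets (>= 1).
#' @return List with components `n1`, `n2`, `c1`, `c2`.
#' @examples
#' class_weights(20, 80)  # c1 = 0.8, c2 = 0.2
#' @export
class_weights <- function(n1, n2) {
  if (n1 < 1 || n2 < 1) stop("class counts must be >= 1")
  s <- 1 / n1 + 1 / n2
  list(n1 = n1, n2 = n2, c1 = (1 / n1) / s, c2 = (1 / n2) / s)
}

#' Train one weighted RBF-SVM member on a labeled feature matrix
#'
#' Fits a C-classification SVM with radial kernel and per-class penalties
#' `cost * c1` / `cost * c2`.  The fitted member exposes a signed
#' continuous decision value with positive = TT side regardless of the
#' internal class ordering of the backend.
#'
#' @param matrix A labeled `te_matrix` with at least one TT and one FT
#'   row.
#' @param cfg A [svm_config()].
#' @param experiment Member id (defaults to the matrix provenance).
#' @return A `te_member` object.
#' @export
train_member <- function(matrix, cfg = svm_config(),
                         experiment = matrix$experiment) {
  stopifnot(inherits(matrix, "te_matrix"), inherits(cfg, "te_svm_config"))
  if (is.null(matrix$labels)) stop("training requires a labeled matrix")
  y <- factor(ifelse(matrix$labels > 0, "TT", "FT"), levels = c("TT", "FT"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training matrix contains a single class")
  }
  w <- class_weights(sum(y == "TT"), sum(y == "FT"))
  fit <- e1071::svm(x = matrix$x, y = y, type = "C-classification",
                    kernel = "radial", gamma = cfg$gamma, cost = cfg$cost,
                    class.weights = c(TT = w$c1, FT = w$c2), scale = FALSE)
  dv <- attr(stats::predict(fit, matrix$x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  # libsvm reports the decision value for "A/B" as positive-favours-A
  flip <- if (startsWith(colnames(dv)[1L], "TT/")) 1 else -1
  structure(list(experiment = experiment, fit = fit, flip = flip,
                 features = colnames(matrix$x), weights = w),
            class = "te_member")
}

#' Signed decision values of one member on a feature matrix
#'
#' @param member A `te_member`.
#' @param matrix A `te_matrix` with matching feature order.
#' @param vote If `TRUE`, return hard +1/-1 votes instead of continuous
#'   decision values.
#' @return Named numeric vector (positive = predicted True Target).
#' @export
member_decision <- function(member, matrix, vote = FALSE) {
  stopifnot(inherits(member, "te_member"), inherits(matrix, "te_matrix"))
  if (!identical(member$features, colnames(matrix$x))) {
    stop("feature-order mismatch between member and matrix")
  }
  dv <- attr(stats::predict(member$fit, matrix$x, decision.values = TRUE),
             "decision.values")
  d <- member$flip * dv[, 1L]
  if (vote) d <- sign(d)
  stats::setNames(unname(d), matrix$ids)
}

#' Train the full ensemble over eligible experiments
#'
#' Eligibility per experiment follows [experiment_eligible()]: a passing
#' seed-enrichment QC gate and at least `min_tt` True-Target rows.
#' Ineligible experiments are skipped with a message; if none survive,
#' the error lists the per-experiment failure reasons.
#'
#' @param experiments List of entries, each a list with elements
#'   `matrix` (labeled `te_matrix`), `qc` (logical QC-gate result) and
#'   optionally `id`.
#' @param cfg A [svm_config()].
#' @param min_tt Minimum True-Target count (default 20).
#' @return A `te_ensemble` object.
#' @export
train_ensemble <- function(experiments, cfg = svm_config(), min_tt = 20L) {
  stopifnot(length(experiments) >= 1L)
  members <- list()
  reasons <- character(0)
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    id <- if (!is.null(ex$id)) ex$id else ex$matrix$experiment
    n_tt <- sum(ex$matrix$labels > 0)
    if (!isTRUE(ex$qc)) {
      reasons <- c(reasons, paste0(id, ": seed-enrichment QC failed"))
      next
    }
    if (n_tt < min_tt) {
      reasons <- c(reasons, paste0(id, ": only ", n_tt, " True Targets (< ",
                                   min_tt, ")"))
      next
    }
    members[[length(members) + 1L]] <- train_member(ex$matrix, cfg,
                                                    experiment = id)
  }
  if (length(reasons) > 0L) {
    message("skipped ", length(reasons), " ineligible experiment(s): ",
            paste(reasons, collapse = "; "))
  }
  if (length(members) == 0L) {
    stop("no eligible experiment to train on: ",
         paste(reasons, collapse = "; "))
  }
  structure(list(members = members, n = length(members), config = cfg,
                 features = members[[1L]]$features,
                 version = .ENSEMBLE_FORMAT_VERSION),
            class = "te_ensemble")
}

#' @export
print.te_ensemble <- function(x, ...) {
  cat("SVM ensemble: ", x$n, " member(s) [",
      paste(vapply(x$members, `[[`, "", "experiment"), collapse = ", "),
      "], gamma = ", format(x$config$gamma), ", cost = ",
      format(x$config$cost), "\n", sep = "")
  invisible(x)
}

#' Consensus score: summed member decisions
#'
#' The final context-specific prediction score of a transcript is the sum
#' of the (signed, continuous) decision values of all ensemble members.
#' Positive consensus = predicted functional target in the supplied
#' expression context.
#'
#' @param ensemble A `te_ensemble`.
#' @param matrix A `te_matrix` with matching feature order.
#' @return Named numeric vector of consensus scores.
#' @export
predict_consensus <- function(ensemble, matrix) {
  stopifnot(inherits(ensemble, "te_ensemble"), inherits(matrix, "te_matrix"))
  if (!identical(ensemble$features, colnames(matrix$x))) {
    stop("feature-order mismatch between ensemble and matrix")
  }
  vote <- identical(ensemble$config$aggregate, "vote")
  per <- vapply(ensemble$members,
                function(m) member_decision(m, matrix, vote = vote),
                numeric(length(matrix$ids)))
  if (length(matrix$ids) == 1L) per <- matrix(per, nrow = 1L)
  stats::setNames(rowSums(per), matrix$ids)
}

#' Persist a fitted ensemble
#'
#' The serialized object stores the fitted members, feature order and a
#' format version; [load_ensemble()] refuses files with a different
#' version or missing metadata.
#'
#' @param ensemble A `te_ensemble`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "te_ensemble"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' Load a persisted ensemble
#'
#' @param path Path written by [save_ensemble()].
#' @return A `te_ensemble`.
#' @export
load_ensemble <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot load ensemble from ", path,
                                           ": ", conditionMessage(e)))
  if (!inherits(obj, "te_ensemble")) stop("not an ensemble file: ", path)
  if (!identical(obj$version, .ENSEMBLE_FORMAT_VERSION)) {
    stop("ensemble format version mismatch in ", path)
  }
  if (is.null(obj$features)) stop("ensemble file lacks feature-order metadata")
  obj
}
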
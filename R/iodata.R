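# Tabular and sequence I/O: prediction score tables, expression profiles,
# differential-expression tables, score output, and RPKM computation.

#' Names of the six sequence-based prediction score columns
#'
#' Column order is fixed throughout the package: TargetScan Total Context+
#' (`context_plus`, more negative = stronger predicted repression),
#' Probability of Conserved Targeting (`pct`, in \[0, 1\]), microT-CDS miTG
#' (`mitg`), and the three MIRZA per-transcript aggregates (`mirza`,
#' `mirza_f`, `mirza_n`).
#'
#' @return Character vector of length 6.
#' @export
score_columns <- function() {
  c("context_plus", "pct", "mitg", "mirza", "mirza_f", "mirza_n")
}

#' Names of the seven SVM features
#'
#' The six prediction scores plus the context expression value, in the
#' order used by every feature matrix and fitted model.
#'
#' @return Character vector of length 7.
#' @export
feature_names <- function() {
  c(score_columns(), "expression")
}

# header aliases accepted when reading prediction tables; names are
# normalized to lower case with non-alphanumerics collapsed to "_"
.column_aliases <- list(
  transcript_id = c("transcript_id", "transcript", "refseq", "refseq_id", "id", "gene_id"),
  mirna_id      = c("mirna_id", "mirna", "mir", "mirna_family"),
  context_plus  = c("context_plus", "total_context_plus", "total_context_score",
                    "context_score", "context"),
  pct           = c("pct", "p_ct", "prob_conserved_targeting"),
  mitg          = c("mitg", "mitg_score", "microt", "microt_cds"),
  mirza         = c("mirza", "mirza_canonical"),
  mirza_f       = c("mirza_f", "mirza_freq", "mirza_target_frequency"),
  mirza_n       = c("mirza_n", "mirza_noncanonical", "mirza_non_canonical")
)

.normalize_header <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

.match_column <- function(header, field) {
  hit <- which(header %in% .column_aliases[[field]])
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = c("", "NA", "na", "Na", "nA"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a prediction score table for one miRNA
#'
#' Reads a tab-separated table with a header naming a transcript column, a
#' miRNA column, and at least one recognized score column (see
#' [score_columns()]).  Missing scores may be encoded as empty cells or the
#' literal `NA` (case-insensitive); internally they stay `NA`, never a
#' sentinel number, because 0 is a legal score value.  Rows whose six
#' scores are all missing carry no prediction and are dropped (the count of
#' dropped rows is reported via a message and the `"dropped"` attribute).
#'
#' @param path Path to a TSV file.
#' @param mirna miRNA identifier to select; only rows for this miRNA are
#'   returned.
#' @return A `data.frame` with columns `transcript_id`, `mirna_id` and the
#'   six score columns (`NA` = missing), one row per transcript.
#' @export
read_predictions <- function(path, mirna) {
  stopifnot(is.character(path), length(path) == 1L,
            is.character(mirna), length(mirna) == 1L)
  tab <- .read_tsv(path)
  header <- .normalize_header(names(tab))
  idx_tx  <- .match_column(header, "transcript_id")
  idx_mir <- .match_column(header, "mirna_id")
  if (is.na(idx_tx) || is.na(idx_mir)) {
    stop("prediction table must name a transcript column and a miRNA column; got: ",
         paste(names(tab), collapse = ", "))
  }
  idx_scores <- vapply(score_columns(), function(f) .match_column(header, f), integer(1))
  if (all(is.na(idx_scores))) {
    stop("no recognized score column in ", path,
         " (expected one of: ", paste(score_columns(), collapse = ", "), ")")
  }
  out <- data.frame(transcript_id = as.character(tab[[idx_tx]]),
                    mirna_id = as.character(tab[[idx_mir]]),
                    stringsAsFactors = FALSE)
  for (f in score_columns()) {
    i <- idx_scores[[f]]
    out[[f]] <- if (is.na(i)) NA_real_ else suppressWarnings(as.numeric(tab[[i]]))
  }
  out <- out[out$mirna_id == mirna, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no prediction rows for miRNA '", mirna, "' in ", path)
  }
  all_missing <- rowSums(!is.na(as.matrix(out[score_columns()]))) == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " row(s) with all six scores missing")
    out <- out[!all_missing, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("all prediction rows for miRNA '", mirna, "' had every score missing")
  }
  key <- paste(out$transcript_id, out$mirna_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out$transcript_id[duplicated(key)][1L]
    stop("duplicated (transcript, miRNA) key in ", path, ": (",
         dup, ", ", mirna, ")")
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- n_dropped
  out
}

#' Read a one-column expression profile
#'
#' Reads a two-column TSV (transcript id, expression value).  Any monotone
#' abundance measure is acceptable (microarray log-intensity, RPKM,
#' count-derived values); downstream rank scaling erases the scale.
#' Duplicate ids (e.g. several probes mapping to one transcript) are
#' resolved by the collapse policy.
#'
#' @param path Path to a TSV file with a header and two columns.
#' @param collapse One of `"max"` (default, the microarray
#'   probe-to-transcript convention), `"mean"`, or `"error"` (refuse
#'   duplicates).
#' @param label Context name attached to the profile (defaults to the file
#'   base name).
#' @return An object of class `te_profile`: a list with `values` (named
#'   numeric vector, one entry per transcript) and `label`.
#' @export
read_expression <- function(path, collapse = c("max", "mean", "error"),
                            label = NULL) {
  collapse <- match.arg(collapse)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression profile must have two columns (id, value)")
  ids <- raw[[1L]]
  vals <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad) > 0L) {
    stop("non-numeric or non-finite expression value at line ",
         bad[1L] + 1L, " of ", path, ": '", raw[[2L]][bad[1L]], "'")
  }
  expression_profile(stats::setNames(vals, ids), collapse = collapse,
                     label = if (is.null(label)) basename(path) else label)
}

#' Construct an expression profile from a named vector
#'
#' @param values Named numeric vector of expression values (names are
#'   transcript ids).
#' @param collapse Duplicate-id policy as in [read_expression()].
#' @param label Context name.
#' @return A `te_profile` object.
#' @export
expression_profile <- function(values, collapse = c("max", "mean", "error"),
                               label = "profile") {
  collapse <- match.arg(collapse)
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (anyDuplicated(names(values))) {
    if (collapse == "error") {
      stop("duplicate transcript id(s) in expression profile: ",
           paste(unique(names(values)[duplicated(names(values))])[1:3],
                 collapse = ", "))
    }
    fun <- if (collapse == "max") max else mean
    agg <- tapply(values, names(values), fun)
    values <- stats::setNames(as.numeric(agg), names(agg))
  }
  structure(list(values = values, label = label), class = "te_profile")
}

#' @export
print.te_profile <- function(x, ...) {
  cat("Expression profile '", x$label, "': ", length(x$values),
      " transcripts, range [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Reads Per Kilobase of gene per Million mapped reads
#'
#' `count / (gene_length_nt/1000 * total_mapped/1e6)`.  Linear in the
#' count, inversely proportional to gene length and library size.
#'
#' @param count Non-negative read count (vectorized).
#' @param gene_length_nt Gene length in nucleotides, > 0.
#' @param total_mapped Total mapped reads in the library, > 0.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, gene_length_nt, total_mapped) {
  if (any(gene_length_nt <= 0)) stop("gene_length_nt must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / ((gene_length_nt / 1000) * (total_mapped / 1e6))
}

#' Read a differential-expression result table
#'
#' Expects a TSV with a header and columns `transcript_id`, `log2fc`, `t`,
#' `fdr` (extra columns are ignored; the four are matched by normalized
#' name, with `logfc`/`log2_fold_change` and `adj_p_val`/`padj` accepted
#' as aliases).  These tables are produced upstream by limma/edgeR-style
#' model fits; this package only consumes them.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `transcript_id`, `log2fc`, `t`, `fdr`.
#' @export
read_diffexpr <- function(path) {
  tab <- .read_tsv(path)
  header <- .normalize_header(names(tab))
  pick <- function(aliases) {
    hit <- which(header %in% aliases)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  i_id <- pick(c("transcript_id", "transcript", "id", "gene_id", "refseq"))
  i_fc <- pick(c("log2fc", "logfc", "log2_fold_change", "log2foldchange"))
  i_t  <- pick(c("t", "t_statistic", "tstat"))
  i_q  <- pick(c("fdr", "adj_p_val", "padj", "qvalue"))
  if (any(is.na(c(i_id, i_fc, i_t, i_q)))) {
    stop("differential-expression table needs transcript_id, log2fc, t and fdr columns")
  }
  out <- data.frame(transcript_id = as.character(tab[[i_id]]),
                    log2fc = as.numeric(tab[[i_fc]]),
                    t = as.numeric(tab[[i_t]]),
                    fdr = as.numeric(tab[[i_q]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    if (any(is.na(out$fdr)) || any(out$fdr < 0 | out$fdr > 1)) {
      stop("fdr values must lie in [0, 1]")
    }
    if (anyDuplicated(out$transcript_id)) {
      stop("duplicate transcript id(s) in differential-expression table")
    }
  }
  out
}

#' Write per-transcript scores to a TSV
#'
#' Values are written with six significant digits; a write/read round trip
#' recovers ids exactly and values to within 1e-6 relative error.
#'
#' @param path Output path.
#' @param scores Named numeric vector (names are transcript ids).
#' @return Invisibly, the path.
#' @export
write_scores <- function(path, scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  df <- data.frame(transcript_id = names(scores),
                   score = sprintf("%.6g", unname(scores)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score TSV written by [write_scores()]
#'
#' @param path Path to a two-column TSV (transcript_id, score).
#' @return Named numeric vector.
#' @export
read_scores <- function(path) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2L) stop("score table must have two columns")
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read 3'UTR sequences from a FASTA file
#'
#' @param path FASTA file of UTR sequences; record names up to the first
#'   whitespace are used as transcript ids.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_utrs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Write named sequences to a FASTA file
#'
#' @param path Output path.
#' @param seqs Named character vector of DNA sequences.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(path, seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
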
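# 3'UTR windowing for MIRZA scoring and log-sum aggregation of per-site
# scores into per-transcript values.  The biophysical model itself is
# external: this module prepares its input windows and digests its output.

#' Split a 3'UTR into overlapping scoring windows
#'
#' Windows of `window` nt are emitted every `step` nt until a window
#' reaches the end of the sequence; consecutive windows therefore overlap
#' by `window - step` nt.  A final truncated window shorter than `step` nt
#' is merged into the preceding window (extending it to the sequence end)
#' rather than emitted as a degenerate fragment; sequences shorter than
#' `window` nt yield a single full-length window.
#'
#' @param utr_sequence Non-empty nucleotide string.
#' @param window Window width in nt (default 50).
#' @param step Shift between window starts in nt (default 25); must
#'   satisfy `window >= step >= 1`.
#' @return `data.frame` with columns `start` (0-based inclusive), `end`
#'   (exclusive) and `sequence`, in coordinate order.
#' @examples
#' split_windows(strrep("A", 100))  # [0,50), [25,75), [50,100)
#' @export
split_windows <- function(utr_sequence, window = 50L, step = 25L) {
  stopifnot(length(utr_sequence) == 1L, is.character(utr_sequence))
  len <- nchar(utr_sequence)
  if (len == 0L) stop("empty UTR sequence")
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("need window >= step >= 1")
  starts <- integer(0); ends <- integer(0)
  s <- 0L
  repeat {
    e <- min(s + window, len)
    starts <- c(starts, s); ends <- c(ends, e)
    if (e >= len) break
    s <- s + step
  }
  n <- length(starts)
  if (n >= 2L && (ends[n] - starts[n]) < step) {
    # trailing fragment too short to score on its own: extend the
    # previous window to the sequence end instead
    ends[n - 1L] <- ends[n]
    starts <- starts[-n]; ends <- ends[-n]
    n <- n - 1L
  }
  data.frame(start = starts, end = ends,
             sequence = substring(utr_sequence, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Window a set of UTRs and write them as FASTA
#'
#' Record names are `<transcript_id>|<start>-<end>` with 0-based
#' half-open coordinates, so per-window scores can be traced back.
#'
#' @param utrs Named character vector of UTR sequences.
#' @param path Output FASTA path.
#' @param window,step As in [split_windows()].
#' @return Invisibly, the number of windows written.
#' @export
write_window_fasta <- function(utrs, path, window = 50L, step = 25L) {
  stopifnot(!is.null(names(utrs)))
  pieces <- lapply(names(utrs), function(id) {
    w <- split_windows(utrs[[id]], window, step)
    stats::setNames(w$sequence, sprintf("%s|%d-%d", id, w$start, w$end))
  })
  all <- unlist(pieces)
  write_fasta(path, all)
  invisible(length(all))
}

#' Aggregate per-site scores into one per-transcript score
#'
#' The per-transcript MIRZA-style value is the sum of the logarithms of
#' the individual site (window) target-quality scores.  An empty score
#' list yields `NA` (the transcript simply gets no score of this type);
#' non-positive scores have no logarithm and are an error.
#'
#' @param site_scores Numeric vector of positive per-site scores.
#' @param base Logarithm base (default natural log).  Only relative
#'   ranking matters downstream — rank scaling erases the base — so this
#'   is a presentation choice.
#' @return Sum of logs, or `NA_real_` for an empty input.
#' @export
aggregate_sites <- function(site_scores, base = exp(1)) {
  if (length(site_scores) == 0L) return(NA_real_)
  if (any(!is.finite(site_scores)) || any(site_scores <= 0)) {
    stop("site scores must be positive and finite")
  }
  sum(log(site_scores, base = base))
}

#' Aggregate a per-window site score table by transcript
#'
#' @param sites `data.frame` with columns `transcript_id` and `score`
#'   (one row per scored site/window).
#' @param base Passed to [aggregate_sites()].
#' @return Named numeric vector of per-transcript log-sum scores.
#' @export
aggregate_site_table <- function(sites, base = exp(1)) {
  stopifnot(is.data.frame(sites),
            all(c("transcript_id", "score") %in% names(sites)))
  agg <- tapply(sites$score, sites$transcript_id,
                function(s) aggregate_sites(s, base = base))
  stats::setNames(as.numeric(agg), names(agg))
}
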
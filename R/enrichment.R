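# Seed-match enrichment QC along a ranked gene list (the gate deciding
# whether a perturbation experiment reflects direct miRNA targeting) and
# rank-based gene-set tests on prediction scores.

#' Canonical seed-match words of a miRNA
#'
#' Returns the DNA words in a 3'UTR that base-pair with the miRNA seed:
#' the 7mer-m8 site (reverse complement of miRNA positions 2-8) and the
#' 7mer-A1 site (reverse complement of positions 2-7 followed by an
#' adenine opposite miRNA position 1).
#'
#' @param mirna_sequence Mature miRNA sequence, 5' to 3', RNA or DNA
#'   alphabet, length >= 8.
#' @return Named character vector with elements `m8` and `a1`.
#' @examples
#' seed_words("UGGAAUGUAAAGAAGUAUGUAU")  # m8 = "ACATTCC", a1 = "CATTCCA"
#' @export
seed_words <- function(mirna_sequence) {
  stopifnot(is.character(mirna_sequence), length(mirna_sequence) == 1L)
  s <- toupper(mirna_sequence)
  if (nchar(s) < 8L) stop("miRNA sequence must be at least 8 nt")
  if (grepl("[^ACGTU]", s)) stop("miRNA sequence contains non-RNA/DNA characters")
  dna <- chartr("U", "T", s)
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  c(m8 = rc(substr(dna, 2L, 8L)),
    a1 = paste0(rc(substr(dna, 2L, 7L)), "A"))
}

#' Seed-word enrichment profile along a ranked gene list
#'
#' At each leading-bin cutoff `c`, tests whether UTRs containing the word
#' are over- or under-represented among the first `c` genes of the
#' ranking, against the exact hypergeometric null (word presence is
#' binary per UTR, so the null is exactly hypergeometric).  The ranking
#' should place the genes expected to respond to the miRNA first (most
#' repressed first, given the treatment = higher-miRNA convention).
#'
#' @param ranked_ids Ordered character vector of gene ids.
#' @param utrs Named character vector of UTR sequences covering every
#'   ranked id.
#' @param word DNA k-mer to count (e.g. a [seed_words()] element).
#' @param cutoffs Leading-bin sizes; default 20 evenly spaced bins across
#'   the ranking (excluding the full list).
#' @return A `te_seed_profile`: list with `word`, `cutoffs`, `p_over`,
#'   `p_under` and `signed_logp` (-log10 p, positive = over-represented
#'   in the leading bin).
#' @export
seed_enrichment <- function(ranked_ids, utrs, word, cutoffs = NULL) {
  missing_utr <- setdiff(ranked_ids, names(utrs))
  if (length(missing_utr) > 0L) {
    stop("no UTR sequence for ", length(missing_utr), " ranked id(s), e.g. ",
         missing_utr[1L])
  }
  n <- length(ranked_ids)
  if (is.null(cutoffs)) {
    cutoffs <- unique(pmax(1L, as.integer(round(seq_len(20L) * n / 21))))
  }
  if (any(cutoffs < 1L | cutoffs > n)) stop("cutoffs must lie in [1, n]")
  contains <- grepl(word, utrs[ranked_ids], fixed = TRUE)
  m <- sum(contains)
  if (m == 0L) {
    warning("word ", word, " absent from every UTR; flat profile")
    return(structure(list(word = word, cutoffs = cutoffs,
                          p_over = rep(1, length(cutoffs)),
                          p_under = rep(1, length(cutoffs)),
                          signed_logp = rep(0, length(cutoffs))),
                     class = "te_seed_profile"))
  }
  lead <- cumsum(contains)
  x <- lead[cutoffs]
  p_over <- stats::phyper(x - 1, m, n - m, cutoffs, lower.tail = FALSE)
  p_under <- stats::phyper(x, m, n - m, cutoffs)
  signed <- ifelse(p_over <= p_under, -log10(p_over), log10(p_under))
  structure(list(word = word, cutoffs = cutoffs, p_over = p_over,
                 p_under = p_under, signed_logp = signed),
            class = "te_seed_profile")
}

#' @export
print.te_seed_profile <- function(x, ...) {
  i <- which.max(abs(x$signed_logp))
  cat("Seed enrichment for ", x$word, ": peak signed -log10 p = ",
      format(x$signed_logp[i], digits = 3), " at leading bin ",
      x$cutoffs[i], "\n", sep = "")
  invisible(x)
}

#' Seed-enrichment QC gate
#'
#' Passes when the seed word is significantly over-represented at the
#' leading edge of the ranking: the smallest over-representation p across
#' cutoffs, Bonferroni-corrected for the number of cutoffs, must fall
#' below `alpha`.
#'
#' @param profile A `te_seed_profile`.
#' @param alpha Gate significance level (default 0.001; the original
#'   inclusion decision was a visual call on enrichment landscapes, so
#'   the explicit level is this package's own gate).  `alpha >= 1`
#'   disables the gate: everything passes.
#' @return Logical scalar.
#' @export
qc_pass <- function(profile, alpha = 0.001) {
  stopifnot(inherits(profile, "te_seed_profile"))
  if (alpha >= 1) return(TRUE)   # a unit-level gate rejects nothing
  p_adj <- min(1, min(profile$p_over) * length(profile$cutoffs))
  p_adj < alpha
}

#' One-sided rank-based gene-set test
#'
#' Wilcoxon rank-sum test that the scores of set members tend to be
#' larger (`alternative = "up"`) or smaller (`"down"`) than those of
#' non-members, computed on ranks within the universe.  The exact null
#' (all member-rank assignments equally likely) is enumerated when the
#' universe is small; otherwise the normal approximation with tie and
#' continuity correction is used — the same statistic limma's wilcoxGST
#' computes.
#'
#' @param scores Named numeric vector covering the universe.
#' @param members Character vector of set member ids.
#' @param universe Character vector defining the tested universe
#'   (typically the union of all predicted targets).
#' @param alternative `"up"` or `"down"`.
#' @param exact_limit Enumerate the exact null when
#'   `choose(N, n_set) <= exact_limit` (default 2e5).
#' @return One-sided p-value.
#' @export
gene_set_test <- function(scores, members, universe,
                          alternative = c("up", "down"),
                          exact_limit = 2e5) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (!all(universe %in% names(scores))) {
    stop("scores must cover the universe")
  }
  members <- intersect(unique(members), universe)
  n_set <- length(members)
  n_all <- length(universe)
  if (n_set == 0L) stop("gene set has no member in the universe")
  if (n_set == n_all) stop("gene set covers the whole universe: test degenerate")
  r <- rank(scores[universe])
  w <- sum(r[match(members, universe)])
  if (choose(n_all, n_set) <= exact_limit) {
    null_w <- colSums(matrix(r[utils::combn(n_all, n_set)], nrow = n_set))
    if (alternative == "up") mean(null_w >= w - 1e-9)
    else mean(null_w <= w + 1e-9)
  } else {
    n_rest <- n_all - n_set
    mu <- n_set * (n_all + 1) / 2
    ties <- table(r)
    sigma2 <- (n_set * n_rest / 12) *
      ((n_all + 1) - sum(ties^3 - ties) / (n_all * (n_all - 1)))
    if (alternative == "up") {
      stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    } else {
      stats::pnorm((w - mu + 0.5) / sqrt(sigma2), lower.tail = TRUE)
    }
  }
}

#' Filter gene sets by effective size
#'
#' Keeps sets whose intersection with the universe has strictly more than
#' `min_size` and strictly fewer than `max_size` members (defaults 5 and
#' 100, the usual window for interpretable Biological Process terms).
#' Members are reduced to the universe intersection.
#'
#' @param terms Named list of character vectors (term id -> member ids),
#'   e.g. from [read_gmt()].
#' @param universe Character vector.
#' @param min_size,max_size Strict size bounds.
#' @return Filtered named list.
#' @export
filter_terms <- function(terms, universe, min_size = 5L, max_size = 100L) {
  trimmed <- lapply(terms, intersect, y = universe)
  sizes <- lengths(trimmed)
  trimmed[sizes > min_size & sizes < max_size]
}

#' Read gene sets in GMT format
#'
#' Each line: term id, description, then member ids, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  stats::setNames(sets, ids)
}
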
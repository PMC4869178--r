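# Independent brute-force oracles used across the suite.  These must stay
# naive: they re-derive expected values by enumeration, never by calling
# the code paths they check.

# AUC as the exhaustive pairwise win probability with ties counted 1/2
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# exact one-sided signed-rank p (A > B) by enumerating all 2^n sign
# assignments of the |difference| ranks
signed_rank_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  w_obs <- sum(r[d > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    if (sum(r[signs]) >= w_obs - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# exact one-sided rank-sum p by enumerating every subset of the universe
# of the member-set size
ranksum_oracle <- function(scores, member_idx, alternative = "up") {
  r <- rank(scores)
  k <- length(member_idx)
  w_obs <- sum(r[member_idx])
  combos <- utils::combn(length(scores), k)
  w_all <- colSums(matrix(r[combos], nrow = k))
  if (alternative == "up") mean(w_all >= w_obs - 1e-9)
  else mean(w_all <= w_obs + 1e-9)
}

# hypergeometric upper/lower tails from first principles
hyper_tail_oracle <- function(x, m, n_total, k, upper = TRUE) {
  support <- max(0, k - (n_total - m)):min(k, m)
  pmf <- choose(m, support) * choose(n_total - m, k - support) /
    choose(n_total, k)
  if (upper) sum(pmf[support >= x]) else sum(pmf[support <= x])
}

# small prediction table with controlled missingness
make_toy_preds <- function(ids = c("A", "B", "C"), mirna = "miR-test") {
  data.frame(transcript_id = ids, mirna_id = mirna,
             context_plus = c(-0.5, -0.1, NA),
             pct = c(0.9, NA, 0.2),
             mitg = c(0.8, 0.3, 0.6),
             mirza = c(2.0, NA, -1.0),
             mirza_f = c(NA, 1.0, 0.5),
             mirza_n = c(0.4, NA, NA),
             stringsAsFactors = FALSE)
}

make_toy_profile <- function(ids = c("A", "B", "C"),
                             values = c(10, 5, 1)) {
  expression_profile(stats::setNames(values, ids), label = "toy")
}

# linearly separable labeled matrix: TT at expression +1, FT at -1,
# score features neutral
make_separable_matrix <- function(n_per_class = 25L) {
  ids <- sprintf("S%03d", seq_len(2L * n_per_class))
  x <- matrix(0, length(ids), 7,
              dimnames = list(ids, feature_names()))
  x[, "expression"] <- rep(c(1, -1), each = n_per_class)
  x[, "context_plus"] <- rep(c(0.4, -0.4), each = n_per_class) +
    seq(-0.05, 0.05, length.out = length(ids))
  labels <- stats::setNames(rep(c(1, -1), each = n_per_class), ids)
  structure(list(ids = ids, x = x, imputed = x == 0, labels = labels,
                 experiment = "separable",
                 orientation = default_orientation()),
            class = "te_matrix")
}

# labeled matrix sampled from two noisy classes; deterministic given seed
make_noisy_matrix <- function(n_tt, n_ft, seed, sep = 1.2,
                              experiment = "noisy") {
  set.seed(seed)
  n <- n_tt + n_ft
  ids <- sprintf("N%04d", seq_len(n))
  shift <- c(rep(sep / 2, n_tt), rep(-sep / 2, n_ft))
  raw <- vapply(seq_len(7), function(j) shift + rnorm(n), numeric(n))
  x <- apply(raw, 2, rank_scale)
  dimnames(x) <- list(ids, feature_names())
  labels <- stats::setNames(c(rep(1, n_tt), rep(-1, n_ft)), ids)
  structure(list(ids = ids, x = x,
                 imputed = matrix(FALSE, n, 7, dimnames = dimnames(x)),
                 labels = labels, experiment = experiment,
                 orientation = default_orientation()),
            class = "te_matrix")
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
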
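# Seeded generator of synthetic miRNA-perturbation experiments with the
# statistical structure the method assumes: a shared latent targeting
# affinity behind the six prediction scores, expression spanning several
# orders of magnitude, and a repression probability that increases with
# both prediction score and expression level.

#' Simulation configuration
#'
#' Defaults describe one realistic perturbation experiment: 2000
#' predicted targets, expression log10-normal around 30 with SD one
#' decade (so the bulk spans roughly four orders of magnitude), about 15%
#' of targets truly repressed, and per-method score missingness matching
#' the partial overlap of real prediction databases.  `effect_score` and
#' `effect_expr` are logit-scale weights of the (standardized) latent
#' affinity and log-expression in the repression probability; with
#' `effect_expr = 0` expression carries no information about repression
#' and the repression magnitude no longer scales with abundance.
#'
#' @param n_transcripts Number of predicted target transcripts.
#' @param n_experiments Number of experiments written by
#'   [simulate_manifest()].
#' @param seed Integer seed; every draw is determined by it.
#' @param score_missingness Named per-method missingness probabilities
#'   over [score_columns()].
#' @param effect_score Logit weight of the latent affinity (>= 0).
#' @param effect_expr Logit weight of log-expression (>= 0); also scales
#'   how strongly repression magnitude grows with abundance.
#' @param noise_sd Per-sample log2 residual SD of the expression assay
#'   (default 0.35, a typical microarray value).
#' @param n_rep Replicates per group in the simulated contrast
#'   (default 6).
#' @param frac_true_sites Baseline fraction of truly repressed targets.
#' @param utr_length_range UTR length range in nt.
#' @param mirna_id,mirna_seq Identity and mature sequence (5'->3') of the
#'   perturbed miRNA; the seed-match word is planted in the UTRs of truly
#'   repressed targets.
#' @return A `te_sim_config` list.
#' @export
sim_config <- function(n_transcripts = 2000L, n_experiments = 5L, seed = 1L,
                       score_missingness = c(context_plus = 0.25, pct = 0.35,
                                             mitg = 0.35, mirza = 0.45,
                                             mirza_f = 0.45, mirza_n = 0.45),
                       effect_score = 1.2, effect_expr = 1.2,
                       noise_sd = 0.35, n_rep = 6L,
                       frac_true_sites = 0.15,
                       utr_length_range = c(300L, 1500L),
                       mirna_id = "sim-miR-1",
                       mirna_seq = "UGGAAUGUAAAGAAGUAUGUAU") {
  stopifnot(all(score_columns() %in% names(score_missingness)),
            all(score_missingness >= 0 & score_missingness <= 1),
            effect_score >= 0, effect_expr >= 0, noise_sd > 0,
            frac_true_sites > 0, frac_true_sites < 1,
            length(utr_length_range) == 2L,
                 utr_length_range[1] <= utr_length_range[2])
  if (frac_true_sites * n_transcripts < 1) {
    stop("infeasible config: frac_true_sites * n_transcripts < 1")
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 n_experiments = as.integer(n_experiments),
                 seed = as.integer(seed),
                 score_missingness = score_missingness[score_columns()],
                 effect_score = effect_score, effect_expr = effect_expr,
                 noise_sd = noise_sd, n_rep = as.integer(n_rep),
                 frac_true_sites = frac_true_sites,
                 utr_length_range = as.integer(utr_length_range),
                 mirna_id = mirna_id, mirna_seq = toupper(mirna_seq)),
            class = "te_sim_config")
}

.random_utr <- function(len, rate_matrix = NULL) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate one miRNA-perturbation experiment
#'
#' Draws, in order: (i) expression from a log10-normal distribution;
#' (ii) a latent per-transcript targeting affinity and six correlated
#' prediction scores (each the affinity plus independent method noise,
#' mapped onto its method's scale — Total Context+ negative-is-strong,
#' PCT and miTG in (0, 1), MIRZA-style log-sums unbounded) with
#' per-method missingness; (iii) a repression indicator with probability
#' `plogis(qlogis(frac_true_sites) + effect_score * z_affinity +
#' effect_expr * z_logexpr)`; (iv) a differential-expression table in
#' which repressed transcripts receive a negative log2 fold-change whose
#' magnitude grows with abundance (when `effect_expr > 0`), t statistics,
#' two-sided p-values and Benjamini-Hochberg FDR; (v) optionally random
#' UTR sequences with the miRNA 7mer-m8 seed match planted in truly
#' repressed targets.  Everything is determined by `seed`.
#'
#' @param cfg A [sim_config()].
#' @param experiment_id Identifier stored with the experiment.
#' @param seed Overrides `cfg$seed` (used for per-experiment sub-seeds).
#' @param utrs If `FALSE`, skip UTR generation (the earlier draws are
#'   unchanged; useful when only the tabular data are needed).
#' @return A `te_sim` object: list with `predictions` (data.frame),
#'   `expression` (`te_profile`), `diffexpr` (data.frame), `utrs` (named
#'   character or `NULL`), `truth` (character vector of truly repressed
#'   ids), plus the miRNA identity and id.
#' @export
simulate_experiment <- function(cfg = sim_config(),
                                experiment_id = "sim_exp1",
                                seed = cfg$seed, utrs = TRUE) {
  stopifnot(inherits(cfg, "te_sim_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_transcripts
  ids <- sprintf("TX%05d", seq_len(n))

  # (i) expression: log10-normal, bulk spanning ~4 orders of magnitude
  log10_expr <- stats::rnorm(n, mean = 1.5, sd = 1)
  expr_vals <- 10^log10_expr

  # (ii) latent affinity and correlated method scores
  affinity <- stats::rnorm(n)
  method_noise <- 0.8
  raw_latent <- vapply(score_columns(), function(m) {
    affinity + stats::rnorm(n, sd = method_noise)
  }, numeric(n))
  preds <- data.frame(transcript_id = ids, mirna_id = cfg$mirna_id,
                      stringsAsFactors = FALSE)
  preds$context_plus <- -0.8 * stats::plogis(raw_latent[, "context_plus"])
  preds$pct          <- stats::plogis(raw_latent[, "pct"])
  preds$mitg         <- stats::plogis(raw_latent[, "mitg"])
  preds$mirza        <- 2 * raw_latent[, "mirza"] + 5
  preds$mirza_f      <- 1.5 * raw_latent[, "mirza_f"] + 3
  preds$mirza_n      <- 2 * raw_latent[, "mirza_n"] + 2
  miss <- vapply(score_columns(), function(m) {
    stats::runif(n) < cfg$score_missingness[[m]]
  }, logical(n))
  all_missing <- rowSums(miss) == length(score_columns())
  miss[all_missing, "mitg"] <- FALSE    # every record keeps >= 1 score
  for (m in score_columns()) preds[[m]][miss[, m]] <- NA_real_

  # (iii) repression indicator
  z_s <- as.numeric(scale(affinity))
  z_e <- as.numeric(scale(log10_expr))
  p_rep <- stats::plogis(stats::qlogis(cfg$frac_true_sites) +
                           cfg$effect_score * z_s + cfg$effect_expr * z_e)
  repressed <- stats::runif(n) < p_rep

  # (iv) differential expression: magnitude grows with abundance when
  # expression is informative
  se <- cfg$noise_sd * sqrt(2 / cfg$n_rep)
  df <- 2L * (cfg$n_rep - 1L)
  w_e <- min(cfg$effect_expr, 1)
  mu <- ifelse(repressed, -(0.8 + 0.6 * w_e * stats::pnorm(z_e)), 0)
  log2fc <- mu + stats::rnorm(n, sd = se)
  t_stat <- log2fc / se
  p_val <- 2 * stats::pt(-abs(t_stat), df = df)
  diffexpr <- data.frame(transcript_id = ids, log2fc = log2fc, t = t_stat,
                         fdr = stats::p.adjust(p_val, method = "BH"),
                         stringsAsFactors = FALSE)

  # (v) UTRs with the seed word planted in truly repressed targets
  utr_seqs <- NULL
  if (isTRUE(utrs)) {
    lens <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]), n,
                   replace = TRUE)
    utr_seqs <- vapply(lens, .random_utr, character(1))
    word <- seed_words(cfg$mirna_seq)[["m8"]]
    k <- nchar(word)
    for (i in which(repressed)) {
      pos <- sample(nchar(utr_seqs[i]) - k + 1L, 1L)
      substr(utr_seqs[i], pos, pos + k - 1L) <- word
    }
    names(utr_seqs) <- ids
  }

  structure(list(predictions = preds,
                 expression = expression_profile(
                   stats::setNames(expr_vals, ids),
                   label = experiment_id),
                 diffexpr = diffexpr, utrs = utr_seqs,
                 truth = ids[repressed],
                 mirna_id = cfg$mirna_id, mirna_seq = cfg$mirna_seq,
                 experiment_id = experiment_id),
            class = "te_sim")
}

#' @export
print.te_sim <- function(x, ...) {
  cat("Simulated experiment '", x$experiment_id, "': ",
      nrow(x$predictions), " predicted targets, ", length(x$truth),
      " truly repressed\n", sep = "")
  invisible(x)
}

.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Package a simulated experiment for training or cross-validation
#'
#' Builds TT/FT labels from the simulated differential-expression table,
#' assembles the labeled feature matrix, and (when UTRs are present)
#' runs the seed-enrichment QC gate on the t-ranked gene list.
#'
#' @param sim A `te_sim`.
#' @param label_cfg A [label_config()].
#' @param qc Override the QC-gate result; by default it is computed from
#'   the simulated UTRs, or assumed passing when UTRs were not generated.
#' @param qc_alpha Gate level passed to [qc_pass()].
#' @return List with `matrix`, `expr`, `qc` and `id`, as consumed by
#'   [train_ensemble()] and [loocv()].
#' @export
sim_to_experiment <- function(sim, label_cfg = label_config("fdr"),
                              qc = NULL, qc_alpha = 0.001) {
  stopifnot(inherits(sim, "te_sim"))
  labels <- assign_labels_fdr(sim$diffexpr, sim$predictions$transcript_id,
                              label_cfg)
  if (is.null(qc)) {
    qc <- if (is.null(sim$utrs)) TRUE else {
      ranked <- sim$diffexpr$transcript_id[order(sim$diffexpr$t)]
      word <- seed_words(sim$mirna_seq)[["m8"]]
      qc_pass(seed_enrichment(ranked, sim$utrs, word), alpha = qc_alpha)
    }
  }
  list(matrix = build_matrix(sim$predictions, sim$expression, labels,
                             experiment = sim$experiment_id),
       expr = sim$expression, qc = qc, id = sim$experiment_id)
}

#' Write a set of simulated experiments to disk
#'
#' Produces, per experiment, the exact file formats the command-line
#' interface consumes (prediction TSV, expression TSV, DE TSV, UTR
#' FASTA) plus a manifest TSV with columns `experiment_id`,
#' `predictions`, `expression`, `diffexpr`, `utrs`, `qc`.  Experiments
#' use distinct sub-seeds derived from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param utrs Generate and write UTR FASTA files (default `TRUE`); when
#'   `FALSE` the QC column is `TRUE` by assumption.
#' @return Invisibly, the manifest path.
#' @export
simulate_manifest <- function(cfg = sim_config(), dir, utrs = TRUE) {
  stopifnot(inherits(cfg, "te_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (e in seq_len(cfg$n_experiments)) {
    id <- sprintf("sim_exp%d", e)
    sim <- simulate_experiment(cfg, experiment_id = id,
                               seed = .sub_seed(cfg$seed, e), utrs = utrs)
    p_pred <- file.path(dir, paste0(id, "_predictions.tsv"))
    p_expr <- file.path(dir, paste0(id, "_expression.tsv"))
    p_de   <- file.path(dir, paste0(id, "_diffexpr.tsv"))
    p_utr  <- if (utrs) file.path(dir, paste0(id, "_utrs.fa")) else NA
    utils::write.table(sim$predictions, p_pred, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(transcript_id = names(sim$expression$values),
                                  expression = sprintf("%.6g", sim$expression$values)),
                       p_expr, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$diffexpr, p_de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    qc <- TRUE
    if (utrs) {
      write_fasta(p_utr, sim$utrs)
      ranked <- sim$diffexpr$transcript_id[order(sim$diffexpr$t)]
      qc <- qc_pass(seed_enrichment(ranked, sim$utrs,
                                    seed_words(sim$mirna_seq)[["m8"]]))
    }
    rows[[e]] <- data.frame(experiment_id = id, predictions = p_pred,
                            expression = p_expr, diffexpr = p_de,
                            utrs = if (utrs) p_utr else "", qc = qc,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
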
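de_fixture <- function() {
  data.frame(transcript_id = c("A", "B", "C", "D", "E"),
             log2fc = c(-1.2, 0.8, -0.5, 0.8, -2.0),
             t = c(-4, 2, -1.5, 3, -6),
             fdr = c(0.05, 0.5, 0.15, 0.01, 0.001),
             stringsAsFactors = FALSE)
}

test_that("FDR-band labels follow the strict inequalities", {
  labels <- assign_labels_fdr(de_fixture(), c("A", "B", "C", "D", "E", "Z"))
  expect_setequal(labels$tt, c("A", "E"))        # repressed & significant
  expect_setequal(labels$ft, "B")                # unchanged, direction-blind
  expect_setequal(labels$unlabeled, c("C", "D")) # between bands / up-regulated
  # Z was predicted but never measured: excluded entirely
  expect_false("Z" %in% unlist(labels[c("tt", "ft", "unlabeled")]))
  expect_error(assign_labels_fdr(de_fixture(), character(0)), "empty")
})

test_that("boundary FDR values stay unlabeled under strict comparison", {
  de <- data.frame(transcript_id = c("X", "Y"), log2fc = c(-1, -1),
                   t = c(-2, -2), fdr = c(0.1, 0.2))
  labels <- assign_labels_fdr(de, c("X", "Y"))
  expect_length(labels$tt, 0)   # fdr == 0.1 is not < 0.1
  expect_length(labels$ft, 0)   # fdr == 0.2 is not > 0.2
  expect_setequal(labels$unlabeled, c("X", "Y"))
})

test_that("labels partition the predicted-and-measured pool", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(20:120, 1)
    de <- data.frame(transcript_id = sprintf("T%03d", seq_len(n)),
                     log2fc = rnorm(n), t = rnorm(n),
                     fdr = runif(n))
    predicted <- sample(de$transcript_id, sample(5:n, 1))
    predicted <- c(predicted, "UNMEASURED1")
    labels <- assign_labels_fdr(de, predicted)
    pool <- intersect(predicted, de$transcript_id)
    parts <- list(labels$tt, labels$ft, labels$unlabeled)
    expect_setequal(unlist(parts), pool)
    expect_equal(sum(lengths(parts)), length(pool))  # disjoint
  }
})

test_that("tightening FDR bands shrinks the corresponding class", {
  set.seed(22)
  n <- 200
  de <- data.frame(transcript_id = sprintf("T%03d", 1:n),
                   log2fc = rnorm(n), t = rnorm(n), fdr = runif(n))
  pred <- de$transcript_id
  loose <- assign_labels_fdr(de, pred, label_config("fdr", 0.1, 0.2))
  tight_tt <- assign_labels_fdr(de, pred, label_config("fdr", 0.05, 0.2))
  high_ft <- assign_labels_fdr(de, pred, label_config("fdr", 0.1, 0.5))
  expect_true(all(tight_tt$tt %in% loose$tt))
  expect_true(all(high_ft$ft %in% loose$ft))
})

test_that("top-k labels take the k most extreme t statistics", {
  set.seed(23)
  n <- 700
  de <- data.frame(transcript_id = sprintf("T%04d", 1:n),
                   log2fc = rnorm(n), t = rnorm(n, sd = 2), fdr = runif(n))
  cfg <- label_config("topk", k = 250)
  labels <- assign_labels_topk(de, de$transcript_id, cfg)
  expect_length(labels$tt, 250)
  down <- de[de$t < 0, ]
  expect_setequal(labels$tt, down$transcript_id[order(down$t)][1:250])
  expect_true(all(abs(de$t[match(labels$ft, de$transcript_id)]) < 1))
  # FT are those closest to zero among eligible non-TT transcripts
  eligible <- de[abs(de$t) < 1 & !(de$transcript_id %in% labels$tt), ]
  kth <- sort(abs(eligible$t))[length(labels$ft)]
  expect_true(max(abs(de$t[match(labels$ft, de$transcript_id)])) <= kth)
})

test_that("top-k exhaustion uses all candidates with a warning", {
  de <- data.frame(transcript_id = sprintf("T%02d", 1:30),
                   log2fc = 0, t = c(rep(-3, 10), rep(5, 20)),
                   fdr = 0.5)
  expect_warning(
    expect_warning(labels <- assign_labels_topk(de, de$transcript_id),
                   "down-regulated"),
    "non-changing")
  expect_length(labels$tt, 10)
  expect_length(labels$ft, 0)
})

test_that("top-k ties break deterministically on transcript id", {
  de <- data.frame(transcript_id = c("B", "A", "C", "D"),
                   log2fc = 0, t = c(-2, -2, -2, -5), fdr = 0.5)
  cfg <- label_config("topk", k = 2)
  labels <- suppressWarnings(assign_labels_topk(de, de$transcript_id, cfg))
  expect_equal(labels$tt, c("A", "D"))  # D most negative, then A before B
})

test_that("experiment eligibility needs QC and 20 True Targets inclusive", {
  mk <- function(n_tt) {
    de <- data.frame(transcript_id = sprintf("T%03d", 1:200),
                     log2fc = c(rep(-1, n_tt), rep(0, 200 - n_tt)),
                     t = 0,
                     fdr = c(rep(0.01, n_tt), rep(0.9, 200 - n_tt)))
    assign_labels_fdr(de, de$transcript_id)
  }
  expect_false(experiment_eligible(mk(19), TRUE))
  expect_true(experiment_eligible(mk(20), TRUE))
  expect_false(experiment_eligible(mk(180), FALSE))  # QC gate overrides size
})
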
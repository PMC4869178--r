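test_that("AUC matches hand-checked configurations", {
  s <- c(a = 0.9, b = 0.8, c = 0.2, d = 0.1)
  l <- c(a = 1, b = 1, c = -1, d = -1)
  expect_equal(roc_auc(s, l)$auc, 1.0)
  l2 <- c(a = 1, b = -1, c = 1, d = -1)  # pos 0.9, 0.2; neg 0.8, 0.1
  expect_equal(roc_auc(s, l2)$auc, 0.75)
  s3 <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(roc_auc(s3, l2)$auc, 0.5)
  expect_error(roc_auc(s, c(a = 1, b = 1, c = 1, d = 1)), "negative")
})

test_that("AUC equals the exhaustive pairwise oracle", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- stats::setNames(sample(-5:5, n, TRUE), sprintf("t%02d", 1:n))
    labels <- stats::setNames(sample(c(-1, 1), n, TRUE), names(scores))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels, ci = FALSE)$auc,
                 auc_pairwise_oracle(scores, labels))
  }
})

test_that("AUC is rank-invariant and anti-symmetric", {
  set.seed(52)
  for (i in 1:20) {
    n <- 30
    scores <- stats::setNames(rnorm(n), sprintf("t%02d", 1:n))
    labels <- stats::setNames(sample(c(-1, 1), n, TRUE), names(scores))
    if (length(unique(labels)) < 2) next
    a <- roc_auc(scores, labels, ci = FALSE)$auc
    expect_equal(roc_auc(exp(scores), labels, ci = FALSE)$auc, a)
    expect_equal(roc_auc(-scores, labels, ci = FALSE)$auc, 1 - a)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (i in 1:10) {
    n <- 200
    scores <- stats::setNames(rnorm(n), sprintf("t%03d", 1:n))
    labels <- stats::setNames(sample(c(-1, 1), n, TRUE), names(scores))
    ours <- roc_auc(scores, labels, ci = FALSE)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE)))
    expect_equal(ours, as.numeric(ref))
  }
})

test_that("the operating point minimizes distance to perfection", {
  pts <- data.frame(sensitivity = c(1, 0.75), specificity = c(0.5, 1))
  op <- operating_point(pts)
  expect_equal(unname(op[c("sensitivity", "specificity")]), c(0.75, 1))
  pts2 <- data.frame(sensitivity = c(1, 0.2), specificity = c(1, 0.9))
  expect_equal(unname(operating_point(pts2)), c(1, 1))
  tie <- data.frame(sensitivity = c(0.8, 0.6), specificity = c(0.6, 0.8))
  expect_equal(unname(operating_point(tie)), c(0.8, 0.6))
  # operating point of a full ROC is one of its points
  set.seed(54)
  s <- stats::setNames(rnorm(40), sprintf("t%02d", 1:40))
  l <- stats::setNames(sample(c(-1, 1), 40, TRUE), names(s))
  roc <- roc_auc(s, l)
  expect_true(any(roc$points$sensitivity == roc$operating_point[["sensitivity"]] &
                    roc$points$specificity == roc$operating_point[["specificity"]]))
})

test_that("the intersect baseline keeps strictly above-median targets", {
  expr <- expression_profile(c(A = 5, B = 1, C = 3, D = 2, E = 4))
  kept <- intersect_baseline(c(A = 0.9, C = 0.8), expr)
  expect_equal(names(kept), "A")   # median 3, strict inequality drops C
  expect_warning(intersect_baseline(c(B = 1, D = 1), expr), "median")
  # even-length profile: median is the midpoint of the central pair
  expr4 <- expression_profile(c(A = 1, B = 2, C = 3, D = 4))
  kept4 <- intersect_baseline(c(B = 0.5, C = 0.5), expr4)
  expect_equal(names(kept4), "C")  # median 2.5
  expect_error(intersect_baseline(c(A = 1),
                                  expression_profile(stats::setNames(numeric(0),
                                                                     character(0)))),
               "empty")
})

test_that("the sum baseline adds selected scaled columns", {
  m <- make_noisy_matrix(10, 10, seed = 55)
  expect_equal(sum_baseline(m, "context_plus"),
               stats::setNames(m$x[, "context_plus"], m$ids))
  expect_equal(sum_baseline(m, c("context_plus", "mitg")),
               sum_baseline(m, c("mitg", "context_plus")))
  m$x[3, "mitg"] <- 0; m$imputed[3, "mitg"] <- TRUE
  expect_equal(unname(sum_baseline(m, c("context_plus", "mitg"))[3]),
               unname(m$x[3, "context_plus"]))
})

test_that("leave-one-out holds each experiment out exactly once", {
  cfg <- sim_config(n_transcripts = 500)
  sims <- lapply(1:3, function(e) {
    simulate_experiment(cfg, sprintf("exp%d", e), seed = 560 + e,
                        utrs = FALSE)
  })
  exps <- lapply(sims, sim_to_experiment)
  methods <- list(ts = cv_method("raw", "context_plus"),
                  ts_x = cv_method("svm", "context_plus"))
  report <- loocv(exps, methods = methods)
  expect_equal(nrow(report), 6L)
  expect_equal(sort(unique(report$experiment)),
               c("exp1", "exp2", "exp3"))
  expect_true(all(table(report$experiment) == 2))
  expect_true(all(report$auc >= 0 & report$auc <= 1))
  expect_error(loocv(exps[1], methods = methods), "at least two")
})

test_that("paired signed-rank p-values match exact enumeration", {
  expect_equal(paired_wilcoxon(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.8)), 0.125)
  expect_warning(p <- paired_wilcoxon(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)),
                 "degenerate")
  expect_equal(p, 1)
  expect_equal(paired_wilcoxon(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7)),
               signed_rank_oracle(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7)))
  set.seed(57)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    a <- round(runif(n), 2)
    b <- round(runif(n), 2)
    if (all(a == b)) next
    expect_equal(paired_wilcoxon(a, b), signed_rank_oracle(a, b))
  }
})

test_that("paired test agrees with wilcox.test when ties are absent", {
  set.seed(58)
  a <- rnorm(12); b <- rnorm(12)
  ours <- paired_wilcoxon(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                            exact = TRUE)$p.value
  expect_equal(ours, ref)
})

test_that("cv_compare pairs method AUCs by experiment", {
  report <- data.frame(experiment = rep(c("e1", "e2", "e3"), each = 2),
                       method = rep(c("m1", "m2"), 3),
                       auc = c(0.9, 0.8, 0.85, 0.7, 0.95, 0.9))
  expect_equal(cv_compare(report, "m1", "m2"), 0.125)
  expect_error(cv_compare(report, "m1", "missing"), "paired")
})
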
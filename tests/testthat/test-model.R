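test_that("class weights follow the inverse-frequency formulas", {
  w <- class_weights(10, 10)
  expect_equal(c(w$c1, w$c2), c(0.5, 0.5))
  w <- class_weights(20, 80)
  expect_equal(c(w$c1, w$c2), c(0.8, 0.2))
  w <- class_weights(1, 99)
  expect_equal(c(w$c1, w$c2), c(0.99, 0.01))
  expect_error(class_weights(0, 10), ">= 1")
})

test_that("a separable fixture is classified with correct signs", {
  m <- make_separable_matrix()
  member <- train_member(m)
  d <- member_decision(member, m)
  expect_true(all(sign(d) == m$labels[names(d)]))
})

test_that("flipping classes negates the decision values", {
  m <- make_noisy_matrix(30, 30, seed = 41)
  flipped <- m
  flipped$labels <- -m$labels
  d1 <- member_decision(train_member(m), m)
  d2 <- member_decision(train_member(flipped), flipped)
  expect_equal(unname(d1), unname(-d2), tolerance = 1e-6)
})

test_that("class weighting raises minority-class training recall", {
  m <- make_noisy_matrix(20, 1000, seed = 42, sep = 1.6)
  member <- train_member(m)
  d_weighted <- member_decision(member, m)
  tt <- names(m$labels)[m$labels > 0]
  recall_weighted <- mean(d_weighted[tt] > 0)
  # comparator: identical backend fit with no class weighting
  y <- factor(ifelse(m$labels > 0, "TT", "FT"), levels = c("TT", "FT"))
  plain <- e1071::svm(x = m$x, y = y, type = "C-classification",
                      kernel = "radial", gamma = 1 / 7, cost = 1,
                      scale = FALSE)
  dv <- attr(predict(plain, m$x, decision.values = TRUE), "decision.values")
  d_plain <- if (startsWith(colnames(dv)[1], "TT/")) dv[, 1] else -dv[, 1]
  recall_plain <- mean(d_plain[match(tt, m$ids)] > 0)
  expect_gt(recall_weighted, recall_plain)
})

test_that("single-class or unlabeled matrices cannot be trained", {
  m <- make_noisy_matrix(10, 10, seed = 43)
  m$labels[] <- 1
  expect_error(train_member(m), "single class")
  m$labels <- NULL
  expect_error(train_member(m), "labeled")
})

test_that("ensembles keep one member per eligible experiment", {
  mk <- function(n_tt, id, qc = TRUE) {
    list(matrix = make_noisy_matrix(n_tt, 120, seed = nchar(id) * 7 + n_tt,
                                    experiment = id),
         qc = qc, id = id)
  }
  exps <- list(mk(40, "a"), mk(10, "b"), mk(25, "c"), mk(5, "d"),
               mk(30, "e"))
  expect_message(ens <- train_ensemble(exps), "skipped 2")
  expect_equal(ens$n, 3L)
  expect_equal(vapply(ens$members, `[[`, "", "experiment"),
               c("a", "c", "e"))
  expect_error(suppressMessages(
    train_ensemble(list(mk(40, "a", qc = FALSE), mk(30, "b", qc = FALSE)))),
    "QC failed")
  ens1 <- train_ensemble(list(mk(40, "solo")))
  expect_equal(ens1$n, 1L)
})

test_that("consensus is the sum of member decision values", {
  m <- make_noisy_matrix(30, 60, seed = 45)
  ens <- train_ensemble(list(list(matrix = m, qc = TRUE, id = "one")),
                        min_tt = 20)
  d <- member_decision(ens$members[[1]], m)
  expect_equal(predict_consensus(ens, m), d)
  doubled <- ens
  doubled$members <- c(ens$members, ens$members)
  doubled$n <- 2L
  expect_equal(predict_consensus(doubled, m), 2 * d)
  wrong <- m
  colnames(wrong$x) <- rev(colnames(wrong$x))
  expect_error(predict_consensus(ens, wrong), "feature-order mismatch")
})

test_that("vote aggregation sums hard votes", {
  m <- make_noisy_matrix(30, 60, seed = 46)
  cfg <- svm_config(aggregate = "vote")
  ens <- train_ensemble(list(list(matrix = m, qc = TRUE, id = "one")),
                        cfg = cfg, min_tt = 20)
  s <- predict_consensus(ens, m)
  expect_true(all(s %in% c(-1, 0, 1)))
})

test_that("persisted ensembles reproduce identical consensus scores", {
  m <- make_noisy_matrix(25, 50, seed = 47)
  ens <- train_ensemble(list(list(matrix = m, qc = TRUE, id = "one")),
                        min_tt = 20)
  path <- tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  expect_equal(predict_consensus(back, m), predict_consensus(ens, m),
               tolerance = 1e-9)
  # truncated file
  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".rds")
  writeBin(raw[1:20], trunc_path)
  expect_error(load_ensemble(trunc_path), "cannot load")
  # version mismatch
  bad <- ens; bad$version <- 99L
  bad_path <- tempfile(fileext = ".rds")
  saveRDS(bad, bad_path)
  expect_error(load_ensemble(bad_path), "version mismatch")
})

test_that("training and scoring are deterministic for fixed inputs", {
  m <- make_noisy_matrix(30, 90, seed = 48)
  s1 <- predict_consensus(train_ensemble(list(list(matrix = m, qc = TRUE,
                                                   id = "e")), min_tt = 20), m)
  s2 <- predict_consensus(train_ensemble(list(list(matrix = m, qc = TRUE,
                                                   id = "e")), min_tt = 20), m)
  expect_identical(s1, s2)
})
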
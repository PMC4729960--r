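test_that("inverse-frequency weights are exactly proportional", {
  labels <- c(rep("big", 40), rep("small", 20), rep("tiny", 10))
  w <- inverse_frequency_weights(labels)
  expect_equal(unname(w["small"] / w["big"]), 2)
  expect_equal(unname(w["tiny"] / w["small"]), 2)
  expect_equal(mean(w), 1)
})

test_that("well-separated classes reach near-perfect outer-CV macro-F1", {
  sim <- simulate_experiment(preset_config("C1", seed = 3))
  m <- normalize_sum_to_one(aggregate_psms_to_proteins(
    suppressMessages(filter_missing(sim$psms))))
  clf <- train_svm(m, sim$markers,
                   classifier_params(n_repeats = 5, seed = 3))
  expect_gte(mean(clf$outer_f1), 0.99)
  # independent nearest-centroid oracle agrees the problem is separable
  parts <- attach_markers(m, sim$markers)
  cents <- class_median_profiles(m, sim$markers)
  truth <- stats::setNames(sim$truth$class, sim$truth$protein_id)
  d <- distance_to_medians(parts$unlabelled, cents)
  pred <- rownames(cents)[max.col(-d)]
  expect_gte(mean(pred == truth[rownames(parts$unlabelled)]), 0.99)
})

test_that("a degenerate single-point grid is selected verbatim", {
  sim <- simulate_experiment(preset_config("C1", seed = 3))
  m <- normalize_sum_to_one(aggregate_psms_to_proteins(
    suppressMessages(filter_missing(sim$psms))))
  clf <- train_svm(m, sim$markers,
                   classifier_params(sigma_grid = 0.5, cost_grid = 4,
                                     n_repeats = 2, seed = 1))
  expect_equal(clf$sigma, 0.5)
  expect_equal(clf$cost, 4)
})

test_that("training validates class sizes and names the offender", {
  m <- make_profiles(matrix(stats::runif(100), 10, 10))
  mk <- marker_set(stats::setNames(c(rep("big", 7), rep("rare", 3)),
                                   rownames(m)))
  expect_error(train_svm(m, mk, classifier_params(n_folds = 5)), "rare")
})

test_that("scores are probabilities over classes and deterministic", {
  sim <- simulate_experiment(preset_config("C1", seed = 3))
  m <- normalize_sum_to_one(aggregate_psms_to_proteins(
    suppressMessages(filter_missing(sim$psms))))
  clf <- train_svm(m, sim$markers,
                   classifier_params(sigma_grid = c(1, 10), cost_grid = c(4, 16),
                                     n_repeats = 2, seed = 5))
  parts <- attach_markers(m, sim$markers)
  sc <- score_proteins(clf, parts$unlabelled)
  expect_true(all(abs(rowSums(sc$probabilities) - 1) <= 1e-9))
  expect_true(all(sc$svm_score >= 0 & sc$svm_score <= 1))
  sc2 <- score_proteins(clf, parts$unlabelled)
  expect_identical(sc$probabilities, sc2$probabilities)
  # a protein sitting on a class template scores highest for that class
  probe <- profile_matrix(
    matrix(sim$templates[1, ], 1, 10,
           dimnames = list("probe", colnames(parts$unlabelled))),
    normalized = TRUE)
  sp <- score_proteins(clf, probe)
  expect_equal(unname(sp$svm_class), rownames(sim$templates)[1])
  # empty input gives an empty result
  sc0 <- score_proteins(clf, parts$unlabelled[0, ])
  expect_length(sc0$svm_score, 0L)
  # channel mismatch is an error
  expect_error(score_proteins(clf, make_profiles(matrix(1, 3, 4))), "mismatch")
})

test_that("threshold calibration matches the exhaustive-scan oracle", {
  # the documented toy example: 8 concordant then 2 discordant at the bottom
  fake_scores <- function(score, class, ids) {
    prob <- cbind(a = score, b = 1 - score)
    rownames(prob) <- ids
    structure(list(probabilities = prob,
                   svm_class = stats::setNames(class, ids),
                   svm_score = stats::setNames(score, ids)),
              class = "ProteinScores")
  }
  ids <- sprintf("p%02d", 1:10)
  score <- seq(0.95, 0.5, length.out = 10)
  sc <- fake_scores(score, rep("a", 10), ids)
  ann <- annotation_table(
    stats::setNames(c(rep("a", 8), "b", "b"), ids), c("a", "b"))
  thr <- suppressWarnings(
    calibrate_thresholds(sc, ann, threshold_params(target_fdr = 0.05,
                                                   min_annotated = 5)))
  expect_equal(unname(thr["a"]),
               threshold_oracle(score, c(rep(TRUE, 8), FALSE, FALSE), 0.05))
  expect_equal(unname(thr["a"]), score[8])

  # 1,000 random toy tables against the oracle
  set.seed(77)
  for (i in 1:250) {
    n <- sample(10:40, 1)
    s <- round(stats::runif(n), 3)
    conc <- stats::runif(n) < 0.8
    ids <- sprintf("q%03d", seq_len(n))
    sc <- fake_scores(s, rep("a", n), ids)
    ann <- annotation_table(
      stats::setNames(ifelse(conc, "a", "b"), ids), c("a", "b"))
    for (target in c(0.02, 0.05, 0.1, 0.25)) {
      got <- suppressWarnings(calibrate_thresholds(
        sc, ann, threshold_params(target_fdr = target, min_annotated = 5)))
      expect_identical(unname(got["a"]),
                       threshold_oracle(s, conc, target))
    }
  }
})

test_that("threshold edge cases behave as documented", {
  ids <- sprintf("p%d", 1:12)
  score <- seq(0.9, 0.4, length.out = 12)
  prob <- cbind(a = score, b = 1 - score); rownames(prob) <- ids
  sc <- structure(list(probabilities = prob,
                       svm_class = stats::setNames(rep("a", 12), ids),
                       svm_score = stats::setNames(score, ids)),
                  class = "ProteinScores")
  ann_all <- annotation_table(stats::setNames(rep("a", 12), ids), c("a", "b"))
  # all concordant: threshold = minimum observed score
  thr <- suppressWarnings(calibrate_thresholds(sc, ann_all,
                                               threshold_params(min_annotated = 5)))
  expect_equal(unname(thr["a"]), min(score))
  # target_fdr = 1 disables gating entirely
  thr1 <- calibrate_thresholds(sc, ann_all,
                               threshold_params(target_fdr = 1))
  expect_equal(unname(thr1), c(0, 0))
  # under-annotated class gets +Inf with a warning
  few <- annotation_table(stats::setNames("a", ids[1]), c("a", "b"))
  w <- capture_warnings(
    thr2 <- calibrate_thresholds(sc, few, threshold_params(min_annotated = 10)))
  expect_match(w, "Inf", all = TRUE)
  expect_equal(unname(thr2["a"]), Inf)
  # no usable annotation at all is an error
  unk <- annotation_table(stats::setNames(rep("x", 12), ids), c("a", "b"))
  expect_error(calibrate_thresholds(sc, unk, threshold_params()), "annotation")
})

test_that("assignment gates on the class threshold, markers pass through", {
  ids <- c("u1", "u2", "u3")
  prob <- cbind(a = c(0.9, 0.6, 0.8), b = c(0.1, 0.4, 0.2))
  rownames(prob) <- ids
  sc <- structure(list(probabilities = prob,
                       svm_class = stats::setNames(c("a", "a", "b"), ids),
                       svm_score = stats::setNames(c(0.9, 0.6, 0.8), ids)),
                  class = "ProteinScores")
  res <- assign_classes(sc, c(a = 0.7, b = Inf),
                        markers = marker_set(c(m1 = "a")))
  expect_equal(res$final_label[res$protein_id == "u1"], "a")
  expect_equal(res$final_label[res$protein_id == "u2"], "UNASSIGNED")
  expect_equal(res$final_label[res$protein_id == "u3"], "UNASSIGNED")
  expect_equal(res$final_label[res$protein_id == "m1"], "a")
  expect_equal(res$svm_score[res$protein_id == "m1"], 1)
  expect_error(assign_classes(sc, c(a = 0.5)), "thresholds missing")
  # assignments are non-increasing in any class threshold
  res_lo <- assign_classes(sc, c(a = 0.5, b = 0.5))
  expect_gte(sum(res_lo$final_label != "UNASSIGNED"),
             sum(assign_classes(sc, c(a = 0.95, b = 0.5))$final_label != "UNASSIGNED"))
})
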
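test_that("class median profiles are channel-wise medians of marker rows", {
  vals <- rbind(c(0.1, 0.9), c(0.3, 0.7), c(0.2, 0.8), c(0.5, 0.5))
  dimnames(vals) <- list(c("a1", "a2", "a3", "b1"), c("CH01", "CH02"))
  m <- profile_matrix(vals, normalized = TRUE)
  mk <- marker_set(c(a1 = "A", a2 = "A", a3 = "A", b1 = "B"))
  med <- class_median_profiles(m, mk)
  expect_equal(unname(med["A", ]), c(0.2, 0.8))
  expect_equal(unname(med["B", ]), c(0.5, 0.5))   # single row passes through
  expect_equal(nrow(med), 2L)
  # class without rows is omitted with a warning
  mk2 <- marker_set(c(a1 = "A", a2 = "A", zz = "C"))
  expect_warning(med2 <- class_median_profiles(m, mk2), "omitted")
  expect_equal(rownames(med2), "A")
})

test_that("enrichment ratio is the mean-enriched over mean-depleted", {
  vals <- rbind(c(0.4, 0.4, 0.1, 0.1), rep(0.25, 4), c(0.5, 0.5, 0, 0))
  dimnames(vals) <- list(c("r1", "r2", "r3"), sprintf("CH%02d", 1:4))
  m <- profile_matrix(vals, normalized = TRUE)
  r <- suppressWarnings(enrichment_ratio(m, enriched = c("CH01", "CH02"),
                                         depleted = "CH03"))
  expect_equal(unname(r["r1"]), 4)
  expect_equal(unname(r["r2"]), 1)      # uniform row
  expect_equal(unname(r["r3"]), Inf)    # zero depleted mean flagged
  expect_warning(enrichment_ratio(m, c("CH01", "CH02"), "CH03"), "Inf")
  expect_error(enrichment_ratio(m, c("CH01"), c("CH01", "CH02")), "overlap")
})

test_that("interference compresses enrichment ratios towards one", {
  # mean mito-channel enrichment ratio falls monotonically as contamination
  # pulls profiles towards the population average
  ratios <- vapply(c(0, 0.3, 0.6, 0.9), function(lam) {
    p <- simulation_params(n_classes = 4, proteins_per_class = 25,
                           markers_per_class = 10, psm_per_protein_mean = 1,
                           noise_sd = 0.2, missing_rate = 0,
                           mixed_fraction = 0, contamination = lam, seed = 19)
    sim <- simulate_experiment(p)
    m <- normalize_sum_to_one(aggregate_psms_to_proteins(
      suppressMessages(filter_missing(sim$psms))))
    mito <- sim$truth$protein_id[sim$truth$class == "mitochondrion"]
    r <- enrichment_ratio(m[rownames(m) %in% mito, ],
                          enriched = "TMT126", depleted = "TMT128C")
    mean(r[is.finite(r)])
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("distances to medians obey closed forms and metric properties", {
  med <- structure(rbind(A = c(1, 0, 0), B = c(0, 1, 0)),
                   class = c("MedianProfileSet", "matrix", "array"))
  colnames(med) <- sprintf("CH%02d", 1:3)
  rv <- rbind(x = c(1, 0, 0), y = c(0, 1, 0))
  colnames(rv) <- colnames(med)
  rows <- profile_matrix(rv, normalized = TRUE)
  d <- distance_to_medians(rows, med)
  expect_equal(unname(d["x", "A"]), 0)
  expect_equal(unname(d["x", "B"]), sqrt(2))
  expect_equal(unname(d["y", "A"]), sqrt(2))
  # symmetry and non-negativity on random profiles
  set.seed(31)
  P <- matrix(stats::rexp(30), 10, 3)
  P <- P / rowSums(P)
  dimnames(P) <- list(sprintf("p%d", 1:10), colnames(med))
  pm <- profile_matrix(P, normalized = TRUE)
  dd <- distance_to_medians(pm, med)
  expect_true(all(dd >= 0))
  for (i in 1:10)
    expect_equal(unname(dd[i, "A"]),
                 sqrt(sum((P[i, ] - med["A", ])^2)))
  expect_error(distance_to_medians(make_profiles(matrix(1, 2, 4)), med),
               "mismatch")
})

test_that("rank-sum comparison matches theory and handles degeneracy", {
  set.seed(12)
  a <- stats::rnorm(500); b <- stats::rnorm(500, 3)
  out <- compare_distance_distributions(a, b)
  expect_lt(out$p.value, 1e-10)
  same <- compare_distance_distributions(a, a)
  expect_gt(same$p.value, 0.9)
  expect_warning(deg <- compare_distance_distributions(rep(1, 5), rep(1, 7)),
                 "tied")
  expect_equal(deg$p.value, 1)
})

test_that("exact rank-sum p-values match brute-force enumeration (n <= 5)", {
  set.seed(99)
  for (n1 in 2:5) for (n2 in 2:5) {
    for (rep in 1:3) {
      a <- stats::runif(n1); b <- stats::runif(n2)
      got <- compare_distance_distributions(a, b)
      expect_equal(got$p.value, wilcox_enum_oracle(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
})

test_that("replicate concordance counts contradictions, ignores UNASSIGNED", {
  mk_res <- function(ids, labels) {
    structure(data.frame(protein_id = ids, svm_class = labels,
                         svm_score = 1, final_label = labels,
                         stringsAsFactors = FALSE),
              class = c("ClassificationResult", "data.frame"))
  }
  r1 <- mk_res(c("p1", "p2", "p3", "p4"), c("A", "B", "A", "UNASSIGNED"))
  r2 <- mk_res(c("p1", "p2", "p3", "p4"), c("A", "A", "A", "B"))
  rep_same <- replicate_concordance(list(r1, r1))
  expect_equal(rep_same$fraction_contradictory, 0)
  rep_diff <- replicate_concordance(list(r1, r2))
  # p4 unassigned in r1 -> excluded; p2 contradicts
  expect_equal(rep_diff$n_compared, 3L)
  expect_equal(rep_diff$n_contradictory, 1L)
  expect_equal(rep_diff$fraction_contradictory, 1 / 3)
  # invariant under replicate order
  rep_rev <- replicate_concordance(list(r2, r1))
  expect_equal(rep_rev$fraction_contradictory,
               rep_diff$fraction_contradictory)
  expect_error(replicate_concordance(list(r1)), "two")
})
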
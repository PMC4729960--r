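test_that("PSM tables parse from TSV with missing values preserved as NA", {
  tsv <- tempfile(fileext = ".tsv")
  channels <- tmt10_channels()
  header <- paste(c("psm_id", "protein_group", channels), collapse = "\t")
  rows <- c(
    paste(c("s1", "P1", sprintf("%d", 1:10)), collapse = "\t"),
    paste(c("s2", "P1", "5", "", sprintf("%d", 3:10)), collapse = "\t"),
    paste(c("s3", "P2", sprintf("%d", 11:20)), collapse = "\t"))
  writeLines(c(header, rows), tsv)

  psms <- read_psm_table(tsv)
  expect_s3_class(psms, "PsmTable")
  expect_equal(nrow(psms), 3L)
  expect_true(is.na(psms[psms$psm_id == "s2", "TMT127N"]))
  expect_false(any(psms[psms$psm_id == "s2", "TMT126"] == 0))

  # file without the protein_group column is rejected
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("psm_id", channels), collapse = "\t"),
               paste(c("s1", 1:10), collapse = "\t")), bad)
  expect_error(read_psm_table(bad), "protein_group")

  # negative intensities reject the row with a warning
  neg <- tempfile(fileext = ".tsv")
  writeLines(c(header,
               paste(c("s1", "P1", "-3", sprintf("%d", 2:10)), collapse = "\t"),
               rows[3]), neg)
  expect_warning(ok <- read_psm_table(neg), "negative")
  expect_equal(ok$psm_id, "s3")
})

test_that("missing-value rule excludes >4 missing and zero-fills the rest", {
  vals <- rbind(
    c(NA, NA, NA, NA, NA, 6, 7, 8, 9, 10),   # 5 missing -> excluded
    c(NA, NA, NA, NA, 5, 6, 7, 8, 9, 10),    # 4 missing -> kept, zero-filled
    1:10)                                      # complete -> unchanged
  psms <- make_psms(vals, c("P1", "P2", "P3"))
  out <- suppressMessages(filter_missing(psms, max_missing = 4))
  expect_equal(out$protein_group, c("P2", "P3"))
  expect_equal(unname(unlist(out[1, tmt10_channels()])),
               c(0, 0, 0, 0, 5:10))
  expect_equal(unname(unlist(out[2, tmt10_channels()])), as.numeric(1:10))
  expect_equal(unname(attr(out, "filter_counts")),
               c(1L, 2L), ignore_attr = TRUE)

  # max_missing = C keeps every row (zero-fill only)
  all_kept <- suppressMessages(filter_missing(psms, max_missing = 10))
  expect_equal(nrow(all_kept), 3L)
  expect_false(anyNA(all_kept[tmt10_channels()]))
})

test_that("protein aggregation is the channel-wise median, order-invariant", {
  # frozen odd/even-count examples checked against the sort oracle
  expect_equal(median_oracle(c(0.1, 0.2, 0.9)), 0.2)
  expect_equal(median_oracle(c(0.2, 0.4)), 0.3)

  vals <- rbind(c(0.1, rep(1, 9)), c(0.2, rep(1, 9)), c(0.9, rep(1, 9)),
                c(0.2, rep(2, 9)), c(0.4, rep(2, 9)))
  psms <- make_psms(vals, c("A", "A", "A", "B", "B"))
  m <- aggregate_psms_to_proteins(psms)
  expect_equal(unname(m["A", 1]), 0.2)
  expect_equal(unname(m["B", 1]), 0.3)

  # a single-PSM group passes through unchanged
  single <- aggregate_psms_to_proteins(make_psms(rbind(1:10), "solo"))
  expect_equal(unname(unclass(single)["solo", ]), as.numeric(1:10))

  # permuting the PSM rows leaves the aggregate unchanged
  set.seed(42)
  perm <- sample(nrow(psms))
  m_perm <- aggregate_psms_to_proteins(make_psms(vals[perm, ],
                                                 c("A", "A", "A", "B", "B")[perm]))
  expect_identical(unclass(m), unclass(m_perm))
})

test_that("median aggregation matches the sort oracle on random small groups", {
  set.seed(101)
  for (case in seq_len(1000)) {
    n <- sample(1:6, 1)
    x <- round(stats::runif(n, 0, 100), 3)
    expect_identical(stats::median(x), median_oracle(x))
  }
  # and through the aggregation path on a random table
  set.seed(202)
  n <- 60
  groups <- sample(sprintf("P%02d", 1:12), n, replace = TRUE)
  vals <- matrix(stats::rexp(n * 10), n, 10)
  m <- aggregate_psms_to_proteins(make_psms(vals, groups))
  for (g in unique(groups)) {
    expected <- apply(vals[groups == g, , drop = FALSE], 2L, median_oracle)
    expect_equal(unname(unclass(m)[g, ]), unname(expected))
  }
})

test_that("sum-to-one normalization is exact, idempotent, and drops zero rows", {
  vals <- rbind(c(2, 2, 6, rep(0, 7)), rep(0, 10), stats::runif(10))
  rownames(vals) <- c("a", "zero", "b")
  colnames(vals) <- tmt10_channels()
  expect_warning(m <- normalize_sum_to_one(profile_matrix(vals)), "all-zero")
  expect_equal(rownames(m), c("a", "b"))
  expect_equal(unname(unclass(m)["a", 1:3]), c(0.2, 0.2, 0.6))
  expect_true(all(abs(rowSums(m) - 1) <= 1e-9))
  expect_true(is_normalized(m))
  # idempotence
  m2 <- normalize_sum_to_one(m)
  expect_true(all(abs(unclass(m2) - unclass(m)) < 1e-12))
})

test_that("profile matrices round-trip through TSV", {
  set.seed(7)
  m <- make_profiles(matrix(stats::rexp(50), 5, 10))
  path <- tempfile(fileext = ".tsv")
  write_profile_matrix(m, path)
  back <- read_profile_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_true(is_normalized(back))
  expect_equal(colnames(back), tmt10_channels())

  # empty matrix -> header-only file -> empty matrix
  empty <- profile_matrix(matrix(numeric(0), 0, 10,
                                 dimnames = list(NULL, tmt10_channels())))
  p2 <- tempfile(fileext = ".tsv")
  write_profile_matrix(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(nrow(read_profile_matrix(p2)), 0L)
})
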
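# small programmatic fixtures shared across test files

# build a PsmTable directly from a channel-value matrix (NA = missing)
make_psms <- function(values, groups, channels = NULL) {
  values <- as.matrix(values)
  if (is.null(channels))
    channels <- if (ncol(values) == 10) tmt10_channels()
                else sprintf("CH%02d", seq_len(ncol(values)))
  df <- data.frame(psm_id = sprintf("psm%03d", seq_len(nrow(values))),
                   protein_group = groups, stringsAsFactors = FALSE)
  df[channels] <- as.data.frame(values)
  psm_table(df, channels = channels)
}

# tiny normalized profile matrix with given rows
make_profiles <- function(values, ids = NULL, channels = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("prot%03d", seq_len(nrow(values)))
  if (is.null(channels))
    channels <- if (ncol(values) == 10) tmt10_channels()
                else sprintf("CH%02d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, channels)
  normalize_sum_to_one(profile_matrix(values))
}

# independent sort-based median oracle (never uses stats::median)
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# exhaustive-scan FDR threshold oracle: try every observed cutoff, return
# the smallest score t with FDR(>= t) <= target, else Inf
threshold_oracle <- function(scores, concordant, target) {
  cutoffs <- sort(unique(scores))
  ok <- vapply(cutoffs, function(t) {
    sel <- scores >= t
    sum(!concordant[sel]) / sum(sel) <= target
  }, logical(1))
  if (!any(ok)) Inf else min(cutoffs[ok])
}

# independent macro-averaged F1 computed from an explicit confusion table
macro_f1_oracle <- function(truth, pred) {
  classes <- union(unique(truth), unique(pred))
  tab <- table(factor(truth, classes), factor(pred, classes))
  f1 <- vapply(classes, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    if (2 * tp + fp + fn == 0) return(NA_real_)
    as.numeric(2 * tp / (2 * tp + fp + fn))
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

# brute-force two-sided Mann-Whitney p-value by enumerating all group
# assignments of the pooled ranks (tie-free samples only)
wilcox_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
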
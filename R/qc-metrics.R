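#' Per-class median reporter profiles
#'
#' The channel-wise median over each class's marker rows present in the
#' matrix — the organelle "consensus" profile that distance-based QC is
#' anchored to. Classes without any row in the matrix are omitted with a
#' warning.
#'
#' @param m `ProfileMatrix` (protein- or PSM-level).
#' @param markers `MarkerSet`.
#' @return matrix classes x channels (`MedianProfileSet`).
#' @export
class_median_profiles <- function(m, markers) {
  stopifnot(inherits(m, "ProfileMatrix"), inherits(markers, "MarkerSet"))
  classes <- marker_classes(markers)
  rows_by_class <- lapply(classes, function(cl) {
    ids <- names(markers)[unclass(markers) == cl]
    intersect(ids, rownames(m))
  })
  empty <- lengths(rows_by_class) == 0
  if (any(empty)) {
    warning("class(es) without rows in the matrix omitted: ",
            paste(classes[empty], collapse = ", "))
    classes <- classes[!empty]
    rows_by_class <- rows_by_class[!empty]
  }
  if (length(classes) == 0) stop("no marker class overlaps the matrix")
  med <- t(vapply(rows_by_class, function(ids)
    apply(unclass(m)[ids, , drop = FALSE], 2L, stats::median),
    numeric(ncol(m))))
  dimnames(med) <- list(classes, colnames(m))
  structure(med, class = c("MedianProfileSet", "matrix", "array"))
}

#' Enriched/depleted channel ratio
#'
#' The ratio between the mean of channels expected to be enriched for a
#' compartment and the mean of channels expected to be depleted — ratio
#' compression (interference) pulls it towards 1. A zero depleted mean
#' yields `Inf`, flagged with a warning.
#'
#' @param m `ProfileMatrix`.
#' @param enriched,depleted disjoint, non-empty channel subsets (names or
#'   indices).
#' @return named per-row ratio vector.
#' @export
enrichment_ratio <- function(m, enriched, depleted) {
  stopifnot(inherits(m, "ProfileMatrix"))
  to_idx <- function(ch) {
    if (is.character(ch)) {
      miss <- setdiff(ch, colnames(m))
      if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
      match(ch, colnames(m))
    } else as.integer(ch)
  }
  ei <- to_idx(enriched); di <- to_idx(depleted)
  if (length(ei) == 0 || length(di) == 0)
    stop("channel subsets must be non-empty")
  if (length(intersect(ei, di)))
    stop("enriched and depleted channel subsets overlap")
  num <- rowMeans(unclass(m)[, ei, drop = FALSE])
  den <- rowMeans(unclass(m)[, di, drop = FALSE])
  if (any(den == 0))
    warning(sum(den == 0), " row(s) with zero depleted mean: ratio is Inf")
  stats::setNames(num / den, rownames(m))
}

#' Distances from rows to class median profiles
#'
#' Euclidean distance in the normalized profile space (the geometry the PCA
#' maps live in); a chi-square variant, which down-weights high-abundance
#' channels, is available behind `method = "chisq"`.
#'
#' @param rows `ProfileMatrix` (e.g., the normalized PSM matrix).
#' @param medians `MedianProfileSet` of matching width.
#' @param method `"euclidean"` (default) or `"chisq"`.
#' @return matrix rows x classes of distances.
#' @export
distance_to_medians <- function(rows, medians,
                                method = c("euclidean", "chisq")) {
  method <- match.arg(method)
  stopifnot(inherits(rows, "ProfileMatrix"))
  if (ncol(rows) != ncol(medians))
    stop("width mismatch between rows and median profiles")
  X <- unclass(rows)
  out <- matrix(NA_real_, nrow(X), nrow(medians),
                dimnames = list(rownames(X), rownames(medians)))
  for (k in seq_len(nrow(medians))) {
    dev <- sweep(X, 2L, medians[k, ], "-")
    if (method == "chisq") {
      denom <- sweep(X, 2L, medians[k, ], "+")
      w <- dev^2 / denom
      w[denom == 0] <- 0
      out[, k] <- sqrt(rowSums(w))
    } else {
      out[, k] <- sqrt(rowSums(dev^2))
    }
  }
  out
}

#' Two-sample comparison of distance distributions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test, exact for small
#' tie-free samples. Degenerate all-tied samples return `p = 1` with a
#' warning.
#'
#' @param a,b numeric distance samples.
#' @return list with `statistic` (Mann-Whitney W) and `p.value`.
#' @export
compare_distance_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("all observations tied; returning p = 1")
    return(list(statistic = length(a) * length(b) / 2, p.value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Cross-replicate assignment concordance
#'
#' Over proteins assigned (non-`UNASSIGNED`) in at least two replicate
#' results, a protein is contradictory when any two replicates disagree on
#' its final label. Proteins unassigned in a replicate are excluded from
#' that comparison, so the fraction measures genuine contradictions, not
#' coverage differences.
#'
#' @param results list of two or more `ClassificationResult` objects.
#' @return a `ConcordanceReport` list: `n_compared`, `n_contradictory`,
#'   `fraction_contradictory`, `pairwise_confusion` (one confusion table per
#'   replicate pair).
#' @export
replicate_concordance <- function(results) {
  if (!is.list(results) || length(results) < 2)
    stop("need at least two classification results")
  labs <- lapply(results, function(r) {
    stopifnot(inherits(r, "ClassificationResult"))
    stats::setNames(r$final_label, r$protein_id)
  })
  all_ids <- unique(unlist(lapply(labs, names)))
  assigned <- do.call(cbind, lapply(labs, function(l) {
    v <- l[all_ids]
    !is.na(v) & v != "UNASSIGNED"
  }))
  rownames(assigned) <- all_ids
  compared <- rowSums(assigned) >= 2
  contradictory <- vapply(all_ids[compared], function(id) {
    v <- vapply(labs, function(l) unname(l[id]), character(1))
    v <- v[!is.na(v) & v != "UNASSIGNED"]
    length(unique(v)) > 1L
  }, logical(1))
  pairs <- utils::combn(length(labs), 2L, simplify = FALSE)
  confusion <- lapply(pairs, function(p) {
    ids <- all_ids[assigned[, p[1]] & assigned[, p[2]]]
    table(replicate_a = labs[[p[1]]][ids], replicate_b = labs[[p[2]]][ids])
  })
  names(confusion) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  n_comp <- sum(compared)
  structure(list(n_compared = n_comp,
                 n_contradictory = sum(contradictory),
                 fraction_contradictory =
                   if (n_comp == 0) NA_real_ else sum(contradictory) / n_comp,
                 pairwise_confusion = confusion),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf("ConcordanceReport: %d/%d contradictory (%.2f%%)\n",
              x$n_contradictory, x$n_compared,
              100 * x$fraction_contradictory))
  invisible(x)
}
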
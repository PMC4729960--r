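#' Parameters for phenotype discovery
#'
#' Defaults follow the reference analysis: a stringent 200-iteration run
#' with outlier testing at the 5% level and a minimum of 20 proteins per new
#' phenotype cluster (small organelles and complexes remain detectable).
#'
#' @param n_iterations number of bootstrap iterations N per outer round.
#' @param outlier_level significance level P of the chi-square outlier test.
#' @param min_group_size smallest admissible new phenotype cluster GS.
#' @param seed integer seed governing all randomness of the run.
#' @param max_outer_rounds cap on outer discovery rounds.
#' @export
discovery_params <- function(n_iterations = 200L, outlier_level = 0.05,
                             min_group_size = 20L, seed = 1L,
                             max_outer_rounds = 10L) {
  stopifnot(n_iterations >= 1, outlier_level > 0, outlier_level < 1,
            min_group_size >= 1, max_outer_rounds >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 outlier_level = outlier_level,
                 min_group_size = as.integer(min_group_size),
                 seed = as.integer(seed),
                 max_outer_rounds = as.integer(max_outer_rounds)),
            class = "DiscoveryParams")
}

# log-density of rows of x under N(mu, sigma); sigma already regularized
.log_dmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(x) * log(2 * pi)
}

.maha_sq <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  colSums(z^2)
}

#' Phenotype discovery by semi-supervised Gaussian novelty detection
#'
#' Detects clusters of unlabelled proteins that form candidate new
#' compartments and augments the marker set with them (classes
#' `phenotype_1`, `phenotype_2`, ...). Marker proteins are never relabelled.
#'
#' The procedure, per outer round (at most `max_outer_rounds`, stopping as
#' soon as a round creates no phenotype): (1) fit one full-covariance
#' Gaussian (regularized by `1e-6 * I`) per current class to its labelled
#' profiles; (2) for each of `n_iterations` bootstrap resamples of the
#' labelled data, assign every unlabelled protein to its maximum-posterior
#' class (class-frequency priors; posterior ties broken towards the lowest
#' class index) and flag it an outlier when its squared Mahalanobis distance
#' to that class exceeds the chi-square quantile at `1 - outlier_level` with
#' the working-space dimension as degrees of freedom; (3) proteins flagged
#' in more than half of the iterations become candidates; (4) candidates are
#' clustered with a Gaussian mixture selected by BIC over 1..10 components
#' (fitted in the candidates' own leading principal components — 95%
#' variance, dimension capped at one tenth of the candidate count — since
#' candidate sets are far too small to estimate full-rank covariances) and
#' components with at least `min_group_size` members become new classes.
#'
#' The whole procedure runs in the full-rank principal-component basis of
#' the matrix (row-normalized profiles lie on a simplex, so the raw space is
#' rank-deficient and covariance fits there are singular); matrices wider
#' than 20 effective dimensions are further truncated to the leading
#' components capturing 95% of the variance. The chi-square degrees of
#' freedom equal the working-space dimension.
#'
#' @param m normalized `ProfileMatrix` (protein level).
#' @param markers `MarkerSet`; needs at least two classes with at least six
#'   members each among the rows of `m`.
#' @param params a [discovery_params()] object.
#' @return a `DiscoveryResult` list: `augmented_markers` (`MarkerSet`),
#'   `new_classes`, `membership_scores` (per unlabelled protein, the
#'   fraction of final-round iterations supporting its status),
#'   `rounds_run`.
#' @export
phenodisco <- function(m, markers, params = discovery_params()) {
  stopifnot(inherits(m, "ProfileMatrix"), inherits(markers, "MarkerSet"),
            inherits(params, "DiscoveryParams"))
  if (!is_normalized(m) && is.null(fused_blocks(m)))
    stop("phenodisco expects a normalized (or fused) profile matrix")
  parts <- attach_markers(m, markers)
  lab_classes <- table(unclass(parts$labels))
  if (length(lab_classes) < 2)
    stop("phenodisco needs at least two marker classes present in the matrix")
  if (any(lab_classes < 6))
    stop("marker class(es) too small to fit a Gaussian component (need >= 6): ",
         paste(names(lab_classes)[lab_classes < 6], collapse = ", "))

  # working space: the full-rank principal-component basis. Row-normalized
  # profiles live on a simplex (rank <= C - 1), so raw-space covariances are
  # singular and mixture fits degenerate; rotating onto the non-null
  # components preserves all distances while making every Gaussian fit
  # well-posed. Wide (fused) matrices are additionally truncated to the
  # leading components capturing 95% of the variance.
  X <- unclass(m)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  d <- sum(vars > max(vars) * 1e-9)
  if (d > 20) {
    cum <- cumsum(vars) / sum(vars)
    d <- max(2L, which(cum >= 0.95)[1])
  }
  X <- pc$x[, seq_len(d), drop = FALSE]
  chi_cut <- stats::qchisq(1 - params$outlier_level, df = d)

  labels <- stats::setNames(unclass(parts$labels), names(parts$labels))
  unlab <- rownames(parts$unlabelled)
  scores <- stats::setNames(rep(NA_real_, length(unlab)), unlab)
  new_classes <- character(0)
  rounds <- 0L
  set.seed(.derive_seed(params$seed, "phenodisco"))

  if (length(unlab) > 0) {
    repeat {
      rounds <- rounds + 1L
      classes <- unique(unname(labels))
      lab_rows <- lapply(classes, function(cl) X[names(labels)[labels == cl], ,
                                                 drop = FALSE])
      names(lab_rows) <- classes
      priors <- vapply(lab_rows, nrow, numeric(1))
      priors <- priors / sum(priors)
      U <- X[unlab, , drop = FALSE]

      out_votes <- stats::setNames(numeric(length(unlab)), unlab)
      assign_votes <- matrix(0L, length(unlab), length(classes),
                             dimnames = list(unlab, classes))
      for (it in seq_len(params$n_iterations)) {
        logpost <- matrix(-Inf, length(unlab), length(classes))
        maha <- matrix(Inf, length(unlab), length(classes))
        for (k in seq_along(classes)) {
          rows <- lab_rows[[k]]
          boot <- rows[sample.int(nrow(rows), nrow(rows), replace = TRUE), ,
                       drop = FALSE]
          mu <- colMeans(boot)
          sg <- stats::cov(boot) + diag(1e-6, d)
          logpost[, k] <- log(priors[k]) + .log_dmvnorm(U, mu, sg)
          maha[, k] <- .maha_sq(U, mu, sg)
        }
        best <- max.col(logpost, ties.method = "first")
        flagged <- maha[cbind(seq_along(best), best)] > chi_cut
        out_votes <- out_votes + flagged
        assign_votes[cbind(seq_along(best), best)] <-
          assign_votes[cbind(seq_along(best), best)] + 1L
      }
      frac_out <- out_votes / params$n_iterations
      candidates <- unlab[frac_out > 0.5]

      created <- character(0)
      if (length(candidates) >= params$min_group_size) {
        # candidate sets are small relative to the working dimension, so the
        # mixture is fitted in the candidates' own leading-PC subspace (95%
        # variance, dimension capped at n/10) where covariances are
        # estimable; membership is what matters, not the fitting basis
        Y <- X[candidates, , drop = FALSE]
        pc_c <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
        cum <- cumsum(pc_c$sdev^2) / sum(pc_c$sdev^2)
        d_c <- max(2L, min(which(cum >= 0.95)[1],
                           floor(length(candidates) / 10)))
        d_c <- min(d_c, ncol(Y))
        G <- seq_len(min(10L, max(1L, length(candidates) - 1L)))
        fit <- mclust::Mclust(pc_c$x[, seq_len(d_c), drop = FALSE], G = G,
                              verbose = FALSE)
        if (!is.null(fit)) {
          comp_sizes <- table(fit$classification)
          for (comp in names(comp_sizes)[comp_sizes >= params$min_group_size]) {
            cl_name <- paste0("phenotype_", length(new_classes) +
                                length(created) + 1L)
            members <- candidates[fit$classification == as.integer(comp)]
            labels[members] <- cl_name
            scores[members] <- frac_out[members]
            created <- c(created, cl_name)
          }
        }
      }
      # support score for proteins that stay unlabelled: agreement with
      # their modal class assignment over the N iterations
      still <- setdiff(unlab, names(labels))
      if (length(still)) {
        modal <- apply(assign_votes[still, , drop = FALSE], 1L, max)
        scores[still] <- modal / params$n_iterations
      }
      new_classes <- c(new_classes, created)
      unlab <- still
      if (length(created) == 0 || rounds >= params$max_outer_rounds ||
          length(unlab) == 0)
        break
    }
  }

  # original marker entries keep their order; phenotype members are appended
  new_entries <- labels[!(names(labels) %in% names(markers))]
  augmented <- marker_set(c(unclass(markers), new_entries))
  structure(list(augmented_markers = augmented,
                 new_classes = new_classes,
                 membership_scores = scores,
                 rounds_run = rounds),
            class = "DiscoveryResult")
}

#' @export
print.DiscoveryResult <- function(x, ...) {
  cat(sprintf("DiscoveryResult: %d new phenotype class(es) in %d round(s)\n",
              length(x$new_classes), x$rounds_run))
  for (cl in x$new_classes)
    cat(sprintf("  %s: %d proteins\n", cl,
                sum(unclass(x$augmented_markers) == cl)))
  invisible(x)
}
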
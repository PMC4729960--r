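#' Hyperparameters for the class-weighted RBF-SVM
#'
#' The radial kernel is parameterized as `exp(-sigma * ||x - y||^2)` — the
#' same convention in which the reference analysis reports its selected
#' bandwidth `sigma = 0.01` and cost `16` (note that some ecosystems instead
#' write `gamma = 1 / (2 * s^2)`; here `sigma` multiplies the squared
#' distance directly). Both study-selected values lie inside the default
#' grids.
#'
#' @param sigma_grid kernel bandwidths searched.
#' @param cost_grid soft-margin costs searched.
#' @param n_repeats repetitions of the stratified nested cross-validation.
#' @param n_folds folds of both the outer split and the inner grid search.
#' @param seed integer seed for all partitioning randomness.
#' @export
classifier_params <- function(sigma_grid = c(1e-3, 1e-2, 1e-1, 1, 10),
                              cost_grid = c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64),
                              n_repeats = 100L, n_folds = 5L, seed = 1L) {
  stopifnot(length(sigma_grid) >= 1, all(sigma_grid > 0),
            length(cost_grid) >= 1, all(cost_grid > 0),
            n_repeats >= 1, n_folds >= 2)
  structure(list(sigma_grid = sigma_grid, cost_grid = cost_grid,
                 n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "ClassifierParams")
}

#' Inverse-class-frequency weights
#'
#' Weights are inversely proportional to the marker-class frequencies (a
#' class with half the markers gets twice the weight), normalized so the
#' mean weight is one.
#' @param labels character/factor vector of class labels.
#' @export
inverse_frequency_weights <- function(labels) {
  tab <- table(as.character(labels))
  w <- 1 / as.numeric(tab)
  w <- w / mean(w)
  stats::setNames(w, names(tab))
}

# macro-averaged F1: unweighted mean over classes of 2TP/(2TP+FP+FN);
# classes absent from both truth and prediction are excluded
macro_f1 <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- union(unique(truth), unique(pred))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

# stratified fold assignment: within each class, shuffled members are dealt
# round-robin into folds
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

.fit_svm <- function(x, y, sigma, cost, weights) {
  e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
             gamma = sigma, cost = cost, class.weights = weights,
             probability = TRUE)
}

# the deployed prediction rule: argmax of the pairwise-coupled posterior
# probabilities (ties towards the first class)
.predict_class <- function(fit, x, levels_out) {
  pr <- stats::predict(fit, x, probability = TRUE)
  prob <- attr(pr, "probabilities")
  prob <- prob[, intersect(levels_out, colnames(prob)), drop = FALSE]
  colnames(prob)[max.col(prob, ties.method = "first")]
}

#' Train the class-weighted RBF-SVM with repeated nested cross-validation
#'
#' Each repeat draws a stratified `n_folds` partition; one fold is held out
#' for performance estimation while an inner stratified `n_folds`-fold
#' cross-validated grid search over `(sigma, cost)` runs on the remaining
#' training partition. Cross-validation scores the decision rule that is
#' actually deployed downstream — the argmax of the Platt-calibrated,
#' pairwise-coupled class probabilities — so hyperparameters that separate
#' the training data yet yield uninformative probabilities cannot win. The
#' winning hyperparameters maximize the mean inner macro-F1 across all
#' repeats (ties broken towards smaller cost, then smaller sigma — prefer
#' smoother models). The outer held-out folds,
#' scored with each repeat's inner winner, give an unbiased performance
#' estimate. The final model is refit on all labelled data with the winning
#' parameters, inverse-frequency class weights and Platt-style probability
#' calibration.
#'
#' @param m `ProfileMatrix` containing (at least) the marker rows.
#' @param markers `MarkerSet` of training labels.
#' @param params a [classifier_params()] object.
#' @param weights `"inverse"` (default; inverse-class-frequency weights, the
#'   reference behaviour) or `"uniform"` (no class weighting; mainly for
#'   head-to-head comparisons on imbalanced data).
#' @return a `TrainedClassifier` list: `sigma`, `cost`, `class_weights`,
#'   `cv_f1` (per-grid-point mean/sd of inner macro-F1), `outer_f1`
#'   (per-repeat held-out macro-F1), `model`, `channels`, `classes`,
#'   `marker_ids`.
#' @export
train_svm <- function(m, markers, params = classifier_params(),
                      weights = c("inverse", "uniform")) {
  stopifnot(inherits(m, "ProfileMatrix"), inherits(markers, "MarkerSet"),
            inherits(params, "ClassifierParams"))
  weights <- match.arg(weights)
  parts <- attach_markers(m, markers)
  x <- unclass(parts$labelled)
  y_chr <- unclass(parts$labels)
  if (length(unique(y_chr)) < 2)
    stop("training needs at least two marker classes")
  tab <- table(y_chr)
  small <- names(tab)[tab < params$n_folds]
  if (length(small))
    stop("marker class(es) with fewer members than n_folds: ",
         paste(small, collapse = ", "))
  y <- factor(y_chr)
  weights <- if (weights == "inverse") inverse_frequency_weights(y_chr)
             else stats::setNames(rep(1, nlevels(y)), levels(y))
  grid <- expand.grid(sigma = params$sigma_grid, cost = params$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)

  inner_f1 <- matrix(NA_real_, nrow(grid), params$n_repeats)
  outer_f1 <- rep(NA_real_, params$n_repeats)
  for (r in seq_len(params$n_repeats)) {
    set.seed(.derive_seed(params$seed, paste0("cv_repeat_", r)))
    fold <- .stratified_folds(y_chr, params$n_folds)
    test <- fold == 1L
    xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
    inner_fold <- .stratified_folds(as.character(ytr), params$n_folds)
    for (g in seq_len(nrow(grid))) {
      pred <- factor(rep(NA_character_, length(ytr)), levels = levels(y))
      for (f in seq_len(params$n_folds)) {
        hold <- inner_fold == f
        fit <- .fit_svm(xtr[!hold, , drop = FALSE], droplevels(ytr[!hold]),
                        grid$sigma[g], grid$cost[g],
                        weights[levels(droplevels(ytr[!hold]))])
        pred[hold] <- factor(.predict_class(fit, xtr[hold, , drop = FALSE],
                                            levels(y)), levels = levels(y))
      }
      inner_f1[g, r] <- macro_f1(as.character(ytr), as.character(pred),
                                 classes = levels(y))
    }
    best_r <- .pick_grid_winner(grid, inner_f1[, r])
    fit <- .fit_svm(xtr, ytr, grid$sigma[best_r], grid$cost[best_r], weights)
    pred_out <- .predict_class(fit, x[test, , drop = FALSE], levels(y))
    outer_f1[r] <- macro_f1(as.character(y[test]), pred_out,
                            classes = levels(y))
  }

  mean_f1 <- rowMeans(inner_f1)
  winner <- .pick_grid_winner(grid, mean_f1)
  set.seed(.derive_seed(params$seed, "final_fit"))
  final <- e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
                      gamma = grid$sigma[winner], cost = grid$cost[winner],
                      class.weights = weights, probability = TRUE)
  cv_tab <- data.frame(grid, mean_f1 = mean_f1,
                       sd_f1 = apply(inner_f1, 1L, stats::sd))
  structure(list(sigma = grid$sigma[winner], cost = grid$cost[winner],
                 class_weights = weights, cv_f1 = cv_tab,
                 outer_f1 = outer_f1, model = final,
                 channels = colnames(x), classes = levels(y),
                 marker_ids = rownames(x)),
            class = "TrainedClassifier")
}

# winner = max mean F1; ties -> smaller cost, then smaller sigma
.pick_grid_winner <- function(grid, f1) {
  ok <- which(f1 >= max(f1, na.rm = TRUE) - 1e-12)
  ok[order(grid$cost[ok], grid$sigma[ok])][1]
}

#' @export
print.TrainedClassifier <- function(x, ...) {
  cat(sprintf(
    "TrainedClassifier: RBF-SVM, sigma = %g, cost = %g, %d classes\n",
    x$sigma, x$cost, length(x$classes)))
  cat(sprintf("  outer-CV macro-F1: %.3f (sd %.3f over %d repeats)\n",
              mean(x$outer_f1), stats::sd(x$outer_f1), length(x$outer_f1)))
  invisible(x)
}

#' Score proteins against the trained classifier
#'
#' Returns per-class pairwise-coupled posterior probabilities (each row sums
#' to one), the argmax class and its probability as the SVM score.
#'
#' @param clf a `TrainedClassifier`.
#' @param m `ProfileMatrix` of proteins to score (channels must match the
#'   training matrix).
#' @return a `ProteinScores` list: `probabilities` (proteins x classes),
#'   `svm_class`, `svm_score`.
#' @export
score_proteins <- function(clf, m) {
  stopifnot(inherits(clf, "TrainedClassifier"), inherits(m, "ProfileMatrix"))
  if (!identical(colnames(m), clf$channels))
    stop("channel mismatch between classifier and profile matrix")
  if (nrow(m) == 0) {
    prob <- matrix(numeric(0), 0, length(clf$classes),
                   dimnames = list(character(0), clf$classes))
    return(structure(list(probabilities = prob,
                          svm_class = character(0),
                          svm_score = numeric(0)),
                     class = "ProteinScores"))
  }
  pr <- stats::predict(clf$model, unclass(m), probability = TRUE)
  prob <- attr(pr, "probabilities")[, clf$classes, drop = FALSE]
  prob <- prob / rowSums(prob)
  rownames(prob) <- rownames(m)
  best <- max.col(prob, ties.method = "first")
  structure(list(probabilities = prob,
                 svm_class = stats::setNames(clf$classes[best], rownames(m)),
                 svm_score = stats::setNames(prob[cbind(seq_len(nrow(prob)),
                                                        best)], rownames(m))),
            class = "ProteinScores")
}

#' Threshold-calibration parameters
#' @param target_fdr target false discovery rate among annotation-bearing
#'   assignments (default 0.05).
#' @param min_annotated minimum annotated predictions a class needs before a
#'   finite threshold is calibrated (default 10).
#' @export
threshold_params <- function(target_fdr = 0.05, min_annotated = 10L) {
  stopifnot(target_fdr > 0, min_annotated >= 1)
  structure(list(target_fdr = target_fdr,
                 min_annotated = as.integer(min_annotated)),
            class = "ThresholdParams")
}

#' Calibrate per-class score thresholds to a target FDR
#'
#' For each class, the proteins predicted into it that carry a non-UNKNOWN
#' annotation are ranked by descending score; the estimated FDR at a cutoff
#' is the fraction of retained proteins whose annotation disagrees with the
#' predicted class. The threshold is the smallest observed score whose
#' cutoff attains `FDR <= target_fdr` (different compartments have different
#' score distributions, hence per-class thresholds). Classes with fewer than
#' `min_annotated` annotated predictions — or no admissible cutoff — get an
#' infinite threshold (nothing auto-assigned) with a warning. A
#' `target_fdr >= 1` disables gating (threshold 0 everywhere).
#'
#' @param scores a `ProteinScores` object.
#' @param annotation `AnnotationTable` (values in the class vocabulary or
#'   `"UNKNOWN"`).
#' @param params a [threshold_params()] object.
#' @return named numeric vector, one threshold per class.
#' @export
calibrate_thresholds <- function(scores, annotation,
                                 params = threshold_params()) {
  stopifnot(inherits(scores, "ProteinScores"))
  classes <- colnames(scores$probabilities)
  ann <- annotation[names(annotation) %in% names(scores$svm_class)]
  ann <- ann[unclass(ann) != UNKNOWN_LABEL]
  if (length(ann) == 0)
    stop("no scored protein carries a usable annotation; cannot calibrate")
  thr <- stats::setNames(rep(Inf, length(classes)), classes)
  if (params$target_fdr >= 1)
    return(stats::setNames(rep(0, length(classes)), classes))
  for (cl in classes) {
    ids <- names(scores$svm_class)[scores$svm_class == cl]
    ids <- ids[ids %in% names(ann)]
    if (length(ids) < params$min_annotated) {
      warning("class '", cl, "': only ", length(ids),
              " annotated prediction(s); threshold set to +Inf")
      next
    }
    sc <- sort(scores$svm_score[ids], decreasing = TRUE)
    discordant <- unclass(ann)[names(sc)] != cl
    fdr <- cumsum(discordant) / seq_along(sc)
    # a cutoff is only realizable at a tie-block boundary: "score >= t"
    # always retains every protein tied at t
    boundary <- c(sc[-length(sc)] > sc[-1], TRUE)
    eligible <- which(fdr <= params$target_fdr & boundary)
    if (length(eligible) == 0) {
      warning("class '", cl, "': no cutoff attains the target FDR; ",
              "threshold set to +Inf")
      next
    }
    thr[cl] <- sc[max(eligible)]
  }
  thr
}

#' Final threshold-gated class assignment
#'
#' A protein receives its argmax SVM class when its score reaches that
#' class's calibrated threshold, and `UNASSIGNED` otherwise. Marker proteins
#' pass through with their curated label and score 1.
#'
#' @param scores a `ProteinScores` object.
#' @param thresholds named numeric vector covering every class.
#' @param markers optional `MarkerSet` passed through unchanged.
#' @return a `ClassificationResult` data.frame with columns `protein_id`,
#'   `svm_class`, `svm_score`, `final_label`.
#' @export
assign_classes <- function(scores, thresholds, markers = NULL) {
  stopifnot(inherits(scores, "ProteinScores"))
  classes <- colnames(scores$probabilities)
  miss <- setdiff(classes, names(thresholds))
  if (length(miss))
    stop("thresholds missing for class(es): ", paste(miss, collapse = ", "))
  ids <- names(scores$svm_class)
  final <- ifelse(scores$svm_score >= thresholds[scores$svm_class],
                  scores$svm_class, "UNASSIGNED")
  out <- data.frame(protein_id = ids,
                    svm_class = unname(scores$svm_class),
                    svm_score = unname(scores$svm_score),
                    final_label = unname(final),
                    stringsAsFactors = FALSE)
  if (!is.null(markers)) {
    # curated labels always win over (re-)scored marker rows
    out <- out[!(out$protein_id %in% names(markers)), , drop = FALSE]
    mk <- data.frame(protein_id = names(markers),
                     svm_class = unname(unclass(markers)),
                     svm_score = 1,
                     final_label = unname(unclass(markers)),
                     stringsAsFactors = FALSE)
    out <- rbind(out, mk)
  }
  rownames(out) <- NULL
  structure(out, class = c("ClassificationResult", "data.frame"))
}
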
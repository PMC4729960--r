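#' Principal component projection of a profile matrix
#'
#' Column-mean-centered PCA without unit-variance scaling (profiles already
#' share the sum-to-one scale, so scaling would only inflate low-signal
#' channels). Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param m `ProfileMatrix` with at least `k + 1` rows.
#' @param k number of components to keep (default 2).
#' @return a `Projection` list: `coordinates` (rows x k scores),
#'   `explained_variance` (per retained component), `total_variance`,
#'   `loadings` (channels x k), `center`, `all_variances` (every
#'   component's variance, for scree/rank diagnostics).
#' @export
project_pca <- function(m, k = 2L) {
  stopifnot(inherits(m, "ProfileMatrix"))
  if (nrow(m) < k + 1)
    stop("PCA needs at least k + 1 rows")
  X <- unclass(m)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  rank <- sum(vars > max(vars) * 1e-12)
  if (k > rank)
    stop("requested k = ", k, " components but the centered matrix has rank ",
         rank)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, "*")
  colnames(coords) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 explained_variance = vars[seq_len(k)],
                 total_variance = sum(vars),
                 loadings = loadings,
                 center = pc$center,
                 all_variances = vars),
            class = "Projection")
}

#' @export
print.Projection <- function(x, ...) {
  cat(sprintf("Projection: %d rows, %d components (%.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$explained_variance) / x$total_variance))
  invisible(x)
}

#' Write projection coordinates as TSV
#' @export
write_projection <- function(proj, path) {
  df <- data.frame(protein_id = rownames(proj$coordinates),
                   proj$coordinates, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a subcellular map from a PCA projection
#'
#' Classified proteins are drawn as coloured points on the chosen component
#' pair, unassigned proteins as a grey background layer, and each overlay
#' protein set (a complex, an interactome, an isoform pair, ...) on top with
#' a distinct shape. Overlay proteins absent from the projection are listed
#' in a warning, never fatal.
#'
#' @param proj a [project_pca()] result covering the result's proteins.
#' @param result optional `ClassificationResult`; colours come from
#'   `final_label`.
#' @param overlays named list of protein-id vectors.
#' @param components which component pair to draw (default `c(1, 2)`).
#' @param file optional output path (`.png`, `.pdf` or `.svg`); rendering is
#'   deterministic.
#' @return the ggplot object, invisibly.
#' @export
render_map <- function(proj, result = NULL, overlays = list(),
                       components = c(1L, 2L), file = NULL) {
  stopifnot(inherits(proj, "Projection"))
  k <- ncol(proj$coordinates)
  if (any(components > k))
    stop("projection holds only ", k, " components")
  ids <- rownames(proj$coordinates)
  df <- data.frame(protein_id = ids,
                   x = proj$coordinates[, components[1]],
                   y = proj$coordinates[, components[2]],
                   label = "UNASSIGNED",
                   stringsAsFactors = FALSE)
  if (!is.null(result)) {
    lab <- stats::setNames(result$final_label, result$protein_id)
    hit <- ids %in% names(lab)
    df$label[hit] <- lab[ids[hit]]
  }
  pct <- 100 * proj$explained_variance[components] / proj$total_variance
  axis_lab <- sprintf("PC%d (%.1f%%)", components, pct)
  bg <- df[df$label == "UNASSIGNED", , drop = FALSE]
  fg <- df[df$label != "UNASSIGNED", , drop = FALSE]
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = bg, colour = "grey80", size = 1) +
    ggplot2::geom_point(data = fg,
                        ggplot2::aes(colour = .data$label), size = 1.5) +
    ggplot2::labs(x = axis_lab[1], y = axis_lab[2], colour = "compartment",
                  shape = "overlay") +
    ggplot2::theme_bw()
  if (length(overlays)) {
    if (is.null(names(overlays)))
      names(overlays) <- paste0("set", seq_along(overlays))
    ov <- do.call(rbind, lapply(names(overlays), function(nm) {
      present <- overlays[[nm]] %in% ids
      if (any(!present))
        warning("overlay '", nm, "': ", sum(!present),
                " protein(s) absent from the projection: ",
                paste(overlays[[nm]][!present], collapse = ", "))
      if (!any(present)) return(NULL)
      data.frame(protein_id = overlays[[nm]][present], set = nm,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(ov) && nrow(ov)) {
      ov <- merge(ov, df[, c("protein_id", "x", "y")], by = "protein_id")
      p <- p + ggplot2::geom_point(
        data = ov, ggplot2::aes(shape = .data$set),
        size = 3, colour = "black", stroke = 1)
    }
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
  }
  invisible(p)
}
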
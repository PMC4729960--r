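#' Construct a marker set
#'
#' Curated protein -> compartment assignments used as training labels. Each
#' protein belongs to exactly one class; the ordered set of class labels is
#' the classification vocabulary (the class count is always taken from the
#' marker file, never hard-coded).
#'
#' @param labels named character vector: `names` are protein ids, values are
#'   class labels.
#' @return a `MarkerSet` (named character vector).
#' @export
marker_set <- function(labels) {
  labels <- unlist(labels)
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("marker set entries must be named by protein id")
  if (anyDuplicated(names(labels))) {
    dup <- unique(names(labels)[duplicated(names(labels))])
    conflicting <- vapply(dup, function(p)
      length(unique(labels[names(labels) == p])) > 1L, logical(1))
    if (any(conflicting))
      stop("protein(s) listed under conflicting classes: ",
           paste(dup[conflicting], collapse = ", "))
    labels <- labels[!duplicated(names(labels))]
  }
  labels <- vapply(labels, as.character, character(1))
  if (any(is.na(labels) | labels == ""))
    stop("marker set contains empty class labels")
  structure(labels, class = "MarkerSet")
}

#' @export
marker_classes <- function(markers) unique(unname(unclass(markers)))

#' @export
print.MarkerSet <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = marker_classes(x)))
  cat(sprintf("MarkerSet: %d proteins in %d classes\n", length(x), length(tab)))
  print(tab)
  invisible(x)
}

#' @export
`[.MarkerSet` <- function(x, i, ...) {
  out <- NextMethod()
  structure(out, class = "MarkerSet")
}

#' Load a marker file (protein_id <TAB> class)
#'
#' Extra columns are ignored with a warning; a protein listed under two
#' different classes is an error.
#' @param path two-column TSV with header.
#' @export
load_markers <- function(path) {
  if (!file.exists(path)) stop("no such marker file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  if (ncol(df) < 2) stop("marker file must have two columns (protein_id, class)")
  if (ncol(df) > 2)
    warning("marker file: ignoring extra column(s): ",
            paste(names(df)[-(1:2)], collapse = ", "))
  marker_set(stats::setNames(as.character(df[[2]]), as.character(df[[1]])))
}

#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "MarkerSet"))
  utils::write.table(
    data.frame(protein_id = names(markers), class = unclass(markers),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition a profile matrix into marker-labelled and unlabelled rows
#'
#' @param m a `ProfileMatrix`.
#' @param markers a `MarkerSet`.
#' @return list with components `labelled` (ProfileMatrix), `labels`
#'   (MarkerSet restricted to present rows, in row order), `unlabelled`
#'   (ProfileMatrix) and `absent_markers` (marker ids not found in `m`).
#' @export
attach_markers <- function(m, markers) {
  stopifnot(inherits(m, "ProfileMatrix"), inherits(markers, "MarkerSet"))
  present <- intersect(rownames(m), names(markers))
  if (length(present) == 0)
    stop("no marker protein occurs in the profile matrix; ",
         "classification is impossible")
  absent <- setdiff(names(markers), rownames(m))
  if (length(absent))
    warning(length(absent), " marker(s) absent from the matrix: ",
            paste(utils::head(absent, 10L), collapse = ", "))
  keep <- rownames(m) %in% present
  list(labelled   = m[keep, , drop = FALSE],
       labels     = markers[rownames(m)[keep]],
       unlabelled = m[!keep, , drop = FALSE],
       absent_markers = absent)
}

#' @export
UNKNOWN_LABEL <- "UNKNOWN"

#' Load an annotation table used for threshold calibration
#'
#' Independent protein -> compartment annotation (e.g., a curated mapping of
#' gene-ontology terms onto the class vocabulary). Labels outside the
#' vocabulary lack the specificity to calibrate against and are mapped to
#' `UNKNOWN` with a message.
#'
#' @param path two-column TSV (protein_id, annotation).
#' @param vocabulary character vector of admissible class labels.
#' @return named character vector (`AnnotationTable`), values in
#'   `vocabulary` or `"UNKNOWN"`.
#' @export
load_annotation <- function(path, vocabulary) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "",
                      check.names = FALSE),
    error = function(e) data.frame(protein_id = character(0),
                                   annotation = character(0)))
  if (nrow(df) == 0) {
    warning("annotation file is empty")
    return(structure(character(0), class = "AnnotationTable"))
  }
  if (ncol(df) < 2) stop("annotation file must have two columns")
  ann <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  out_of_vocab <- !(ann %in% vocabulary)
  if (any(out_of_vocab)) {
    message(sum(out_of_vocab),
            " annotation label(s) outside the class vocabulary mapped to UNKNOWN")
    ann[out_of_vocab] <- UNKNOWN_LABEL
  }
  structure(ann, class = "AnnotationTable")
}

#' @export
annotation_table <- function(labels, vocabulary) {
  labels <- stats::setNames(as.character(labels), names(labels))
  labels[!(labels %in% vocabulary)] <- UNKNOWN_LABEL
  structure(labels, class = "AnnotationTable")
}
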
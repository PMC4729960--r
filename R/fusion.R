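#' Fuse replicate experiments into a higher-plex profile matrix
#'
#' The intersection of the replicates' protein groups is kept (in
#' first-input row order) and the channel blocks are concatenated, so two
#' 10-plex replicates become one 20-plex matrix. Each block keeps its own
#' row normalization — a fused row sums to the number of replicates — which
#' preserves every experiment's within-gradient distribution.
#'
#' @param ms list of two or more normalized `ProfileMatrix` objects.
#' @param prefixes replicate identifiers used to disambiguate channel names
#'   (default `exp1`, `exp2`, ...); emitted as `exp1.TMT126`, ...
#' @return a fused `ProfileMatrix` (`normalized = FALSE`; attribute
#'   `"blocks"` maps each replicate to its column indices, attribute
#'   `"provenance"` records the replicate identifiers).
#' @export
fuse_replicates <- function(ms, prefixes = NULL) {
  if (!is.list(ms) || length(ms) < 2)
    stop("fusion needs a list of at least two profile matrices")
  for (m in ms) {
    if (!inherits(m, "ProfileMatrix")) stop("inputs must be ProfileMatrix objects")
    if (!is_normalized(m)) stop("all replicates must be row-normalized before fusion")
  }
  if (is.null(prefixes)) prefixes <- paste0("exp", seq_along(ms))
  if (length(prefixes) != length(ms) || anyDuplicated(prefixes))
    stop("prefixes must be unique, one per replicate")
  common <- Reduce(intersect, lapply(ms, rownames))
  if (length(common) == 0)
    stop("replicates share no protein groups; fusion impossible")
  common <- rownames(ms[[1]])[rownames(ms[[1]]) %in% common]
  blocks <- list()
  off <- 0L
  parts <- vector("list", length(ms))
  for (i in seq_along(ms)) {
    b <- unclass(ms[[i]])[common, , drop = FALSE]
    colnames(b) <- paste(prefixes[i], colnames(b), sep = ".")
    parts[[i]] <- b
    blocks[[prefixes[i]]] <- off + seq_len(ncol(b))
    off <- off + ncol(b)
  }
  fused <- profile_matrix(do.call(cbind, parts), normalized = FALSE)
  attr(fused, "blocks") <- blocks
  attr(fused, "provenance") <- prefixes
  fused
}

#' @export
fused_blocks <- function(m) attr(m, "blocks")
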
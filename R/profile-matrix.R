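#' Construct a profile matrix
#'
#' A `ProfileMatrix` is the central container of the package: a numeric
#' matrix with one row per protein group (or PSM) and one column per
#' labelled reporter channel. Values are non-negative relative abundances;
#' after [normalize_sum_to_one()] every row sums to one and the matrix
#' carries `normalized = TRUE`.
#'
#' @param values numeric matrix with unique rownames (protein/PSM ids) and
#'   unique colnames (channel labels); all entries finite and `>= 0`.
#' @param normalized logical flag; if `TRUE`, every row must sum to 1
#'   within `1e-9`.
#' @return a `ProfileMatrix` (a classed numeric matrix).
#' @export
profile_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("profile matrix rows must carry unique identifiers")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("profile matrix columns must carry unique channel names")
  if (anyNA(values))
    stop("profile matrix must not contain missing entries (zero-fill first)")
  if (any(values < 0))
    stop("profile matrix entries must be non-negative")
  if (normalized && nrow(values) > 0 &&
      any(abs(rowSums(values) - 1) > 1e-9))
    stop("matrix flagged normalized but some row sums differ from 1")
  structure(values, normalized = isTRUE(normalized),
            class = c("ProfileMatrix", class(values)))
}

#' @export
is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' @export
channel_names <- function(m) colnames(m)

#' @export
row_ids <- function(m) rownames(m)

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf("ProfileMatrix: %d rows x %d channels%s\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) " (row-normalized)" else ""))
  if (!is.null(attr(x, "blocks")))
    cat(sprintf("  fused blocks: %s\n",
                paste(names(attr(x, "blocks")), collapse = ", ")))
  if (nrow(x) > 0)
    print(utils::head(unclass(x), 4L))
  invisible(x)
}

# subsetting follows matrix semantics; when the result is still a matrix it
# keeps the class, and the normalized flag survives row subsets (row sums
# are untouched) but not column subsets
#' @export
`[.ProfileMatrix` <- function(x, i, j, ..., drop) {
  blocks <- attr(x, "blocks")
  out <- NextMethod()
  if (is.matrix(out)) {
    keep_cols <- missing(j) || identical(ncol(out), ncol(x))
    out <- structure(out, normalized = is_normalized(x) && keep_cols,
                     class = c("ProfileMatrix", "matrix", "array"))
    if (!is.null(blocks) && keep_cols) attr(out, "blocks") <- blocks
  }
  out
}

# deterministic sub-seed derivation: every stochastic entry point reseeds
# from (user seed, stream name) so stages are reproducible independently
.derive_seed <- function(seed, stream) {
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u)) %% 65521
  v <- ((as.numeric(seed) %% 2147483647) * 48271 + h * 7919) %% 2147483646
  as.integer(v) + 1L
}
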
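#' Default TMT 10-plex reporter channel names
#' @export
tmt10_channels <- function() {
  c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
    "TMT129N", "TMT129C", "TMT130N", "TMT130C", "TMT131")
}

#' Construct a PSM-level reporter table
#'
#' One row per peptide-spectrum match (PSM), with the reporter-ion intensity
#' observed in each labelled channel. Missing reporter values are `NA`, never
#' zero: zero-filling is a deliberate downstream step ([filter_missing()]).
#'
#' @param df data.frame with columns `psm_id`, `protein_group` and one column
#'   per channel (numeric, `NA` = missing).
#' @param channels ordered channel column names.
#' @return a `PsmTable` (a classed data.frame).
#' @export
psm_table <- function(df, channels = tmt10_channels()) {
  stopifnot(is.data.frame(df))
  need <- c("psm_id", "protein_group", channels)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PSM table lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(channels)) stop("channel names must be unique")
  df <- df[, need, drop = FALSE]
  df$psm_id <- as.character(df$psm_id)
  df$protein_group <- as.character(df$protein_group)
  for (ch in channels) df[[ch]] <- as.numeric(df[[ch]])
  vals <- as.matrix(df[, channels, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE))
    stop("reporter intensities must be non-negative")
  structure(df, channels = channels,
            class = c("PsmTable", "data.frame"))
}

#' @export
psm_channels <- function(psms) attr(psms, "channels")

#' Read a PSM-level reporter table from TSV/CSV
#'
#' Empty cells (and any string in `na_strings`) are read as missing, never as
#' zero. Rows carrying a negative intensity are rejected with a warning.
#'
#' @param path input file.
#' @param sep field delimiter (default tab).
#' @param channels reporter column names expected in the header.
#' @param id_col,group_col names of the PSM-identifier and protein-group
#'   columns in the file; they are mapped onto `psm_id` / `protein_group`.
#' @param na_strings strings treated as missing on read.
#' @return [psm_table()] object.
#' @export
read_psm_table <- function(path, sep = "\t", channels = tmt10_channels(),
                           id_col = "psm_id", group_col = "protein_group",
                           na_strings = c("", "NA")) {
  if (!file.exists(path)) stop("cannot read PSM table: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = na_strings, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  for (col in c(id_col, group_col))
    if (!col %in% names(df))
      stop("PSM file lacks required column '", col, "'")
  miss <- setdiff(channels, names(df))
  if (length(miss))
    stop("PSM file lacks reporter column(s): ", paste(miss, collapse = ", "))
  names(df)[names(df) == id_col] <- "psm_id"
  names(df)[names(df) == group_col] <- "protein_group"
  vals <- as.matrix(df[, channels, drop = FALSE])
  bad <- apply(vals < 0, 1L, any)
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    warning(sum(bad), " PSM row(s) with negative intensity rejected")
    df <- df[!bad, , drop = FALSE]
  }
  psm_table(df, channels = channels)
}

#' Apply the missing-reporter exclusion rule
#'
#' PSMs with more than `max_missing` missing reporter values are excluded
#' from quantification; the missing values of the surviving PSMs are set to
#' zero. The counts of removed and retained PSMs are reported via `message()`
#' and attached as the `"filter_counts"` attribute.
#'
#' @param psms a `PsmTable`.
#' @param max_missing maximum number of missing channels tolerated per PSM
#'   (default 4 of 10).
#' @return filtered, zero-filled `PsmTable`.
#' @export
filter_missing <- function(psms, max_missing = 4L) {
  stopifnot(inherits(psms, "PsmTable"))
  channels <- psm_channels(psms)
  if (max_missing < 0 || max_missing > length(channels))
    stop("max_missing must lie in [0, ", length(channels), "]")
  n_missing <- rowSums(is.na(as.matrix(psms[, channels, drop = FALSE])))
  keep <- n_missing <= max_missing
  out <- psms[keep, , drop = FALSE]
  for (ch in channels) out[[ch]][is.na(out[[ch]])] <- 0
  message(sprintf("filter_missing: removed %d, retained %d PSM(s)",
                  sum(!keep), sum(keep)))
  out <- psm_table(as.data.frame(out), channels = channels)
  attr(out, "filter_counts") <- c(removed = sum(!keep), retained = sum(keep))
  out
}

#' Aggregate PSMs to protein groups by the channel-wise median
#'
#' Each protein group's profile is the per-channel median over all of its
#' quantifiable PSMs (even counts: mean of the central pair, the standard
#' sample median). The result is independent of the input PSM order; rows
#' are emitted in sorted protein-group order.
#'
#' @param psms a missing-filtered `PsmTable` (no `NA` entries).
#' @return an unnormalized [profile_matrix()], one row per protein group.
#' @export
aggregate_psms_to_proteins <- function(psms) {
  stopifnot(inherits(psms, "PsmTable"))
  channels <- psm_channels(psms)
  vals <- as.matrix(psms[, channels, drop = FALSE])
  if (anyNA(vals))
    stop("PSM table still contains missing values; run filter_missing() first")
  if (nrow(vals) == 0) {
    m <- matrix(numeric(0), 0, length(channels),
                dimnames = list(character(0), channels))
    return(profile_matrix(m))
  }
  groups <- sort(unique(psms$protein_group))
  idx <- split(seq_len(nrow(vals)), psms$protein_group)[groups]
  med <- t(vapply(idx, function(i)
    apply(vals[i, , drop = FALSE], 2L, stats::median),
    numeric(length(channels))))
  dimnames(med) <- list(groups, channels)
  profile_matrix(med)
}

#' Row-normalize a profile matrix to relative abundances
#'
#' Divides each row by its sum so the reporter values of every protein (or
#' PSM) sum to one. Rows whose sum is zero carry no profile information and
#' are dropped with a warning.
#'
#' @param m a `ProfileMatrix` with non-negative entries.
#' @return normalized `ProfileMatrix` (idempotent).
#' @export
normalize_sum_to_one <- function(m) {
  stopifnot(inherits(m, "ProfileMatrix"))
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) dropped during normalization: ",
            paste(utils::head(rownames(m)[zero], 5L), collapse = ", "))
    m <- m[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  profile_matrix(unclass(m) / rs, normalized = TRUE)
}

#' Write a profile matrix as TSV
#'
#' First column `protein_id`, then one column per channel in declared order.
#' Round-trips losslessly through [read_profile_matrix()].
#' @param m a `ProfileMatrix`.
#' @param path output file.
#' @export
write_profile_matrix <- function(m, path) {
  stopifnot(inherits(m, "ProfileMatrix"))
  ids <- rownames(m)
  if (is.null(ids)) ids <- character(0)
  df <- data.frame(protein_id = ids, unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#'
#' @param path TSV with a `protein_id` column followed by channel columns.
#' @param normalized `NULL` to auto-detect (all row sums within `1e-9` of 1),
#'   or an explicit logical.
#' @export
read_profile_matrix <- function(path, normalized = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!"protein_id" %in% names(df))
    stop("profile file lacks 'protein_id' column")
  vals <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  rownames(vals) <- df$protein_id
  if (is.null(normalized))
    normalized <- nrow(vals) > 0 && all(abs(rowSums(vals) - 1) <= 1e-9)
  profile_matrix(vals, normalized = normalized)
}
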
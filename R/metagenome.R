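# Metagenome prediction: combine ASV abundances, predicted 16S copy
# numbers and predicted gene content into per-sample function abundances,
# with abundance-weighted NSTIs summarising reference coverage.

#' @noRd
check_feature_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    .fail("feature table must be a numeric matrix (ASVs x samples)")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    .fail("feature table requires ASV row names and sample column names")
  if (anyDuplicated(rownames(table)))
    .fail("duplicate ASV id in feature table: %s",
          rownames(table)[duplicated(rownames(table))][1L])
  if (anyDuplicated(colnames(table)))
    .fail("duplicate sample id in feature table")
  if (anyNA(table) || any(table < 0))
    .fail("feature table contains negative or missing counts")
  invisible(table)
}

#' Divide ASV counts by predicted 16S copy number
#'
#' Converts observed 16S amplicon counts into (relative) organism
#' abundances: an organism with c 16S copies contributes c reads per
#' cell, so its counts are divided by c before gene content is applied.
#'
#' @param table numeric matrix, ASVs x samples, non-negative.
#' @param copies named numeric vector of per-ASV predicted 16S copy
#'   numbers (all >= 1); must cover every ASV in `table`.
#' @return matrix of the same shape with `table[i, ] / copies[i]`.
#' @export
normalize_by_copy_number <- function(table, copies) {
  check_feature_table(table)
  miss <- setdiff(rownames(table), names(copies))
  if (length(miss))
    .fail("no 16S copy number for ASV(s): %s", paste(miss, collapse = ", "))
  cp <- copies[rownames(table)]
  if (anyNA(cp) || any(cp < 1))
    .fail("16S copy numbers must be >= 1 and non-missing")
  table / cp
}

#' Predict a metagenome from normalised abundances and gene content
#'
#' `value(s, f) = sum_i normalized(i, s) * traits(i, f)`: each ASV
#' contributes its predicted per-genome gene copy numbers scaled by its
#' copy-number-normalised abundance.
#'
#' @param normalized ASV x sample matrix (see
#'   [normalize_by_copy_number()]).
#' @param traits ASV x function matrix of predicted copy numbers (a
#'   [trait_table()] or plain matrix) covering every ASV.
#' @param stratified if `TRUE`, also return the per-ASV contributions as
#'   a 3-way list (off by default; memory-heavy).
#' @return a `metagenome` object: `$values` (function x sample matrix,
#'   functions sorted lexicographically), `$sample_ids`, `$function_ids`,
#'   and `$strat` when requested.
#' @export
predict_metagenome <- function(normalized, traits, stratified = FALSE) {
  check_feature_table(normalized)
  tm <- unclass(traits)
  miss <- setdiff(rownames(normalized), rownames(tm))
  if (length(miss))
    .fail("no predicted traits for ASV(s): %s", paste(miss, collapse = ", "))
  tm <- tm[rownames(normalized), , drop = FALSE]
  vals <- crossprod(tm, normalized)           # functions x samples
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  out <- list(values = vals,
              sample_ids = colnames(vals),
              function_ids = rownames(vals))
  if (stratified)
    out$strat <- lapply(setNames(nm = rownames(normalized)), function(a)
      outer(tm[a, ], normalized[a, ]))
  structure(out, class = "metagenome")
}

#' @export
print.metagenome <- function(x, ...) {
  cat(sprintf("<metagenome> %d functions x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-sample abundance-weighted NSTI
#'
#' `sum_i counts(i, s) * nsti(i) / sum_i counts(i, s)` per sample, using
#' raw (un-normalised) counts. A sample with zero total count gets `NA`
#' with a warning. The result always lies within the range of the
#' contributing per-ASV NSTIs.
#'
#' @param table ASV x sample count matrix.
#' @param nsti named per-ASV NSTI vector covering every ASV in `table`.
#' @return named numeric vector, one value per sample.
#' @export
weighted_nsti <- function(table, nsti) {
  check_feature_table(table)
  miss <- setdiff(rownames(table), names(nsti))
  if (length(miss))
    .fail("no NSTI for ASV(s): %s", paste(miss, collapse = ", "))
  v <- nsti[rownames(table)]
  if (anyNA(v)) .fail("NSTI must be defined for every retained ASV")
  tot <- colSums(table)
  out <- colSums(table * v) / tot
  if (any(tot == 0)) {
    .warnf("%d sample(s) have zero total count; weighted NSTI undefined",
           sum(tot == 0))
    out[tot == 0] <- NA_real_
  }
  out
}

#' Drop ASVs whose NSTI exceeds a cutoff
#'
#' The conventional guard against wildly extrapolated predictions:
#' queries farther than `max_nsti` substitutions/site from any reference
#' genome are excluded (default downstream convention is 2.0). Samples
#' that lose every ASV are retained as all-zero columns with a warning.
#'
#' @param table ASV x sample count matrix.
#' @param nsti named per-ASV NSTI vector.
#' @param max_nsti positive cutoff; `Inf` disables the filter.
#' @return the filtered matrix with attribute `excluded` (data.frame of
#'   `asv_id`, `nsti` for the removed ASVs).
#' @export
apply_nsti_cutoff <- function(table, nsti, max_nsti = 2.0) {
  check_feature_table(table)
  if (!is.numeric(max_nsti) || max_nsti <= 0)
    .fail("max_nsti must be > 0")
  v <- nsti[rownames(table)]
  drop <- !is.na(v) & v > max_nsti
  drop[is.na(v)] <- TRUE          # no NSTI at all -> excluded
  out <- table[!drop, , drop = FALSE]
  emptied <- colSums(out) == 0 & colSums(table) > 0
  if (any(emptied))
    .warnf("%d sample(s) lost every ASV at max_nsti = %g",
           sum(emptied), max_nsti)
  attr(out, "excluded") <- data.frame(
    asv_id = rownames(table)[drop],
    nsti = unname(v[drop]), stringsAsFactors = FALSE)
  out
}
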
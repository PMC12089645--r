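# Mock-community benchmarking: match community taxa to held-out genomes,
# build gold-standard functional profiles from their true annotations,
# and score predictions with Spearman correlation and Bray-Curtis
# dissimilarity per sample.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

# Split "d__X;p__Y;..." taxonomy strings into a rank matrix; empty rank
# labels (e.g. "s__") count as absent.
#' @noRd
parse_taxonomy <- function(tax) {
  parts <- strsplit(tax, ";", fixed = TRUE)
  m <- matrix(NA_character_, length(tax), length(.RANKS),
              dimnames = list(tax, .RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-z]__", "", p)
    p[p == ""] <- NA_character_
    m[i, seq_len(min(length(p), length(.RANKS)))] <-
      p[seq_len(min(length(p), length(.RANKS)))]
  }
  m
}

#' Match community taxa to a held-out genome pool
#'
#' Maps each taxon of an observed community profile to a genome from a
#' pool of held-out genomes (genomes deliberately absent from the
#' reference database), matching at the deepest taxonomic rank shared by
#' the taxon and any pool genome. Ties at the deepest rank go to the
#' lexicographically smallest genome id. Unmatched taxa are dropped and
#' the retained fraction of total abundance is reported.
#'
#' @param profile taxon x sample abundance matrix; row names are
#'   semicolon-separated taxonomy strings (`d__...;p__...;...`).
#' @param pool data.frame with columns `genome_id` and `taxonomy`
#'   (same string format).
#' @param min_retained minimum tolerated retained abundance fraction.
#' @param on_low `"warn"` (default) or `"error"` when the retained
#'   fraction falls below `min_retained`.
#' @return a `mock_community` skeleton: `genome_ids`, `abundances`
#'   (genome x sample; taxa mapping to the same genome are summed),
#'   `mapping` (taxon, genome_id, matched_rank), `retained_fraction`,
#'   `dropped` taxa.
#' @export
match_taxa_to_heldout <- function(profile, pool, min_retained = 0.5,
                                  on_low = c("warn", "error")) {
  on_low <- match.arg(on_low)
  stopifnot(is.matrix(profile), is.data.frame(pool))
  if (!all(c("genome_id", "taxonomy") %in% names(pool)))
    .fail("pool needs columns genome_id and taxonomy")
  ptax <- parse_taxonomy(rownames(profile))
  gtax <- parse_taxonomy(pool$taxonomy)
  map <- data.frame(taxon = rownames(profile),
                    genome_id = NA_character_,
                    matched_rank = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ptax))) {
    for (r in rev(seq_along(.RANKS))) {
      if (is.na(ptax[i, r])) next
      hit <- rep(TRUE, nrow(gtax))
      for (k in seq_len(r))
        hit <- hit & !is.na(gtax[, k]) & gtax[, k] == ptax[i, k]
      if (any(hit)) {
        map$genome_id[i] <- sort(pool$genome_id[hit])[1L]
        map$matched_rank[i] <- .RANKS[r]
        break
      }
    }
  }
  matched <- !is.na(map$genome_id)
  retained <- sum(profile[matched, , drop = FALSE]) / sum(profile)
  if (retained < min_retained) {
    msg <- sprintf("only %.1f%% of abundance matchable to the held-out pool",
                   100 * retained)
    if (on_low == "error") .fail(msg) else .warnf(msg)
  }
  ab <- profile[matched, , drop = FALSE]
  gid <- map$genome_id[matched]
  abundances <- rowsum(ab, gid)        # sums taxa that share a genome
  structure(list(genome_ids = rownames(abundances),
                 abundances = abundances,
                 mapping = map,
                 retained_fraction = retained,
                 dropped = map$taxon[!matched]),
            class = "mock_community")
}

#' Build the gold-standard functional profile of a mock community
#'
#' `gold(f, s) = sum_g annotation(g, f) * abundance(g, s) /
#' ssu_copies(g)` -- the same copy-number weighting the predictor
#' applies, but with the genomes' true annotations and true 16S copy
#' numbers. Set `normalize = FALSE` to skip the 16S division.
#'
#' @param mock a `mock_community` (or any list with `genome_ids` and
#'   `abundances`).
#' @param annotations genome [trait_table()] covering all mock genomes.
#' @param ssu_copies named per-genome true 16S copy numbers.
#' @param normalize divide abundances by `ssu_copies` (default `TRUE`).
#' @return the `mock_community` with `$gold_standard` set (function x
#'   sample matrix, functions sorted lexicographically).
#' @export
build_gold_standard <- function(mock, annotations, ssu_copies,
                                normalize = TRUE) {
  ids <- mock$genome_ids
  ann <- unclass(annotations)
  miss <- setdiff(ids, rownames(ann))
  if (length(miss))
    .fail("annotations missing for mock genome(s): %s",
          paste(miss, collapse = ", "))
  if (normalize) {
    cp <- ssu_copies[ids]
    if (anyNA(cp)) .fail("16S copy number missing for a mock genome")
  } else cp <- rep(1, length(ids))
  ab <- mock$abundances[ids, , drop = FALSE] / cp
  gold <- crossprod(ann[ids, , drop = FALSE], ab)
  mock$gold_standard <- gold[order(rownames(gold)), , drop = FALSE]
  mock
}

#' Spearman rank correlation between predicted and gold profiles
#'
#' Average ranks for ties. Zero-variance input yields `NA` with a
#' warning.
#'
#' @param pred,gold numeric vectors over the same function ids.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_per_sample <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  if (stats::sd(pred) == 0 || stats::sd(gold) == 0) {
    .warnf("zero-variance profile; Spearman undefined")
    return(NA_real_)
  }
  cor(pred, gold, method = "spearman")
}

#' Bray-Curtis dissimilarity between predicted and gold profiles
#'
#' `sum(|p - g|) / sum(p + g)` over the function vector; 0 for identical
#' profiles, 1 for disjoint supports. Two all-zero profiles yield `NA`
#' with a warning.
#'
#' @param pred,gold non-negative vectors over the same function ids.
#' @return dissimilarity in `[0, 1]`, or `NA`.
#' @export
bray_curtis_per_sample <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  if (any(pred < 0) || any(gold < 0)) .fail("profiles must be non-negative")
  tot <- sum(pred) + sum(gold)
  if (tot == 0) {
    .warnf("both profiles all-zero; Bray-Curtis undefined")
    return(NA_real_)
  }
  sum(abs(pred - gold)) / tot
}

# Align two function x sample matrices on the union of function ids,
# filling absent functions with zero (penalises false positives and
# false negatives symmetrically).
#' @noRd
align_profiles <- function(a, b) {
  fns <- sort(union(rownames(a), rownames(b)))
  pad <- function(m) {
    out <- matrix(0, length(fns), ncol(m), dimnames = list(fns, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  list(a = pad(a), b = pad(b))
}

#' Score a predicted metagenome against a gold standard
#'
#' Aligns the two profiles on the union of function ids (absent = 0) and
#' computes per-sample Spearman correlation and Bray-Curtis
#' dissimilarity.
#'
#' @param pred a `metagenome` (from [predict_metagenome()]) or a
#'   function x sample matrix.
#' @param gold function x sample gold-standard matrix (same samples).
#' @param wnsti optional named per-sample weighted NSTI to carry along.
#' @param dataset optional dataset label.
#' @return an `evaluation` data.frame: `sample`, `spearman_rho`,
#'   `bray_curtis`, `weighted_nsti`, `dataset`.
#' @export
evaluate_predictions <- function(pred, gold, wnsti = NULL,
                                 dataset = NA_character_) {
  pv <- if (inherits(pred, "metagenome")) pred$values else pred
  if (!setequal(colnames(pv), colnames(gold)))
    .fail("prediction and gold standard have different samples")
  gold <- gold[, colnames(pv), drop = FALSE]
  al <- align_profiles(pv, gold)
  samples <- colnames(pv)
  rho <- bc <- numeric(length(samples))
  for (i in seq_along(samples)) {
    rho[i] <- spearman_per_sample(al$a[, i], al$b[, i])
    bc[i] <- bray_curtis_per_sample(al$a[, i], al$b[, i])
  }
  out <- data.frame(sample = samples, spearman_rho = rho,
                    bray_curtis = bc,
                    weighted_nsti = if (is.null(wnsti)) NA_real_
                                    else unname(wnsti[samples]),
                    dataset = dataset, stringsAsFactors = FALSE)
  class(out) <- c("evaluation", "data.frame")
  out
}

# Paired t-test that tolerates exactly-identical pairs: zero spread and
# zero mean difference is "no evidence of difference" (p = 1).
#' @noRd
paired_p <- function(a, b) {
  d <- a - b
  d <- d[!is.na(d)]
  if (length(d) < 2L) return(NA_real_)
  if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Compare two evaluations of the same samples
#'
#' Per dataset and metric: medians and ranges for both evaluations, a
#' two-sided paired t-test, and a significance flag at P <= 0.05.
#'
#' @param eval_a,eval_b `evaluation` data.frames over identical samples.
#' @param labels length-2 character labels for the two evaluations.
#' @return data.frame with one row per dataset x metric: medians, ranges,
#'   `p_value`, `significant`.
#' @export
compare_databases <- function(eval_a, eval_b,
                              labels = c("a", "b")) {
  if (!setequal(eval_a$sample, eval_b$sample))
    .fail("sample sets differ: %s",
          paste(c(setdiff(eval_a$sample, eval_b$sample),
                  setdiff(eval_b$sample, eval_a$sample)), collapse = ", "))
  eval_b <- eval_b[match(eval_a$sample, eval_b$sample), ]
  metrics <- c("spearman_rho", "bray_curtis", "weighted_nsti")
  rows <- list()
  for (ds in unique(eval_a$dataset)) {
    sel <- eval_a$dataset %in% ds
    for (m in metrics) {
      a <- eval_a[[m]][sel]; b <- eval_b[[m]][sel]
      if (all(is.na(a)) || all(is.na(b))) next
      p <- paired_p(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, metric = m,
        median_a = median(a, na.rm = TRUE),
        median_b = median(b, na.rm = TRUE),
        min_a = min(a, na.rm = TRUE), max_a = max(a, na.rm = TRUE),
        min_b = min(b, na.rm = TRUE), max_b = max(b, na.rm = TRUE),
        p_value = p,
        significant = !is.na(p) && p <= 0.05,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}
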
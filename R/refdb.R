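#' Quality thresholds for reference-genome filtering
#'
#' Defaults reproduce the standard reference-database filter: at most 10%
#' contamination and at least 90% completeness (both boundaries inclusive,
#' i.e. a genome at exactly 10% contamination / 90% completeness is kept).
#' The 16S criteria (`min_ssu_length`, `max_ssu_ambiguous_frac`) are
#' explicit, configurable stand-ins for "high quality 16S rRNA gene":
#' a full-length-ish gene (>= 1200 nt) with at most 1% ambiguous bases.
#'
#' @param max_contamination maximum contamination percent (inclusive).
#' @param min_completeness minimum completeness percent (inclusive).
#' @param min_ssu_length minimum 16S sequence length in nucleotides.
#' @param max_ssu_ambiguous_frac maximum fraction of non-ACGT characters.
#' @return a `quality_thresholds` list.
#' @export
quality_thresholds <- function(max_contamination = 10,
                               min_completeness = 90,
                               min_ssu_length = 1200,
                               max_ssu_ambiguous_frac = 0.01) {
  for (v in c(max_contamination, min_completeness))
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 100)
      .fail("percent thresholds must lie in [0, 100]")
  if (max_ssu_ambiguous_frac < 0 || max_ssu_ambiguous_frac > 1)
    .fail("max_ssu_ambiguous_frac must lie in [0, 1]")
  if (min_ssu_length < 0) .fail("min_ssu_length must be >= 0")
  structure(list(max_contamination = max_contamination,
                 min_completeness = min_completeness,
                 min_ssu_length = min_ssu_length,
                 max_ssu_ambiguous_frac = max_ssu_ambiguous_frac),
            class = "quality_thresholds")
}

# IUPAC nucleotide codes (upper case; U tolerated for RNA-style input)
.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Validate a 16S rRNA gene sequence
#'
#' A sequence passes when it is present, at least `min_ssu_length`
#' nucleotides long, and its fraction of ambiguous (non-ACGT) characters
#' is at most `max_ssu_ambiguous_frac`. An absent sequence (`NA` or empty)
#' fails. Characters outside the IUPAC nucleotide alphabet are an error,
#' not a quiet failure.
#'
#' @param sequence a single nucleotide string, or `NA` for absent.
#' @param thresholds a [quality_thresholds()] object.
#' @return `TRUE` or `FALSE`.
#' @export
validate_ssu <- function(sequence, thresholds = quality_thresholds()) {
  if (length(sequence) != 1L) .fail("validate_ssu expects one sequence")
  if (is.na(sequence) || !nzchar(sequence)) return(FALSE)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .IUPAC)
  if (length(bad))
    .fail("sequence contains non-IUPAC characters: %s",
          paste(bad, collapse = ", "))
  if (length(chars) < thresholds$min_ssu_length) return(FALSE)
  ambig <- mean(!(chars %in% c("A", "C", "G", "T")))
  ambig <= thresholds$max_ssu_ambiguous_frac
}

.META_COLS <- c("genome_id", "domain", "completeness", "contamination",
                "is_representative", "in_domain_tree")

#' @noRd
check_genome_records <- function(records) {
  if (!is.data.frame(records))
    .fail("genome records must be a data.frame")
  missing <- setdiff(.META_COLS, names(records))
  if (length(missing))
    .fail("genome metadata is missing columns: %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(records$genome_id))
    .fail("duplicate genome_id in metadata")
  bad_dom <- setdiff(unique(records$domain), c("bacteria", "archaea"))
  if (length(bad_dom))
    .fail("unknown domain value(s): %s", paste(bad_dom, collapse = ", "))
  for (col in c("completeness", "contamination")) {
    v <- records[[col]]
    ok <- is.numeric(v) & !is.na(v) & v >= 0 & v <= 100
    if (!all(ok))
      .fail("malformed %s (must be a percent in [0,100]) for genome(s): %s",
            col, paste(records$genome_id[!ok], collapse = ", "))
  }
  invisible(records)
}

#' Filter genomes for reference-database inclusion
#'
#' Keeps exactly the genomes that are flagged as representative, are
#' present in their domain's phylogenetic tree, carry a 16S gene passing
#' [validate_ssu()], and have contamination `<= max_contamination` and
#' completeness `>= min_completeness` (boundaries inclusive). Input order
#' is preserved. Each rejected genome is assigned a single reason, checked
#' in the order: `not_representative`, `not_in_tree`, `low_quality_ssu`,
#' `contamination`, `completeness`.
#'
#' @param records data.frame with columns `genome_id`, `domain`,
#'   `completeness`, `contamination`, `is_representative`,
#'   `in_domain_tree`, and optionally `ssu` (the 16S sequence, `NA` if
#'   absent).
#' @param thresholds a [quality_thresholds()] object.
#' @return the surviving rows of `records`, with attributes `rejections`
#'   (data.frame of `genome_id`, `reason`) and `counts` (named integer
#'   vector: input, survivors, and one count per rejection reason).
#' @export
filter_genomes <- function(records, thresholds = quality_thresholds()) {
  check_genome_records(records)
  if (!"ssu" %in% names(records)) records$ssu <- NA_character_
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  ssu_ok <- vapply(records$ssu, validate_ssu, logical(1L),
                   thresholds = thresholds, USE.NAMES = FALSE)
  reason[is.na(reason) & !records$is_representative] <- "not_representative"
  reason[is.na(reason) & !records$in_domain_tree]    <- "not_in_tree"
  reason[is.na(reason) & !ssu_ok]                    <- "low_quality_ssu"
  reason[is.na(reason) &
           records$contamination > thresholds$max_contamination] <-
    "contamination"
  reason[is.na(reason) &
           records$completeness < thresholds$min_completeness] <-
    "completeness"
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  rej <- data.frame(genome_id = records$genome_id[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  reasons <- c("not_representative", "not_in_tree", "low_quality_ssu",
               "contamination", "completeness")
  counts <- c(input = n, survivors = sum(keep),
              setNames(as.integer(table(factor(rej$reason, reasons))),
                       reasons))
  attr(out, "rejections") <- rej
  attr(out, "counts") <- counts
  out
}

#' Build a per-domain reference database
#'
#' Filters the genome metadata with [filter_genomes()], prunes each
#' domain's tree to the surviving genomes (branch lengths of removed
#' unifurcations are merged additively, so pairwise distances between
#' surviving tips are unchanged), subsets the trait tables and 16S
#' sequences, and records the thresholds and per-stage counts in a
#' manifest.
#'
#' @param trees named list of `phylo` trees, one per domain
#'   (`bacteria`, `archaea`); branch lengths required. A single-domain
#'   database is allowed.
#' @param trait_tables named list of [trait_table()] objects covering all
#'   genomes of all domains; must include a `"16S"` framework.
#' @param ssu_sequences named character vector of 16S sequences keyed by
#'   genome id (used when `genomes` lacks an `ssu` column).
#' @param genomes genome metadata data.frame (see [filter_genomes()]).
#' @param thresholds a [quality_thresholds()] object.
#' @param version manifest version string.
#' @return a `ref_db` object: `$domains[[d]]` holds `tree`, `traits`
#'   (list of trait tables subset to that domain) and `ssu`;
#'   `$manifest` holds thresholds and filter-stage counts.
#' @export
build_reference <- function(trees, trait_tables, ssu_sequences, genomes,
                            thresholds = quality_thresholds(),
                            version = "0.1") {
  if (is.null(names(trees)) ||
      !all(names(trees) %in% c("bacteria", "archaea")))
    .fail("trees must be a named list with names in {bacteria, archaea}")
  if (!"16S" %in% names(trait_tables))
    .fail("trait_tables must include a '16S' framework")
  for (f in names(trait_tables))
    if (!inherits(trait_tables[[f]], "trait_table"))
      .fail("trait_tables[['%s']] is not a trait_table", f)
  if (!"ssu" %in% names(genomes)) {
    genomes$ssu <- unname(ssu_sequences[genomes$genome_id])
  }
  survivors <- filter_genomes(genomes, thresholds)
  counts <- attr(survivors, "counts")

  domains <- list()
  for (d in names(trees)) {
    tree <- trees[[d]]
    if (!inherits(tree, "phylo")) .fail("tree for %s is not 'phylo'", d)
    if (is.null(tree$edge.length))
      .fail("tree for %s has no branch lengths", d)
    if (any(tree$edge.length < 0))
      .fail("tree for %s has negative branch lengths", d)
    ids <- survivors$genome_id[survivors$domain == d]
    ids <- ids[ids %in% tree$tip.label]
    if (length(ids) < 2L)
      .fail("fewer than 2 surviving genomes for domain %s", d)
    pruned <- if (length(ids) == length(tree$tip.label)) tree
              else ape::keep.tip(tree, ids)
    traits <- lapply(trait_tables, subset_trait_table, ids = ids)
    ssu <- setNames(survivors$ssu[match(ids, survivors$genome_id)], ids)
    if (anyNA(ssu))
      .fail("surviving genome(s) with no 16S sequence in domain %s", d)
    domains[[d]] <- list(tree = pruned, traits = traits, ssu = ssu)
    counts[paste0("tips_", d)] <- length(ids)
  }
  structure(list(domains = domains,
                 manifest = list(version = version,
                                 thresholds = unclass(thresholds),
                                 counts = as.list(counts),
                                 frameworks = names(trait_tables))),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat("<ref_db>", paste(sprintf("%s: %d tips", names(x$domains),
      vapply(x$domains, function(d) length(d$tree$tip.label), 1L)),
      collapse = ", "),
      "| frameworks:", paste(x$manifest$frameworks, collapse = ", "), "\n")
  invisible(x)
}

#' Register an additional annotation framework in a reference database
#'
#' The table must cover every tree tip of at least one domain; it is
#' registered for each domain it fully covers. Re-registering an existing
#' framework id is an error (no silent overwrite).
#'
#' @param db a `ref_db`.
#' @param table a [trait_table()].
#' @return the updated `ref_db`.
#' @export
add_user_framework <- function(db, table) {
  stopifnot(inherits(db, "ref_db"), inherits(table, "trait_table"))
  fid <- framework_id(table)
  if (fid %in% db$manifest$frameworks)
    .fail("framework '%s' already registered; refusing to overwrite", fid)
  covered <- character(0)
  gaps <- list()
  for (d in names(db$domains)) {
    tips <- db$domains[[d]]$tree$tip.label
    miss <- setdiff(tips, rownames(table))
    if (length(miss) == 0L) covered <- c(covered, d)
    else gaps[[d]] <- miss
  }
  if (length(covered) == 0L)
    .fail("framework '%s' covers no domain completely; missing genomes: %s",
          fid, paste(unlist(gaps), collapse = ", "))
  for (d in covered)
    db$domains[[d]]$traits[[fid]] <-
      subset_trait_table(table, db$domains[[d]]$tree$tip.label)
  db$manifest$frameworks <- c(db$manifest$frameworks, fid)
  db
}
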
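#' Run the full prediction pipeline
#'
#' Places the query sequences into every domain tree, drops queries with
#' chosen NSTI above `max_nsti` (or unplaceable everywhere), divides ASV
#' counts by predicted 16S copy number, predicts gene content per
#' framework by hidden-state prediction, and assembles the predicted
#' metagenomes together with per-sample abundance-weighted NSTIs (from
#' the raw, un-normalised counts).
#'
#' @param db a `ref_db`.
#' @param seqs named character vector of query (ASV) sequences.
#' @param table ASV x sample count matrix; rows must be named like
#'   `seqs`.
#' @param frameworks framework ids to predict (default `"KO"`).
#' @param max_nsti NSTI cutoff for inclusion (default 2.0).
#' @param method HSP method passed to [predict_traits()].
#' @param stratified emit per-ASV contributions.
#' @return list: `placements`, `table` (post-cutoff), `copies`,
#'   `metagenomes` (one `metagenome` per framework), `weighted_nsti`,
#'   `excluded` (ASV exclusion report).
#' @export
run_prediction <- function(db, seqs, table, frameworks = "KO",
                           max_nsti = 2.0,
                           method = c("auto", "mp", "dw"),
                           stratified = FALSE) {
  method <- match.arg(method)
  check_feature_table(table)
  common <- intersect(rownames(table), names(seqs))
  if (!length(common)) .fail("no ASVs shared by table and sequences")
  if (length(common) < nrow(table))
    .warnf("%d ASV(s) in the table have no sequence and are dropped",
           nrow(table) - length(common))
  table <- table[common, , drop = FALSE]
  placements <- place_queries(db, seqs[common])

  nsti <- setNames(placements$chosen_nsti, placements$query_id)
  kept <- apply_nsti_cutoff(table, nsti, max_nsti)
  excluded <- attr(kept, "excluded")
  if (nrow(kept) == 0L) .fail("no ASVs survive the NSTI cutoff")

  copies <- setNames(placements$predicted_16S_copies,
                     placements$query_id)[rownames(kept)]
  normalized <- normalize_by_copy_number(kept, copies)
  keep_rows <- placements$query_id %in% rownames(kept)
  placements_kept <- placements[keep_rows, ]
  attr(placements_kept, "placements") <-
    attr(placements, "placements")[placements_kept$query_id]

  metagenomes <- list()
  for (f in frameworks) {
    traits <- predict_traits(db, placements_kept, f, method = method)
    metagenomes[[f]] <- predict_metagenome(normalized, traits,
                                           stratified = stratified)
  }
  list(placements = placements,
       table = kept,
       copies = copies,
       metagenomes = metagenomes,
       weighted_nsti = weighted_nsti(kept, nsti),
       excluded = excluded)
}

#' Run a mock-community benchmark against a reference database
#'
#' Runs [run_prediction()] on the mock queries and scores each
#' framework's predicted metagenome against the gold standard.
#'
#' @param db a `ref_db`.
#' @param world a benchmark world from [make_benchmark_world()] (or a
#'   list with `query_seqs`, `feature_table`, `mock$gold_standard`).
#' @param frameworks framework ids (must be present in both the database
#'   and the gold standard; default `"KO"`).
#' @param max_nsti NSTI cutoff.
#' @param method HSP method.
#' @return list: `prediction` (the [run_prediction()] result) and
#'   `evaluation` (one `evaluation` data.frame per framework).
#' @export
run_benchmark <- function(db, world, frameworks = "KO", max_nsti = 2.0,
                          method = c("auto", "mp", "dw")) {
  pred <- run_prediction(db, world$query_seqs, world$feature_table,
                         frameworks, max_nsti, method)
  evaluation <- lapply(setNames(nm = frameworks), function(f)
    evaluate_predictions(pred$metagenomes[[f]],
                         world$mock$gold_standard,
                         wnsti = pred$weighted_nsti))
  list(prediction = pred, evaluation = evaluation)
}
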
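# Shared synthetic worlds, built once per test run (kept small so the
# whole suite stays inside its time budget).

.world_cache <- new.env(parent = emptyenv())

toy_world <- function() {
  if (is.null(.world_cache$toy))
    .world_cache$toy <- make_benchmark_world(
      synth_config(seed = 101L,
                   n_tips = c(bacteria = 30L, archaea = 12L),
                   n_traits = 10L, n_samples = 4L))
  .world_cache$toy
}

# 50-tip world used by the perfect-recovery checks
recovery_world <- function() {
  if (is.null(.world_cache$recovery))
    .world_cache$recovery <- make_benchmark_world(
      synth_config(seed = 202L,
                   n_tips = c(bacteria = 50L, archaea = 10L),
                   n_samples = 10L),
      queries = "retained")
  .world_cache$recovery
}

# small hand-checkable metadata table for filter tests
toy_records <- function(n = 6L) {
  good_ssu <- paste(rep("ACGT", 400L), collapse = "")
  data.frame(genome_id = sprintf("g%02d", seq_len(n)),
             domain = "bacteria",
             completeness = rep(95, n),
             contamination = rep(1, n),
             is_representative = TRUE,
             in_domain_tree = TRUE,
             ssu = good_ssu,
             stringsAsFactors = FALSE)
}
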
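# Seeded generators for every input the engine and benchmark need:
# pure-birth trees, trait evolution by gain/loss walks, 16S-like
# sequences, genome metadata, community abundances, and complete
# benchmark "worlds" with held-out mock genomes.
#
# Identical config => identical outputs: every generator seeds R's
# Mersenne-Twister stream explicitly and touches no other entropy
# source.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a small but realistic desk-scale world: a 50-tip
#' bacterial and 20-tip archaeal reference, tree depth 0.3
#' substitutions/site (typical within-domain 16S divergence), 20 KO-like
#' gene families evolving by gain/loss at rate 2 events per unit branch
#' length, full-length 1500-nt 16S sequences evolving at 1
#' substitution/site per unit branch length, 10 samples with log-normal
#' abundances (sdlog 1, the typical spread of microbial relative
#' abundances), and 20% of tips held out as mock genomes.
#'
#' @param seed integer master seed.
#' @param n_tips named integer vector, tips per domain.
#' @param tree_depth target mean root-to-tip depth (substitutions/site).
#' @param n_traits number of gene families in the "KO" framework.
#' @param trait_gain,trait_loss gain/loss rates per unit branch length.
#' @param root_lambda Poisson mean of root gene-family copy numbers.
#' @param ssu_root root 16S copy number.
#' @param ssu_gain,ssu_loss gain/loss rates of the 16S copy trait.
#' @param seq_length 16S sequence length (nt).
#' @param sub_rate substitutions/site per unit branch length.
#' @param n_samples samples in the community model.
#' @param abund_meanlog,abund_sdlog log-normal abundance parameters.
#' @param heldout_fraction fraction of tips held out, in (0, 0.5].
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_tips = c(bacteria = 50L, archaea = 20L),
                         tree_depth = 0.3,
                         n_traits = 20L,
                         trait_gain = 2, trait_loss = 2,
                         root_lambda = 2,
                         ssu_root = 4L, ssu_gain = 0.5, ssu_loss = 0.5,
                         seq_length = 1500L, sub_rate = 1,
                         n_samples = 10L,
                         abund_meanlog = 4, abund_sdlog = 1,
                         heldout_fraction = 0.2) {
  if (heldout_fraction <= 0 || heldout_fraction > 0.5)
    .fail("heldout_fraction must lie in (0, 0.5]")
  if (seq_length < 100L) .fail("seq_length must be >= 100")
  if (any(n_tips < 3L)) .fail("need at least 3 tips per domain")
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: starting from two lineages, exponential waiting
#' times (rate proportional to the number of live lineages) separate
#' uniformly chosen splits until `n_tips` lineages exist; a final
#' waiting segment extends all lineages to the present. Branch lengths
#' are then rescaled so the mean root-to-tip depth equals `depth`.
#'
#' @param n_tips number of tips (>= 3).
#' @param depth target mean root-to-tip depth.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param labels optional tip labels (default `t1..tn`, in creation
#'   order).
#' @return a rooted, binary `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, depth = 0.3, seed = NULL,
                          labels = NULL) {
  if (n_tips < 3L) .fail("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  # active lineages: parent (temporary id) and accumulated length
  parent <- c(0L, 0L)          # tmp id 0 = root
  len <- c(0, 0)
  edges <- list()              # (parent_tmp, child_tmp, length)
  next_id <- 1L
  while (length(parent) < n_tips) {
    k <- length(parent)
    t <- rexp(1L, rate = k)
    len <- len + t
    i <- sample.int(k, 1L)
    edges[[length(edges) + 1L]] <- c(parent[i], next_id, len[i])
    parent <- c(parent[-i], next_id, next_id)
    len <- c(len[-i], 0, 0)
    next_id <- next_id + 1L
  }
  len <- len + rexp(1L, rate = length(parent))
  tip_tmp <- seq.int(next_id, next_id + n_tips - 1L)
  for (i in seq_along(parent))
    edges[[length(edges) + 1L]] <- c(parent[i], tip_tmp[i], len[i])
  em <- do.call(rbind, edges)
  # map: tips -> 1..n, internals -> n+1.. (root first)
  internals <- c(0L, setdiff(sort(unique(em[, 1L])), 0L))
  id_map <- integer(max(em) + 1L)
  id_map[tip_tmp + 1L] <- seq_len(n_tips)
  id_map[internals + 1L] <- n_tips + seq_along(internals)
  phy <- list(edge = cbind(id_map[em[, 1L] + 1L], id_map[em[, 2L] + 1L]),
              edge.length = em[, 3L],
              tip.label = if (is.null(labels))
                paste0("t", seq_len(n_tips)) else labels,
              Nnode = length(internals))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  depths <- ape::node.depth.edgelength(phy)[seq_len(n_tips)]
  phy$edge.length <- phy$edge.length * depth / mean(depths)
  phy
}

# one gain/loss step along a branch for a vector of integer traits
#' @noRd
gain_loss_step <- function(values, len, gain, loss, floor = 0L) {
  v <- values + rpois(length(values), gain * len) -
    rpois(length(values), loss * len)
  pmax(v, floor)
}

#' Evolve integer copy-number traits along a tree
#'
#' Each trait performs a seeded random walk from the root: along a branch
#' of length `len` it gains `Poisson(gain * len)` and loses
#' `Poisson(loss * len)` copies, floored at `floor` (0 for gene
#' families, 1 for the 16S copy trait).
#'
#' @param tree a `phylo`.
#' @param root_states integer vector of root copy numbers (one per
#'   trait, named).
#' @param gain,loss event rates per unit branch length.
#' @param seed integer seed (`NULL` = current RNG state).
#' @param framework framework id of the returned table.
#' @param floor minimum copy number.
#' @return a tip [trait_table()].
#' @export
evolve_traits <- function(tree, root_states, gain, loss, seed = NULL,
                          framework = "KO", floor = 0L) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_real_, nnode, length(root_states))
  states[ntip + 1L, ] <- pmax(root_states, floor)
  po <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    states[ch, ] <- gain_loss_step(states[p, ], po$edge.length[r],
                                   gain, loss, floor)
  }
  m <- states[seq_len(ntip), , drop = FALSE]
  dimnames(m) <- list(tree$tip.label, names(root_states))
  trait_table(m, framework)
}

.BASES <- c("A", "C", "G", "T")

# substitute: n Poisson-many positions, uniform alternative base
#' @noRd
mutate_seq <- function(chars, n_sub) {
  if (n_sub == 0L) return(chars)
  pos <- sample.int(length(chars), n_sub, replace = TRUE)
  for (p in pos) {
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  }
  chars
}

#' Evolve nucleotide sequences along a tree
#'
#' The root sequence is uniform random over A/C/G/T; along each branch,
#' `Poisson(rate * len * length)` substitutions hit uniform positions and
#' change to a uniform alternative base (Jukes-Cantor-like dynamics, no
#' rate heterogeneity, no indels).
#'
#' @param tree a `phylo`.
#' @param length sequence length (>= 100 nt).
#' @param rate substitutions/site per unit branch length.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return named character vector of tip sequences.
#' @export
evolve_sequences <- function(tree, length = 1500L, rate = 1,
                             seed = NULL) {
  if (length < 100L) .fail("sequence length must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[ntip + 1L]] <- sample(.BASES, length, replace = TRUE)
  po <- ape::reorder.phylo(tree, "cladewise")
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    n_sub <- rpois(1L, rate * po$edge.length[r] * length)
    seqs[[ch]] <- mutate_seq(seqs[[p]], n_sub)
  }
  setNames(vapply(seqs[seq_len(ntip)], paste, "", collapse = ""),
           tree$tip.label)
}

# simple nested taxonomy: genus groups of ~5 tips by tree order, species
# unique per genome
#' @noRd
synth_taxonomy <- function(tree, domain) {
  tips <- tree$tip.label
  dom <- if (domain == "bacteria") "Bacteria" else "Archaea"
  genus <- (match(tips, tips) - 1L) %/% 5L + 1L
  sprintf("d__%s;p__P1;c__C1;o__O1;f__F1;g__%s_g%d;s__%s",
          dom, substr(dom, 1, 3), genus, tips)
}

#' Generate a complete benchmark world
#'
#' Simulates one tree per domain with evolved gene-family copy numbers,
#' 16S copy numbers and 16S sequences; holds out a seeded fraction of
#' tips per domain (removed from the reference database, kept as the
#' mock-genome pool with their true traits and sequences); builds the
#' reference database; and draws a log-normal mock community over the
#' held-out genomes with its exact gold-standard functional profile.
#'
#' @param config a [synth_config()].
#' @param queries `"heldout"` (default: queries are the held-out
#'   genomes' 16S sequences) or `"retained"` (queries are reference tips
#'   themselves -- the perfect-recovery limit).
#' @return a list: `db` (`ref_db`), `mock` (`mock_community` with gold
#'   standard), `feature_table` (ASV x sample), `query_seqs`,
#'   `query_domain` (true domain per query), `truth` (full trait tables,
#'   16S copies, sequences, taxonomy, metadata and unpruned trees for
#'   every genome),
#'   `heldout` ids, and the `config`.
#' @export
make_benchmark_world <- function(config = synth_config(),
                                 queries = c("heldout", "retained")) {
  queries <- match.arg(queries)
  set.seed(config$seed)
  seeds <- sample.int(2^30, 32L)
  si <- 0L; nxt <- function() { si <<- si + 1L; seeds[si] }

  doms <- names(config$n_tips)
  trees <- list(); ko <- list(); ssu_cp <- list(); seqs <- list()
  tax <- list(); heldout <- list()
  trait_ids <- sprintf("K%05d", seq_len(config$n_traits))
  for (d in doms) {
    n <- config$n_tips[[d]]
    labels <- sprintf("%s_t%03d", substr(d, 1L, 3L), seq_len(n))
    trees[[d]] <- simulate_tree(n, config$tree_depth, seed = nxt(),
                                labels = labels)
    set.seed(nxt())
    roots <- setNames(rpois(config$n_traits, config$root_lambda),
                      trait_ids)
    ko[[d]] <- evolve_traits(trees[[d]], roots, config$trait_gain,
                             config$trait_loss, seed = nxt(),
                             framework = "KO", floor = 0L)
    ssu_cp[[d]] <- evolve_traits(
      trees[[d]], setNames(config$ssu_root, "16S_rRNA_Count"),
      config$ssu_gain, config$ssu_loss, seed = nxt(),
      framework = "16S", floor = 1L)
    seqs[[d]] <- evolve_sequences(trees[[d]], config$seq_length,
                                  config$sub_rate, seed = nxt())
    tax[[d]] <- setNames(synth_taxonomy(trees[[d]], d), labels)
    set.seed(nxt())
    heldout[[d]] <- sort(sample(labels,
                                ceiling(config$heldout_fraction * n)))
  }
  all_ids <- unlist(lapply(doms, function(d) trees[[d]]$tip.label),
                    use.names = FALSE)
  held <- unlist(heldout, use.names = FALSE)
  retained <- setdiff(all_ids, held)

  ko_all <- trait_table(do.call(rbind, lapply(ko, unclass)), "KO")
  ssu_all <- trait_table(do.call(rbind, lapply(ssu_cp, unclass)), "16S")
  seq_all <- unlist(unname(seqs))
  tax_all <- unlist(unname(tax))

  set.seed(nxt())
  meta <- data.frame(
    genome_id = all_ids,
    domain = rep(doms, vapply(doms, function(d) config$n_tips[[d]], 1L)),
    completeness = runif(length(all_ids), 95, 100),
    contamination = runif(length(all_ids), 0, 1),
    is_representative = TRUE, in_domain_tree = TRUE,
    ssu = unname(seq_all[all_ids]),
    stringsAsFactors = FALSE)

  db <- build_reference(trees,
                        list(KO = ko_all, `16S` = ssu_all),
                        ssu_sequences = seq_all,
                        genomes = meta[meta$genome_id %in% retained, ],
                        version = sprintf("synth-seed%d", config$seed))

  mock_ids <- if (queries == "heldout") held else sort(retained)
  set.seed(nxt())
  ab <- matrix(rlnorm(length(mock_ids) * config$n_samples,
                      config$abund_meanlog, config$abund_sdlog),
               length(mock_ids), config$n_samples,
               dimnames = list(mock_ids,
                               sprintf("sample_%02d",
                                       seq_len(config$n_samples))))
  mock <- structure(list(genome_ids = mock_ids, abundances = ab,
                         taxonomy = data.frame(
                           genome_id = mock_ids,
                           taxonomy = unname(tax_all[mock_ids]),
                           stringsAsFactors = FALSE)),
                    class = "mock_community")
  ssu_copies <- setNames(unclass(ssu_all)[, 1L], rownames(ssu_all))
  mock <- build_gold_standard(mock, subset_trait_table(ko_all, mock_ids),
                              ssu_copies)

  qseqs <- setNames(unname(seq_all[mock_ids]),
                    paste0("asv_", mock_ids))
  ft <- ab
  rownames(ft) <- paste0("asv_", mock_ids)
  qdom <- setNames(meta$domain[match(mock_ids, meta$genome_id)],
                   paste0("asv_", mock_ids))

  list(db = db, mock = mock, feature_table = ft, query_seqs = qseqs,
       query_domain = qdom,
       truth = list(traits = ko_all, ssu_copies = ssu_copies,
                    seqs = seq_all, taxonomy = tax_all, metadata = meta,
                    trees = trees),
       heldout = held, config = config)
}

#' Push a world's mock genomes further from the reference
#'
#' Evolves every query sequence, its gene-family copy numbers, and its
#' 16S copy number onward along an extra branch of length `delta`
#' (substitutions/site), then rebuilds the gold standard. Used to create
#' tiers of increasing held-out phylogenetic distance for the
#' degradation benchmark: larger `delta` means larger NSTIs and a truth
#' that has drifted further from anything the reference tips can
#' predict.
#'
#' @param world result of [make_benchmark_world()].
#' @param delta extra branch length.
#' @param seed integer seed.
#' @return the modified world (same samples and abundances).
#' @export
extend_divergence <- function(world, delta, seed) {
  set.seed(seed)
  cfg <- world$config
  ids <- world$mock$genome_ids
  traits <- unclass(world$truth$traits)[ids, , drop = FALSE]
  copies <- world$truth$ssu_copies[ids]
  for (i in seq_along(ids)) {
    g <- ids[i]
    q <- paste0("asv_", g)
    chars <- seq_chars(world$query_seqs[[q]])
    n_sub <- rpois(1L, cfg$sub_rate * delta * length(chars))
    world$query_seqs[[q]] <- paste(mutate_seq(chars, n_sub),
                                   collapse = "")
    traits[i, ] <- gain_loss_step(traits[i, ], delta, cfg$trait_gain,
                                  cfg$trait_loss, floor = 0L)
    copies[i] <- gain_loss_step(copies[i], delta, cfg$ssu_gain,
                                cfg$ssu_loss, floor = 1L)
  }
  mock <- world$mock
  mock$gold_standard <- NULL
  mock <- build_gold_standard(mock, trait_table(traits, "KO"), copies)
  world$mock <- mock
  world$truth$ssu_copies[ids] <- copies
  tt <- unclass(world$truth$traits)
  tt[ids, ] <- traits
  world$truth$traits <- trait_table(tt, "KO")
  world
}
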
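# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: tree distances are computed by explicit
# graph traversal (or igraph), parsimony by exhaustive enumeration,
# Spearman by rank-then-Pearson, Bray-Curtis by vegan.

# all-pairs node distances by breadth-first traversal over the edge list
oracle_node_dists <- function(tree) {
  nnode <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nnode)
  for (r in seq_len(nrow(tree$edge))) {
    a <- tree$edge[r, 1L]; b <- tree$edge[r, 2L]; w <- tree$edge.length[r]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(NA_real_, nnode, nnode)
  for (s in seq_len(nnode)) {
    d <- rep(NA_real_, nnode); d[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        u <- nb[k, 1L]
        if (is.na(d[u])) { d[u] <- d[v] + nb[k, 2L]; queue <- c(queue, u) }
      }
    }
    D[s, ] <- d
  }
  D
}

# minimum-change cost and optimal query value by exhaustive enumeration
# of ALL node labelings (internal nodes and the unconstrained query tip)
# over the given state set, linear cost |a - b| per edge
oracle_parsimony <- function(tree, tipvals, query_tip, states) {
  ntip <- length(tree$tip.label)
  free <- c(which(tree$tip.label == query_tip), ntip + seq_len(tree$Nnode))
  fixed <- setdiff(seq_len(ntip), free)
  lab <- integer(ntip + tree$Nnode)
  lab[fixed] <- tipvals[tree$tip.label[fixed]]
  grid <- t(as.matrix(do.call(expand.grid, rep(list(states),
                                               length(free)))))
  qi <- which(tree$tip.label == query_tip)
  L <- matrix(lab, length(lab), ncol(grid))
  L[free, ] <- grid
  cost <- colSums(abs(L[tree$edge[, 1L], , drop = FALSE] -
                        L[tree$edge[, 2L], , drop = FALSE]))
  best <- which.min(cost)
  list(cost = cost[best], query_value = L[qi, best])
}

# rank-transform then Pearson (average ranks for ties)
oracle_spearman <- function(a, b) cor(rank(a), rank(b))

oracle_bray_curtis <- function(a, b) {
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

# random placement somewhere on a random edge of a tree
random_placement <- function(tree, pendant_max = 0.1) {
  r <- sample.int(nrow(tree$edge), 1L)
  structure(list(query_id = "q", status = "ok",
                 nearest_tip = NA_character_,
                 edge = c(parent = tree$edge[r, 1L],
                          child = tree$edge[r, 2L]),
                 distal = runif(1L, 0, tree$edge.length[r]),
                 pendant = runif(1L, 0, pendant_max)),
            class = "placement")
}

# NSTI by brute force: graph distances from the grafted query tip
oracle_nsti <- function(placement, tree) {
  g <- graft_query(tree, placement, label = ".oracle_query")
  D <- oracle_node_dists(g)
  qi <- which(g$tip.label == ".oracle_query")
  ref <- setdiff(seq_along(g$tip.label), qi)
  min(D[qi, ref])
}

# deterministically mutate a sequence at exactly k positions
mutate_at <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- seq_len(k)
  for (p in pos)
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  paste(chars, collapse = "")
}
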
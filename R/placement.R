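# Query placement into per-domain reference trees.
#
# Desk-scale substitute for alignment+EPA placement: queries are compared
# to every reference 16S by (un)gapped pairwise comparison, distances are
# Jukes-Cantor corrected, and the query is grafted onto the terminal edge
# of the nearest tip (at the tip, distal 0) with the JC distance as
# pendant length. The interface is placement-method agnostic, so a
# likelihood-based placement backend could be swapped in.

# Minimum number of comparable (both-ACGT) positions for a distance
.MIN_INFORMATIVE <- 50L

#' @noRd
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1L]]

#' Jukes-Cantor corrected distance from a proportion of differing sites
#'
#' Returns `NA` for saturated distances (p >= 0.75), which downstream
#' marks the query unplaceable in that domain.
#'
#' @param p proportion of differing sites in `[0, 1]`.
#' @return distance in substitutions/site, or `NA` if saturated.
#' @export
jc_distance <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# p-distance of a query against a reference character matrix (rows =
# references, all the same length as the query). Sites where either
# sequence is not A/C/G/T are uninformative and skipped.
#' @noRd
p_dist_matrix <- function(qchars, refmat) {
  acgt <- c("A", "C", "G", "T")
  qin <- qchars %in% acgt
  inform <- t(t(matrix(refmat %in% acgt, nrow(refmat))) & qin)
  mism <- t(t(refmat) != qchars) & inform
  n_inf <- rowSums(inform)
  p <- ifelse(n_inf > 0, rowSums(mism) / n_inf, NA_real_)
  list(p = p, n_informative = n_inf)
}

# Pairwise p-distance for sequences of unequal length via global
# alignment (Biostrings); used only off the common equal-length fast path.
#' @noRd
p_dist_pair <- function(q, r) {
  if (nchar(q) == nchar(r)) {
    res <- p_dist_matrix(seq_chars(q),
                         matrix(seq_chars(r), nrow = 1L))
    return(c(p = res$p, n_informative = res$n_informative))
  }
  if (!requireNamespace("Biostrings", quietly = TRUE))
    .fail("sequences of unequal length require the Biostrings package")
  al <- Biostrings::pairwiseAlignment(q, r, type = "global")
  qa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  ra <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  res <- p_dist_matrix(qa, matrix(ra, nrow = 1L))
  c(p = res$p, n_informative = res$n_informative)
}

#' Place one query sequence into one domain's reference tree
#'
#' Computes a Jukes-Cantor distance from the query to every reference 16S
#' sequence and attaches the query at the nearest tip (distal position 0
#' on the tip's terminal edge) with the estimated distance as pendant
#' length. Ties between equidistant tips are broken towards the
#' lexicographically smaller genome id. The query is unplaceable in this
#' domain when every reference comparison has fewer than 50 informative
#' positions or every corrected distance is saturated (p >= 0.75).
#'
#' @param query_seq nucleotide string, length >= 50.
#' @param db_domain one domain slice of a `ref_db`
#'   (`db$domains$bacteria` or `db$domains$archaea`).
#' @param query_id identifier carried into the result.
#' @param refmat optional precomputed reference character matrix (rows =
#'   reference tips, in `names(db_domain$ssu)` order) for repeated calls.
#' @return a `placement` object: `query_id`, `status` ("ok" or
#'   "unplaceable"), `nearest_tip`, `edge` (parent, child node ids),
#'   `distal`, `pendant`, `n_informative`.
#' @export
place_query <- function(query_seq, db_domain, query_id = "query",
                        refmat = NULL) {
  if (nchar(query_seq) < 50L) .fail("query '%s' shorter than 50 nt",
                                    query_id)
  ssu <- db_domain$ssu
  lens <- nchar(ssu)
  qchars <- seq_chars(query_seq)
  if (!is.null(refmat) || all(lens == length(qchars))) {
    if (is.null(refmat))
      refmat <- do.call(rbind, lapply(ssu, seq_chars))
    res <- p_dist_matrix(qchars, refmat)
    p <- res$p; n_inf <- res$n_informative
  } else {
    prs <- vapply(ssu, p_dist_pair, numeric(2L), q = query_seq)
    p <- prs["p", ]; n_inf <- prs["n_informative", ]
  }
  p[n_inf < .MIN_INFORMATIVE] <- NA_real_
  d <- jc_distance(p)
  names(d) <- names(ssu)
  if (all(is.na(d)))
    return(structure(list(query_id = query_id, status = "unplaceable",
                          nearest_tip = NA_character_, edge = c(NA, NA),
                          distal = NA_real_, pendant = NA_real_,
                          n_informative = max(n_inf)),
                     class = "placement"))
  cand <- names(d)[!is.na(d) & d == min(d, na.rm = TRUE)]
  nearest <- sort(cand)[1L]
  tree <- db_domain$tree
  tip <- match(nearest, tree$tip.label)
  row <- which(tree$edge[, 2L] == tip)
  structure(list(query_id = query_id, status = "ok",
                 nearest_tip = nearest,
                 edge = c(parent = tree$edge[row, 1L], child = tip),
                 distal = 0, pendant = unname(d[nearest]),
                 n_informative = n_inf[match(nearest, names(ssu))]),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %s: %s", x$query_id, x$status))
  if (x$status == "ok")
    cat(sprintf(" at tip %s, pendant %.4g", x$nearest_tip, x$pendant))
  cat("\n"); invisible(x)
}

# Distance from the attachment point of a placement to every tip of the
# tree. The point sits on edge (parent, child) at `distal` from the
# child; a tip reached through the child contributes distal + d(child,
# tip), one reached through the parent contributes (edge length - distal)
# + d(parent, tip).
#' @noRd
point_tip_dists <- function(tree, placement, tipdist = NULL) {
  child <- placement$edge[["child"]]
  ntip <- length(tree$tip.label)
  if (placement$distal == 0 && child <= ntip) {
    if (!is.null(tipdist)) return(tipdist[tree$tip.label[child], ])
    D <- ape::dist.nodes(tree)
    return(setNames(D[child, seq_len(ntip)], tree$tip.label))
  }
  parent <- placement$edge[["parent"]]
  row <- which(tree$edge[, 1L] == parent & tree$edge[, 2L] == child)
  elen <- tree$edge.length[row]
  D <- ape::dist.nodes(tree)
  tips <- seq_len(ntip)
  via_child <- abs(D[parent, tips] - (elen + D[child, tips])) < 1e-9
  d <- ifelse(via_child, placement$distal + D[child, tips],
              (elen - placement$distal) + D[parent, tips])
  setNames(d, tree$tip.label)
}

#' Nearest Sequenced Taxon Index of a placement
#'
#' NSTI is the minimum, over all reference tips, of pendant length plus
#' the path length along the tree from the attachment point to that tip
#' (substitutions/site). For a placement attached exactly at a tip this
#' reduces to the pendant length, and the function takes that shortcut.
#'
#' @param placement a `placement` (see [place_query()]).
#' @param tree the `phylo` tree the placement refers to.
#' @param tipdist optional precomputed tip-tip distance matrix
#'   (`ape::cophenetic.phylo`), used on the tip-attachment fast path.
#' @return non-negative real, or `NA` for an unplaceable query.
#' @export
compute_nsti <- function(placement, tree, tipdist = NULL) {
  if (placement$status != "ok") return(NA_real_)
  child <- placement$edge[["child"]]
  if (placement$distal == 0 && child <= length(tree$tip.label))
    return(placement$pendant)
  placement$pendant + min(point_tip_dists(tree, placement, tipdist))
}

#' Select the domain with the lowest NSTI for a query
#'
#' @param query_id query identifier.
#' @param nsti_bacteria,nsti_archaea per-domain NSTI (`NA` = undefined,
#'   e.g. the query is unplaceable in that domain).
#' @return one-row data.frame: `query_id`, `nsti_bacteria`,
#'   `nsti_archaea`, `chosen_domain`, `chosen_nsti`. Ties go to bacteria
#'   (deterministic); both undefined yields `chosen_domain = NA` (the
#'   query is unplaceable overall).
#' @export
select_domain <- function(query_id, nsti_bacteria, nsti_archaea) {
  vals <- c(bacteria = nsti_bacteria, archaea = nsti_archaea)
  if (all(is.na(vals))) {
    chosen <- NA_character_; nsti <- NA_real_
  } else {
    nsti <- min(vals, na.rm = TRUE)
    # which.max of the tie-broken candidates: bacteria first
    chosen <- names(vals)[!is.na(vals) & vals == nsti][1L]
  }
  data.frame(query_id = query_id, nsti_bacteria = nsti_bacteria,
             nsti_archaea = nsti_archaea, chosen_domain = chosen,
             chosen_nsti = nsti, stringsAsFactors = FALSE)
}

#' Graft a placed query onto its tree as a new tip
#'
#' Splits the attachment edge at the placement's distal position with a
#' new internal node and hangs the query from it by its pendant length.
#' Pairwise distances among the original tips are unchanged.
#'
#' @param tree a `phylo`.
#' @param placement a `placement` with status "ok".
#' @param label tip label for the query (default its `query_id`).
#' @return a `phylo` with one extra tip.
#' @export
graft_query <- function(tree, placement, label = placement$query_id) {
  stopifnot(inherits(tree, "phylo"), placement$status == "ok")
  n <- length(tree$tip.label)
  child <- placement$edge[["child"]]
  e <- tree$edge
  el <- tree$edge.length
  row <- which(e[, 2L] == child)
  if (length(row) != 1L) .fail("attachment edge not found in tree")
  elen <- el[row]
  if (placement$distal < 0 || placement$distal > elen + 1e-12)
    .fail("distal position outside the attachment edge")
  # shift internal node ids up by one to make room for the new tip
  e2 <- e
  e2[e2 > n] <- e2[e2 > n] + 1L
  child2 <- if (child > n) child + 1L else child
  new_tip <- n + 1L
  new_int <- n + 1L + tree$Nnode + 1L
  parent2 <- e2[row, 1L]
  e2[row, ] <- c(parent2, new_int)
  el[row] <- elen - placement$distal
  e2 <- rbind(e2, c(new_int, child2), c(new_int, new_tip))
  el <- c(el, placement$distal, placement$pendant)
  out <- list(edge = e2, edge.length = el,
              tip.label = c(tree$tip.label, label),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Predict the 16S copy number at a query's attachment point
#'
#' Inverse-distance-weighted hidden-state prediction of the 16S
#' copy-number trait at the attachment point, clamped to >= 1 (every
#' genome carries at least one 16S copy).
#'
#' @param placement a `placement`.
#' @param tree the domain tree.
#' @param ssu_trait the `"16S"` [trait_table()] covering all tips.
#' @param tipdist optional precomputed cophenetic matrix.
#' @return a real >= 1, or `NA` for an unplaceable query.
#' @export
predict_copy_number <- function(placement, tree, ssu_trait,
                                tipdist = NULL) {
  if (placement$status != "ok") return(NA_real_)
  d <- point_tip_dists(tree, placement, tipdist)
  val <- dw_predict(d, unclass(ssu_trait)[names(d), , drop = FALSE])
  max(1, val)
}

#' Place queries into every domain of a reference database
#'
#' Runs [place_query()] against each domain tree, computes per-domain
#' NSTIs, selects the lowest-NSTI domain per query, and predicts 16S copy
#' numbers in the chosen domain. Queries unplaceable in one domain are
#' normal (16S is typically saturated across domains) and are only
#' reported as a summary count, not per query.
#'
#' @param db a `ref_db`.
#' @param seqs named character vector of query (ASV) sequences.
#' @return data.frame with one row per query: `query_id`,
#'   `nsti_bacteria`, `nsti_archaea`, `chosen_domain`, `chosen_nsti`,
#'   `predicted_16S_copies`. The chosen-domain `placement` objects are in
#'   `attr(, "placements")` (named by query id; `NULL` for unplaceable
#'   queries).
#' @export
place_queries <- function(db, seqs) {
  stopifnot(inherits(db, "ref_db"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    .fail("query sequences must have unique names")
  doms <- names(db$domains)
  # per-domain precomputations shared across queries
  prep <- lapply(db$domains, function(dd) {
    lens <- nchar(dd$ssu)
    list(refmat = if (length(unique(lens)) == 1L)
                    do.call(rbind, lapply(dd$ssu, seq_chars)) else NULL,
         reflen = unique(lens),
         tipdist = ape::cophenetic.phylo(dd$tree))
  })
  res <- vector("list", length(seqs))
  placements <- setNames(vector("list", length(seqs)), names(seqs))
  for (i in seq_along(seqs)) {
    qid <- names(seqs)[i]
    per_dom <- lapply(doms, function(d) {
      refmat <- if (length(prep[[d]]$reflen) == 1L &&
                    nchar(seqs[i]) == prep[[d]]$reflen)
                  prep[[d]]$refmat else NULL
      pl <- place_query(seqs[[i]], db$domains[[d]], qid, refmat = refmat)
      list(placement = pl,
           nsti = compute_nsti(pl, db$domains[[d]]$tree,
                               prep[[d]]$tipdist))
    })
    names(per_dom) <- doms
    getn <- function(d) if (d %in% doms) per_dom[[d]]$nsti else NA_real_
    rec <- select_domain(qid, getn("bacteria"), getn("archaea"))
    copies <- NA_real_
    if (!is.na(rec$chosen_domain)) {
      d <- rec$chosen_domain
      placements[[qid]] <- per_dom[[d]]$placement
      copies <- predict_copy_number(per_dom[[d]]$placement,
                                    db$domains[[d]]$tree,
                                    db$domains[[d]]$traits[["16S"]],
                                    prep[[d]]$tipdist)
    }
    rec$predicted_16S_copies <- copies
    res[[i]] <- rec
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_single <- sum(is.na(out$nsti_bacteria) != is.na(out$nsti_archaea))
  n_unpl <- sum(is.na(out$chosen_domain))
  if (n_unpl > 0)
    .warnf("%d of %d queries unplaceable in every domain",
           n_unpl, nrow(out))
  attr(out, "placements") <- placements
  attr(out, "n_single_domain") <- n_single
  out
}
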
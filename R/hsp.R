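# Hidden-state prediction: infer trait values for a placed query from
# the trait values observed at the reference tips.
#
# Two methods:
#  * max_parsimony ("mp"): Sankoff minimum-change reconstruction with
#    linear cost |a - b| between integer states, the classic choice for
#    integer gene-family copy numbers.
#  * distance_weighted ("dw"): inverse-distance-weighted mean of the tip
#    values, a continuous fallback used for 16S copy number and any
#    non-integer trait table.

# Cap on the Sankoff state space per trait; wider traits fall back to dw
.MAX_STATES <- 64L

# Inverse-distance-weighted prediction from point-to-tip distances.
# d == 0 (within tolerance) returns the exact value at that tip (mean if
# several tips coincide through zero-length edges).
#' @noRd
dw_predict <- function(d, traitmat, eps = 1e-9) {
  stopifnot(length(d) == nrow(traitmat))
  zero <- d <= 1e-12
  if (any(zero))
    return(colMeans(traitmat[zero, , drop = FALSE]))
  w <- 1 / (d + eps)
  as.vector(crossprod(traitmat, w)) / sum(w)
}

#' Distance-weighted hidden-state prediction
#'
#' Predicts each trait for the query tip as the inverse-distance-weighted
#' mean of the reference tip values, with weights `1 / (d_k + 1e-9)`
#' where `d_k` is the tree distance from the query's attachment point
#' (the query's parent node side of its pendant edge) to reference tip
#' `k`. An attachment coinciding with a reference tip returns that tip's
#' values exactly.
#'
#' @param tree `phylo` with the query grafted as a tip.
#' @param trait_matrix numeric matrix, rows = reference tips (all tips of
#'   `tree` except the query), columns = traits.
#' @param query_tip label of the query tip.
#' @return named numeric vector of predicted trait values.
#' @export
hsp_distance_weighted <- function(tree, trait_matrix, query_tip) {
  ref <- setdiff(tree$tip.label, query_tip)
  miss <- setdiff(ref, rownames(trait_matrix))
  if (length(miss))
    .fail("trait matrix does not cover tips: %s",
          paste(miss, collapse = ", "))
  if (anyNA(trait_matrix) || any(trait_matrix < 0))
    .fail("trait values must be non-negative")
  D <- ape::cophenetic.phylo(tree)
  qi <- match(query_tip, tree$tip.label)
  if (is.na(qi)) .fail("query tip '%s' not in tree", query_tip)
  pendant <- tree$edge.length[tree$edge[, 2L] == qi]
  d <- pmax(0, D[query_tip, ref] - pendant)
  dw_predict(d, trait_matrix[ref, , drop = FALSE])
}

# One-dimensional min-plus distance transform: for consecutive integer
# states, m(s) = min_{s'} (v(s') + |s - s'|) in two linear passes.
#' @noRd
dtransform <- function(v) {
  k <- length(v)
  if (k > 1L) {
    for (i in 2:k) v[i] <- min(v[i], v[i - 1L] + 1)
    for (i in (k - 1L):1L) v[i] <- min(v[i], v[i + 1L] + 1)
  }
  v
}

# Sankoff DP for one integer trait on a rooted (binarised) tree.
# tipvals: named integer values for reference tips; the query tip has an
# all-zero cost vector (its state is free). Returns the backtracked state
# at every node (smallest co-optimal state) plus the minimum total cost.
#' @noRd
sankoff_one <- function(tree, tipvals, query_tip) {
  states <- seq.int(min(tipvals), max(tipvals))
  K <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- matrix(0, K, nnode)
  for (i in seq_len(ntip)) {
    lab <- tree$tip.label[i]
    if (lab == query_tip) next
    S[, i] <- .BIG
    S[match(tipvals[[lab]], states), i] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    S[, p] <- S[, p] + dtransform(S[, ch])
  }
  root <- ntip + 1L
  cost <- min(S[, root])
  state <- integer(nnode)
  state[root] <- states[which.min(S[, root])]
  for (r in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    comb <- S[, ch] + abs(states - state[p])
    state[ch] <- states[which.min(comb)]
  }
  list(state = state, cost = cost,
       query_value = state[match(query_tip, tree$tip.label)])
}

#' Maximum-parsimony hidden-state prediction
#'
#' Sankoff minimum-change reconstruction per trait with linear cost
#' `|a - b|` between integer states over the observed state range.
#' Polytomies are resolved deterministically (left-leaning, zero-length
#' edges). The query tip carries no state constraint, so its value equals
#' the reconstructed state of its parent node; among co-optimal states
#' the smallest is chosen at every node. If the query's attachment
#' coincides with a reference tip (zero pendant and distal), that tip's
#' values are returned directly.
#'
#' Traits whose observed integer range exceeds 64 states fall back to
#' [hsp_distance_weighted()] with a notice.
#'
#' @param tree `phylo` with the query grafted as a tip.
#' @param trait_matrix non-negative integer matrix, rows = reference
#'   tips, columns = traits.
#' @param query_tip label of the query tip.
#' @return named numeric vector of predictions with attribute `cost`
#'   (per-trait minimum parsimony cost; `NA` for traits that fell back to
#'   the distance-weighted method).
#' @export
hsp_max_parsimony <- function(tree, trait_matrix, query_tip) {
  ref <- setdiff(tree$tip.label, query_tip)
  miss <- setdiff(ref, rownames(trait_matrix))
  if (length(miss))
    .fail("trait matrix does not cover tips: %s",
          paste(miss, collapse = ", "))
  if (anyNA(trait_matrix) || any(trait_matrix < 0))
    .fail("trait values must be non-negative")
  if (any(trait_matrix != round(trait_matrix)))
    .fail(paste("max-parsimony HSP requires integer trait values;",
                "use the distance_weighted method"))
  if (!ape::is.binary.phylo(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  D <- ape::cophenetic.phylo(tree)
  exact <- ref[D[query_tip, ref] <= 1e-12]

  vals <- numeric(ncol(trait_matrix))
  costs <- rep(NA_real_, ncol(trait_matrix))
  wide <- character(0)
  for (j in seq_len(ncol(trait_matrix))) {
    tv <- trait_matrix[ref, j]
    rng <- max(tv) - min(tv) + 1L
    if (rng == 1L) { vals[j] <- tv[1L]; costs[j] <- 0; next }
    if (rng > .MAX_STATES) {
      wide <- c(wide, colnames(trait_matrix)[j])
      vals[j] <- hsp_distance_weighted(
        tree, trait_matrix[, j, drop = FALSE], query_tip)
      next
    }
    sk <- sankoff_one(tree, setNames(tv, ref), query_tip)
    vals[j] <- sk$query_value
    costs[j] <- sk$cost
  }
  if (length(wide))
    message(sprintf(
      "%d trait(s) exceed %d parsimony states; used distance weighting: %s",
      length(wide), .MAX_STATES,
      paste(head(wide, 5L), collapse = ", ")))
  if (length(exact))
    vals <- colMeans(trait_matrix[exact, , drop = FALSE])
  names(vals) <- colnames(trait_matrix)
  attr(vals, "cost") <- setNames(costs, colnames(trait_matrix))
  vals
}

#' Predict gene-family content for placed queries
#'
#' Runs hidden-state prediction for every successfully placed query
#' against one annotation framework of the reference database.
#'
#' @param db a `ref_db`.
#' @param placements the result of [place_queries()].
#' @param framework framework id registered in `db` (e.g. `"KO"`).
#' @param method `"auto"` (max parsimony when the table is all-integer,
#'   distance weighting otherwise), `"mp"`, or `"dw"`.
#' @return a [trait_table()] of predicted copy numbers, rows = placed
#'   query ids, plus attribute `method_used`.
#' @export
predict_traits <- function(db, placements, framework,
                           method = c("auto", "mp", "dw")) {
  method <- match.arg(method)
  pls <- attr(placements, "placements")
  keep <- placements$query_id[!is.na(placements$chosen_domain)]
  if (!length(keep)) .fail("no placed queries to predict for")
  dom_of <- setNames(placements$chosen_domain, placements$query_id)
  prep <- lapply(db$domains, function(dd) {
    if (!framework %in% names(dd$traits))
      .fail("framework '%s' not in database", framework)
    list(tipdist = ape::cophenetic.phylo(dd$tree),
         traits = unclass(dd$traits[[framework]]))
  })
  if (method == "auto") {
    all_int <- all(vapply(prep, function(p)
      all(p$traits == round(p$traits)), logical(1L)))
    method <- if (all_int) "mp" else "dw"
  }
  out <- matrix(NA_real_, length(keep),
                ncol(prep[[1L]]$traits),
                dimnames = list(keep, colnames(prep[[1L]]$traits)))
  for (qid in keep) {
    d <- dom_of[[qid]]
    pl <- pls[[qid]]
    tm <- prep[[d]]$traits
    if (method == "dw") {
      dist_k <- point_tip_dists(db$domains[[d]]$tree, pl,
                                prep[[d]]$tipdist)
      out[qid, ] <- dw_predict(dist_k, tm[names(dist_k), , drop = FALSE])
    } else {
      gt <- graft_query(db$domains[[d]]$tree, pl, label = qid)
      out[qid, ] <- suppressMessages(hsp_max_parsimony(gt, tm, qid))
    }
  }
  tt <- trait_table(out, framework)
  attr(tt, "method_used") <- method
  tt
}
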
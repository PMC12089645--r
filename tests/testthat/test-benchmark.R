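# Mock-community construction, gold standards, metrics, comparisons.

tax <- function(dom, gen, sp)
  sprintf("d__%s;p__P;c__C;o__O;f__F;g__%s;s__%s", dom, gen, sp)

test_that("taxa with exact species matches retain all abundance", {
  profile <- matrix(c(10, 20), 2L, 1L,
                    dimnames = list(c(tax("Bacteria", "G1", "S1"),
                                      tax("Bacteria", "G2", "S2")), "s1"))
  pool <- data.frame(genome_id = c("gA", "gB"),
                     taxonomy = c(tax("Bacteria", "G1", "S1"),
                                  tax("Bacteria", "G2", "S2")))
  mock <- match_taxa_to_heldout(profile, pool)
  expect_equal(mock$retained_fraction, 1.0)
  expect_setequal(mock$genome_ids, c("gA", "gB"))
  expect_equal(mock$mapping$matched_rank, c("species", "species"))
})

test_that("species-level ties pick the lexicographically smaller genome", {
  profile <- matrix(5, 1L, 1L,
                    dimnames = list(tax("Bacteria", "G1", "S1"), "s1"))
  pool <- data.frame(genome_id = c("gZ", "gA"),
                     taxonomy = rep(tax("Bacteria", "G1", "S1"), 2L))
  mock <- match_taxa_to_heldout(profile, pool)
  expect_equal(mock$genome_ids, "gA")
})

test_that("retained fraction matches hand bookkeeping; deep ranks win", {
  rn <- c(tax("Bacteria", "G1", "S1"),      # species match
          tax("Bacteria", "G1", "Sx"),      # genus match
          tax("Bacteria", "Gy", "Sy"),      # domain match only
          tax("Archaea", "Gz", "Sz"),       # unmatched domain? no: pool has none
          tax("Bacteria", "G2", "S2"))      # species match
  profile <- matrix(c(10, 20, 5, 40, 25), 5L, 1L,
                    dimnames = list(rn, "s1"))
  pool <- data.frame(genome_id = c("gA", "gB"),
                     taxonomy = c(tax("Bacteria", "G1", "S1"),
                                  tax("Bacteria", "G2", "S2")))
  expect_warning(mock <- match_taxa_to_heldout(profile, pool,
                                               min_retained = 0.9),
                 "matchable")
  # all Bacteria rows match at least at domain level; Archaea row cannot
  expect_equal(mock$retained_fraction, (10 + 20 + 5 + 25) / 100)
  expect_equal(sum(mock$abundances), 60)
  expect_error(match_taxa_to_heldout(profile, pool, min_retained = 0.9,
                                     on_low = "error"), "matchable")
})

test_that("gold standard follows the copy-number-weighted contract", {
  mock <- list(genome_ids = "g1",
               abundances = matrix(2, 1L, 1L,
                                   dimnames = list("g1", "s1")))
  ann <- trait_table(matrix(5, 1L, 1L, dimnames = list("g1", "K1")), "KO")
  gs <- build_gold_standard(mock, ann, c(g1 = 1))
  expect_equal(gs$gold_standard["K1", "s1"], 10)
  # identical sample compositions give identical gold columns
  mock2 <- list(genome_ids = c("g1", "g2"),
                abundances = matrix(c(2, 3, 2, 3), 2L, 2L,
                                    dimnames = list(c("g1", "g2"),
                                                    c("s1", "s2"))))
  ann2 <- trait_table(matrix(c(5, 1, 0, 2), 2L, 2L,
                             dimnames = list(c("g1", "g2"),
                                             c("K1", "K2"))), "KO")
  gs2 <- build_gold_standard(mock2, ann2, c(g1 = 2, g2 = 1))
  expect_equal(gs2$gold_standard[, "s1"], gs2$gold_standard[, "s2"])
})

test_that("gold standard matches a dense triple-loop oracle", {
  set.seed(31)
  ids <- paste0("g", 1:4)
  mock <- list(genome_ids = ids,
               abundances = matrix(runif(8, 1, 50), 4L, 2L,
                                   dimnames = list(ids, c("s1", "s2"))))
  ann <- trait_table(matrix(rpois(12, 3), 4L, 3L,
                            dimnames = list(ids, paste0("K", 1:3))), "KO")
  cp <- setNames(sample(1:5, 4L, replace = TRUE), ids)
  gs <- build_gold_standard(mock, ann, cp)
  for (s in c("s1", "s2")) for (f in paste0("K", 1:3)) {
    acc <- 0
    for (g in ids)
      acc <- acc + mock$abundances[g, s] / cp[[g]] * unclass(ann)[g, f]
    expect_equal(gs$gold_standard[f, s], acc, tolerance = 1e-12)
  }
  expect_error(build_gold_standard(mock, subset_trait <- trait_table(
    unclass(ann)[1:3, , drop = FALSE], "KO"), cp), "g4")
})

test_that("Spearman handles identity, anti-ranks, and ties like the oracle", {
  x <- c(1, 2, 2, 3, 5)
  expect_equal(spearman_per_sample(x, x), 1.0)
  y <- c(5, 4, 3, 2, 1)
  expect_equal(spearman_per_sample(y, rev(y)), -1.0)
  set.seed(32)
  for (i in 1:100) {
    a <- sample(0:5, 10L, replace = TRUE)
    b <- sample(0:5, 10L, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_per_sample(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_warning(r <- spearman_per_sample(rep(1, 5), x), "zero-variance")
  expect_true(is.na(r))
})

test_that("Bray-Curtis matches hand values and the vegan oracle", {
  expect_equal(bray_curtis_per_sample(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis_per_sample(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis_per_sample(c(1, 2, 3), c(3, 2, 1)), 1 / 3)
  skip_if_not_installed("vegan")
  set.seed(34)
  for (i in 1:100) {
    a <- runif(8, 0, 10); b <- runif(8, 0, 10)
    expect_equal(bray_curtis_per_sample(a, b), oracle_bray_curtis(a, b),
                 tolerance = 1e-12)
  }
  expect_warning(r <- bray_curtis_per_sample(c(0, 0), c(0, 0)),
                 "all-zero")
  expect_true(is.na(r))
})

test_that("Bray-Curtis ranking is invariant under common rescaling", {
  set.seed(35)
  a1 <- runif(10); b1 <- runif(10)
  a2 <- runif(10); b2 <- runif(10)
  d1 <- bray_curtis_per_sample(a1, b1)
  d2 <- bray_curtis_per_sample(a2, b2)
  expect_equal(bray_curtis_per_sample(7 * a1, 7 * b1), d1,
               tolerance = 1e-12)
  expect_equal(sign(d1 - d2),
               sign(bray_curtis_per_sample(3 * a1, 3 * b1) -
                      bray_curtis_per_sample(3 * a2, 3 * b2)))
})

mk_eval <- function(rho, bc, wn, ds = "d1") {
  structure(data.frame(sample = paste0("s", seq_along(rho)),
                       spearman_rho = rho, bray_curtis = bc,
                       weighted_nsti = wn, dataset = ds,
                       stringsAsFactors = FALSE),
            class = c("evaluation", "data.frame"))
}

test_that("comparing an evaluation with itself is a clean null", {
  set.seed(36)
  ev <- mk_eval(runif(10, 0.6, 0.9), runif(10, 0.1, 0.4),
                runif(10, 0, 0.3))
  cmp <- compare_databases(ev, ev)
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))
  expect_equal(cmp$median_a, cmp$median_b)
})

test_that("a consistent shift is flagged significant, matching t.test", {
  set.seed(37)
  rho <- runif(20, 0.5, 0.8)
  ev_a <- mk_eval(rho, runif(20, 0.2, 0.4), runif(20, 0, 0.3))
  ev_b <- ev_a
  ev_b$spearman_rho <- rho + 0.1 + rnorm(20, 0, 0.01)
  cmp <- compare_databases(ev_a, ev_b)
  row <- cmp[cmp$metric == "spearman_rho", ]
  expect_true(row$significant)
  expect_equal(row$p_value,
               t.test(ev_a$spearman_rho, ev_b$spearman_rho,
                      paired = TRUE)$p.value, tolerance = 1e-12)
  # medians equal the sorted-middle oracle
  sorted <- sort(ev_b$spearman_rho)
  expect_equal(row$median_b, mean(sorted[10:11]), tolerance = 1e-12)
})

test_that("sample mismatch is an error listing the difference", {
  ev_a <- mk_eval(c(0.7, 0.8), c(0.2, 0.3), c(0.1, 0.1))
  ev_b <- mk_eval(c(0.7, 0.8, 0.9), c(0.2, 0.3, 0.4), c(0.1, 0.1, 0.2))
  expect_error(compare_databases(ev_a, ev_b), "s3")
})

test_that("held-out mock genomes are truly absent from the reference", {
  w <- toy_world()
  ref_tips <- unlist(lapply(w$db$domains, function(d) d$tree$tip.label))
  expect_length(intersect(w$mock$genome_ids, ref_tips), 0L)
})
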
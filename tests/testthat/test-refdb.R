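# Reference-database construction: quality filtering, tree pruning,
# framework registration.

test_that("filter_genomes applies inclusive boundaries and drops below them", {
  rec <- toy_records(3L)
  rec$contamination <- c(10.0, 1, 1)
  rec$completeness <- c(90.0, 89.9, 95)
  kept <- filter_genomes(rec)
  # boundary genome (exactly 10% contamination, 90% completeness) kept
  expect_true("g01" %in% kept$genome_id)
  # 89.9% completeness is below threshold
  expect_false("g02" %in% kept$genome_id)
  expect_true("g03" %in% kept$genome_id)
  rej <- attr(kept, "rejections")
  expect_equal(rej$reason[rej$genome_id == "g02"], "completeness")
})

test_that("filter_genomes keeps 3 of 6 over a contamination ladder", {
  rec <- toy_records(6L)
  rec$contamination <- c(0, 5, 10, 11, 20, 50)
  kept <- filter_genomes(rec)
  expect_equal(kept$genome_id, c("g01", "g02", "g03"))
  # order preserved, and re-filtering is a no-op (idempotence)
  expect_equal(filter_genomes(kept)$genome_id, kept$genome_id)
})

test_that("filter_genomes respects flags and ssu quality, empty in empty out", {
  rec <- toy_records(4L)
  rec$is_representative[1L] <- FALSE
  rec$in_domain_tree[2L] <- FALSE
  rec$ssu[3L] <- NA_character_
  kept <- filter_genomes(rec)
  expect_equal(kept$genome_id, "g04")
  counts <- attr(kept, "counts")
  expect_equal(unname(counts[c("not_representative", "not_in_tree",
                               "low_quality_ssu")]), c(1L, 1L, 1L))
  expect_equal(nrow(filter_genomes(rec[0L, ])), 0L)
})

test_that("malformed percent is rejected with the record named", {
  rec <- toy_records(2L)
  rec$completeness[2L] <- 150
  expect_error(filter_genomes(rec), "g02")
})

test_that("validate_ssu checks presence, length, and ambiguity", {
  th <- quality_thresholds(min_ssu_length = 1200,
                           max_ssu_ambiguous_frac = 0.01)
  expect_false(validate_ssu(NA_character_, th))
  expect_true(validate_ssu(paste(rep("ACGTA", 300L), collapse = ""), th))
  # 1300 nt with 10% N exceeds the 1% ambiguity allowance
  s <- paste0(paste(rep("A", 1170L), collapse = ""),
              paste(rep("N", 130L), collapse = ""))
  expect_false(validate_ssu(s, th))
  expect_error(validate_ssu("ACGTXXACGT", th), "non-IUPAC")
})

test_that("filter monotonicity: relaxing thresholds never loses genomes", {
  set.seed(11)
  rec <- toy_records(40L)
  rec$contamination <- runif(40L, 0, 30)
  rec$completeness <- runif(40L, 70, 100)
  prev <- -1L
  for (mc in c(2, 5, 10, 20, 30)) {
    n <- nrow(filter_genomes(rec, quality_thresholds(
      max_contamination = mc, min_completeness = 90)))
    expect_gte(n, prev); prev <- n
  }
  prev <- -1L
  for (comp in c(99, 95, 90, 80, 70)) {
    n <- nrow(filter_genomes(rec, quality_thresholds(
      max_contamination = 10, min_completeness = comp)))
    expect_gte(n, prev); prev <- n
  }
})

test_that("manifest counts sum to the input count", {
  set.seed(12)
  rec <- toy_records(30L)
  rec$contamination <- runif(30L, 0, 30)
  rec$completeness <- runif(30L, 70, 100)
  rec$is_representative <- runif(30L) > 0.2
  kept <- filter_genomes(rec)
  counts <- attr(kept, "counts")
  expect_equal(sum(counts[-1L]), unname(counts["input"]))
  expect_equal(nrow(kept) + nrow(attr(kept, "rejections")), 30L)
})

test_that("build_reference prunes trees isometrically", {
  w <- toy_world()
  # pairwise distances among database tips match the original full tree
  for (d in names(w$db$domains)) {
    pruned <- w$db$domains[[d]]$tree
    orig <- w$truth$trees[[d]]
    tips <- pruned$tip.label
    expect_true(all(tips %in% orig$tip.label))
    Dp <- ape::cophenetic.phylo(pruned)[tips, tips]
    Do <- ape::cophenetic.phylo(orig)[tips, tips]
    expect_equal(Dp, Do, tolerance = 1e-9)
  }
})

test_that("caterpillar pruning matches a traversal oracle", {
  tree <- ape::read.tree(
    text = "(((g1:0.1,g2:0.2):0.3,g3:0.4):0.5,g4:0.6);")
  keep <- c("g1", "g3", "g4")
  pruned <- ape::keep.tip(tree, keep)
  Do <- oracle_node_dists(tree)
  idx <- match(keep, tree$tip.label)
  Dp <- ape::cophenetic.phylo(pruned)[keep, keep]
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(Dp[keep[i], keep[j]], Do[idx[i], idx[j]],
                 tolerance = 1e-12)
})

test_that("build_reference with all tips surviving keeps the tree intact", {
  w <- recovery_world()
  cfg <- w$config
  # retained-mode world: db was built from all non-held-out tips; check
  # trait rows == tree tips == ssu entries in every domain
  for (d in names(w$db$domains)) {
    dd <- w$db$domains[[d]]
    for (f in names(dd$traits))
      expect_setequal(rownames(dd$traits[[f]]), dd$tree$tip.label)
    expect_setequal(names(dd$ssu), dd$tree$tip.label)
    expect_true(all(dd$tree$edge.length >= 0))
  }
})

test_that("a surviving genome missing from a trait table is a hard error", {
  w <- toy_world()
  tr <- w$db$domains$bacteria$tree
  ko <- unclass(w$truth$traits)
  ssu <- unclass(w$db$domains$bacteria$traits[["16S"]])
  meta <- w$truth$metadata
  meta <- meta[meta$genome_id %in% tr$tip.label, ]
  broken <- trait_table(ko[setdiff(rownames(ko), tr$tip.label[1L]), ,
                           drop = FALSE], "KO")
  expect_error(
    build_reference(list(bacteria = tr),
                    list(KO = broken,
                         `16S` = w$db$domains$bacteria$traits[["16S"]]),
                    setNames(meta$ssu, meta$genome_id), meta),
    tr$tip.label[1L])
})

test_that("add_user_framework registers, refuses overwrite, names gaps", {
  w <- toy_world()
  db <- w$db
  tips <- unlist(lapply(db$domains, function(d) d$tree$tip.label))
  zero <- trait_table(matrix(0, length(tips), 1L,
                             dimnames = list(tips, "Z00001")), "ZZ")
  db2 <- add_user_framework(db, zero)
  expect_true("ZZ" %in% db2$manifest$frameworks)
  expect_true(all(unclass(db2$domains$bacteria$traits$ZZ) == 0))
  # re-adding is an error
  expect_error(add_user_framework(db2, zero), "already registered")
  # a table covering only one domain fully is registered for that domain
  bac_tips <- db$domains$bacteria$tree$tip.label
  bac_only <- trait_table(matrix(1, length(bac_tips), 1L,
                                 dimnames = list(bac_tips, "B1")), "BO")
  db3 <- add_user_framework(db, bac_only)
  expect_true("BO" %in% names(db3$domains$bacteria$traits))
  expect_false("BO" %in% names(db3$domains$archaea$traits))
  # a gap in every domain is an error naming a missing genome
  drop1 <- c(db$domains$bacteria$tree$tip.label[1L],
             db$domains$archaea$tree$tip.label[1L])
  gap <- trait_table(matrix(1, length(tips) - 2L, 1L,
                            dimnames = list(setdiff(tips, drop1), "Z1")),
                     "GAP")
  expect_error(add_user_framework(db, gap), drop1[1L])
})

test_that("an all-zero user framework predicts zero downstream", {
  w <- toy_world()
  tips <- unlist(lapply(w$db$domains, function(d) d$tree$tip.label))
  zero <- trait_table(matrix(0, length(tips), 2L,
                             dimnames = list(tips, c("Z1", "Z2"))), "ZZ")
  db2 <- add_user_framework(w$db, zero)
  res <- run_prediction(db2, w$query_seqs, w$feature_table,
                        frameworks = "ZZ")
  expect_true(all(res$metagenomes$ZZ$values == 0))
})
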
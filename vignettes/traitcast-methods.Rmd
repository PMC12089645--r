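---
title: "traitcast: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{traitcast: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitcast)
```

This vignette is the package's own account of its science: the model
behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The prediction model

Reference-based functional prediction rests on one assumption:
**gene content is phylogenetically conserved**, so an organism's
gene-family copy numbers can be estimated from the annotated genomes
nearest to it on a phylogeny. The package implements the full chain:

* a **reference database** per domain — an unrooted phylogeny whose
  tips are quality-filtered, fully annotated genomes, with their 16S
  sequences and one trait table per annotation framework (KO, EC, …;
  the 16S copy number is a distinguished single-column framework);
* **placement** of each query ASV into *both* domain trees, keeping
  the domain with the lowest NSTI;
* **hidden-state prediction** of trait values at the attachment point;
* a **predicted metagenome**, `M[s,f] = Σ_i a[i,s]/c[i] · g[i,f]`.

### Placement and NSTI

True likelihood placement (HMM alignment + EPA) is deliberately out of
scope; the package uses a desk-scale substitute: ungapped pairwise
comparison against every reference 16S (global alignment via
Biostrings only when lengths differ), a Jukes–Cantor corrected
distance, and grafting at the nearest tip with the corrected distance
as pendant length. The placement interface (`placement` objects with
an attachment edge, distal position and pendant length) is
representation-complete, so a likelihood-based backend could be
swapped in without touching anything downstream. Consequences of the
substitute:

* NSTI for a nearest-tip placement reduces to the pendant length;
  `compute_nsti()` still implements the general
  min-over-tips-from-the-attachment-point definition and is checked
  against a brute-force path oracle.
* Distances with `p >= 0.75` are saturated and undefined; queries
  saturated against a whole domain are *unplaceable in that domain*,
  which is the normal situation for the other domain's tree and is
  therefore only summarised, never warned per query.
* Comparisons need at least 50 informative (both-ACGT) positions;
  below that the query is unplaceable.
* Ties — equidistant nearest tips, or equal NSTI across domains — are
  broken deterministically (lexicographically smaller genome id;
  bacteria).

### Hidden-state prediction

Two methods, chosen per trait table:

* **Sankoff maximum parsimony** (`mp`, the default for all-integer
  tables): minimum-change reconstruction with linear cost `|a − b|`
  over the observed integer state range of each trait, computed with a
  min-plus distance transform so each node costs O(states). The query
  tip carries a zero cost vector, so its value equals the reconstructed
  state of its parent; among co-optimal states the smallest wins,
  making results platform-independent. Polytomies are binarised
  deterministically (`ape::multi2di(random = FALSE)`). Traits whose
  range exceeds 64 states fall back to distance weighting with a
  notice.
* **Inverse-distance weighting** (`dw`, used for 16S copy numbers and
  any non-integer table): `x̂ = Σ w_k x_k / Σ w_k`,
  `w_k = 1/(d_k + 1e-9)`, with `d_k` the tree distance from the
  attachment point (pendant excluded) to tip `k`.

**Exact-reference shortcut.** A query whose attachment coincides with
a reference tip (zero pendant) receives that tip's observed values
under *both* methods. For `dw` this is the natural `d = 0` limit; for
`mp` it is a deliberate override of the backtracking convention:
with linear costs, any state between the matched tip's value and the
neighbouring clade's pull can be co-optimal at the parent node, and
the smallest-state tie-break would then discard information we
actually possess — the genome is *in* the database. The override is
what makes the perfect-recovery limit exact (acceptance criterion 3).

Predicted 16S copy numbers are clamped to ≥ 1: every genome that
amplifies at all has at least one copy.

### Metagenome assembly

Counts are divided by predicted 16S copy number, multiplied through
the predicted gene content, and summed per sample. Raw counts — not
relative abundances — are used both here and in the per-sample
abundance-weighted NSTI; the literature convention is raw-count
weighting and the two give identical Spearman/Bray–Curtis per sample
(both metrics are scale-free per sample). ASVs with NSTI above
`max_nsti` (default 2.0 substitutions/site, the long-standing
convention for discarding unpredictable placements) are excluded and
reported.

## 2. Reference database construction

Genomes pass the filter when they are representative, present in
their domain's tree, carry a high-quality 16S gene, and have
contamination ≤ 10% and completeness ≥ 90% — both boundaries
inclusive, exactly as the thresholds are printed. Each rejected genome
receives a single reason (checked in a fixed order:
`not_representative`, `not_in_tree`, `low_quality_ssu`,
`contamination`, `completeness`), so the manifest's per-stage counts
always sum to the input count.

The criteria behind "high-quality 16S" are not standardised; the
package uses explicit, configurable stand-ins — length ≥ 1200 nt
(a near-full-length gene) and ≤ 1% ambiguous bases — recorded in the
manifest. **These are package defaults, not a reproduction of any
specific pipeline's supplementary criteria.** Multiple 16S copies per
genome are out of scope: the database stores one sequence per genome.

Pruning a domain tree to the surviving genomes merges the branch
lengths of removed unifurcations additively, so pairwise distances
among survivors are unchanged (tested to 1e-9). Trait tables treat
zero and absent identically — most gene families are absent from most
genomes.

## 3. The synthetic world

The generator is a stated world, not a tuning dial; its defaults are
fixed and the tests run against them.

| parameter | default | why |
|---|---|---|
| tips per domain | 50 bacteria / 20 archaea | smallest sizes where placement, domain choice and pruning are non-trivial |
| tree depth | 0.3 subst/site | typical within-domain 16S divergence scale |
| gene families | 20, root copies ~ Poisson(2) | enough for rank metrics; realistic sparsity (many zeros) |
| gain/loss rate | 2 per unit branch | visible phylogenetic signal without saturation |
| 16S copies | root 4, rates 0.5, floor 1 | real genomes carry ~1–15 copies, conserved |
| sequence length | 1500 nt, 1 subst/site/unit | full-length 16S; JC dynamics |
| samples | 10, log-normal(4, 1) | typical spread of microbial abundances |
| held-out fraction | 20% | enough mock genomes, database stays dense |

Trees are pure-birth (Yule) — simpler than coalescent models and
sufficient for phylogenetic signal. Sequences evolve under a single
substitution rate with no rate heterogeneity and **no indels**, which
keeps the placement-accuracy property analytically checkable (the
expected p-distance between two tips is `3/4(1 − e^{−4d/3})`).
Traits evolve by independent Poisson gain/loss walks floored at 0
(16S at 1).

What a green test therefore does *not* establish: robustness to
chimeras, indels, variable-region primers, rate heterogeneity across
sites or lineages, horizontal transfer of gene families (trait
evolution here is strictly tree-like), or realistic genome sizes.
Those are properties of real data the generator deliberately does not
emulate.

`extend_divergence()` pushes every mock genome further from the
reference along an extra branch of length δ — sequences, gene content
and 16S copies all evolve onward, and the gold standard is rebuilt.
Tiers of δ (0.05, 0.2, 0.5 in the acceptance suite) create the
degradation ladder on which weighted NSTI must rise and Spearman ρ
must fall: the property underlying the claim that a closer reference
yields better predictions.

## 4. Benchmarking choices

* **Gold standard**: `gold[f,s] = Σ_g ann[g,f] · a[g,s] / c_g` — the
  same copy-number weighting the predictor applies, but with true
  annotations and true copy numbers. Dividing by the true 16S copy
  number is the default (`normalize = TRUE`) so that predictor and
  gold standard share one contract; the switch exists because the
  choice is genuinely open when comparing against externally built
  profiles.
* **Metric vectors** are taken over the union of function ids with
  absent = 0, penalising false positives and false negatives
  symmetrically.
* **Spearman** uses average ranks for ties; **Bray–Curtis** is
  `Σ|p−g| / Σ(p+g)`. Zero-variance or all-zero profiles yield `NA`
  with a warning rather than a fabricated value.
* **Taxonomy matching** of community profiles to held-out genomes
  proceeds from species up to domain, taking the deepest rank with any
  match and breaking ties towards the lexicographically smaller genome
  id; unmatched taxa are dropped with the retained abundance fraction
  reported (warning below 50%, configurable to an error).
* **Database comparisons** use two-sided paired t-tests per dataset
  and metric, flagged at P ≤ 0.05, without multiple-testing
  correction (matching the reporting convention of database-upgrade
  studies). Exactly identical evaluations have zero spread, where the
  t statistic is undefined; the package reports p = 1 (no evidence of
  difference) in that degenerate case.

## 5. Numerical and reproducibility notes

* All randomness flows from one integer seed; generators use R's
  Mersenne-Twister and derive sub-seeds below 2^31. Identical configs
  give byte-identical outputs, and the CLI writes no timestamps into
  output files (logs go to stderr) so repeated runs into the same path
  are bit-reproducible.
* Sankoff uses a large finite sentinel (1e18) instead of Inf in DP
  tables; costs are exact integers within double precision.
* Distance comparisons use a 1e-12 tolerance for "exactly at a tip";
  pruning isometry and Newick round-trips are tested at 1e-9.
* Metagenome TSV outputs are written with 6 significant digits;
  internal arithmetic is double precision throughout.
* gzipped TSVs are read through base `gzfile()` connections (fread's
  gz path needs an optional package) and written by `data.table`,
  whose gzip output embeds no timestamp.

## 6. Known limitations

* Nearest-tip placement ignores alignment uncertainty and can
  misattach queries between very short sister branches; ties are
  broken lexicographically, which is deterministic but arbitrary.
* NSTI from JC-corrected 16S distance and NSTI from tree branch
  lengths agree only insofar as the reference branch lengths are on a
  comparable substitutions/site scale (true in the synthetic world by
  construction; approximately true for marker-gene trees).
* Sankoff parsimony treats all branches equally (no branch-length
  weighting) — the classic minimum-change model, not ML.
* The per-ASV stratified output holds one function × sample matrix
  per ASV in memory; it is off by default for that reason.
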
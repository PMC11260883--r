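---
title: "Auditing DNA barcoding gaps: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DNA barcoding gaps: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

# The problem

DNA barcoding identifies specimens by comparing a short mitochondrial
marker (for animals, usually a fragment of the cytochrome c oxidase I
gene, COI) against a reference library. The approach is only trustworthy
where a *barcoding gap* exists:

* A **local barcoding gap** is a per-species property: the smallest K2P
  distance between the focal species and any congener exceeds the largest
  distance found within the species. When it holds, an unknown sequence
  falling near the species' haplotypes cannot be confused with a
  neighbour. The rule here is strict (`min_inter > max_intra`); a tie, or
  a haplotype shared with another species (which forces `min_inter = 0`),
  means no gap.
* A **global barcoding gap** is a per-genus property used for flagging
  provisional species: the distribution of intraspecific distances and the
  distribution of interspecific distances do not overlap. When a gap is
  present, its magnitude `mean_inter / mean_intra` is compared against a
  rule multiplier — classically 10x, though in groups with shallow
  interspecific divergence a ~5x working threshold can be more
  appropriate. Both multipliers are evaluated by default.

`barcodegap` implements the whole audit as composable stages —
ingestion/QC, haplotype collapsing, distances, gap detection, a sample-size
pilot, dataset comparison, distance-based delimitation, and taxonomy
concordance — plus a simulator that generates genera with known truth so
that every stage can be validated without any sequence download.

# Units of analysis: N~H~ and N~S~

Barcoding studies traditionally remove redundant haplotypes before
computing distances; but doing so re-weights the species' gene pool (a rare
divergent haplotype counts as much as a common one), while keeping all
sequences deflates intraspecific means when one haplotype dominates. The
package therefore carries **two parallel dataset views** through the whole
analysis:

* `NH`: one representative per unique haplotype, for species with at least
  `min_n_h` haplotypes (default 6);
* `NS`: every sequence, redundancy retained, for species with at least
  `min_n_s` sequences (default 12).

In either view a genus is analysed only when at least
`min_species_per_genus` (default 4) species qualify — with fewer species a
"minimum distance to a congener" is close to meaningless. The defaults
come from the sample-size pilot (below) and are fully configurable via
`inclusion_config()`. A species can qualify in one view only; report
tables therefore also show the union ("total examined"), where a species
counts as having a local gap if it has one in *either* view, with
view-discrepant species flagged.

Haplotype collapsing groups sequences with **zero countable differences**:
no alignment column where both sequences carry unambiguous, different
nucleotides. Missing data make this relation non-transitive (`ACGT` ~
`ACGN` ~ `ACGA`, yet `ACGT` differs from `ACGA`), so groups are closed
transitively with union-find — deterministic and order-independent — and a
warning is raised whenever a chain merges sequences that differ at
mutually masked sites. The representative is the member with the most
non-missing characters, ties broken by smallest id, so outputs are
reproducible. Multiplicities are preserved: expanding every haplotype by
its multiplicity always reconstitutes N~S~.

# Distances

Distances use the Kimura two-parameter model with uniform rates, the
standard choice in barcoding because the original barcoding literature
used it and most reference thresholds are quoted on that scale. For a
sequence pair, comparable sites are the columns where *both* sequences
carry `A`, `C`, `G` or `T` (pairwise deletion); with transition fraction
$P$ and transversion fraction $Q$ over those sites,

$$ d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big). $$

Design choices worth knowing:

* **Partial IUPAC ambiguities (R, Y, ...) are never comparable sites.**
  This is the strictest defensible reading of pairwise deletion; tools
  that resolve ambiguities fractionally can differ slightly on low-quality
  data. (They count as *present* for trimming coverage, since they do
  carry information about sequence extent.)
* **Saturated pairs are masked, not capped.** When no site is comparable
  or a logarithm argument is non-positive the pair is *inapplicable*;
  downstream statistics skip masked pairs and report how many were
  skipped. Substituting an arbitrary large distance would manufacture
  extremes in exactly the statistics (maxima, minima) the gap rules use.
* Distances are kept in substitutions/site internally and rendered as
  percentages (1 decimal) only in report tables; threshold ratios are
  computed from full-precision means, so a printed ratio is not generally
  recomputable from the printed rounded means.

The test suite verifies the implementation against `ape::dist.dna(model =
"K80", pairwise.deletion = TRUE)` to 1e-12 on fixtures with missing data
and ambiguities; `ape` is used only as an oracle, never as the
implementation, so the masking and site-accounting contracts stay
explicit.

For the global gap the intra/inter distributions are, by default, one mean
per species and one mean per species pair (`pooling = "species_means"`),
matching reports that quote a single genus-level mean per dataset; set
`pooling = "raw_pairs"` to pool all pairwise distances instead. On
balanced designs the two agree; under very uneven sampling they can
differ, which is why the switch exists.

# Minimum sample sizes: the pilot

Estimating a species' intraspecific distance distribution from two or
three sequences is hopeless; demanding fifty excludes almost everything.
`subsample_curve()` quantifies the trade-off: the full dataset of a deeply
sampled species provides a benchmark mean distance treated as the truth,
and random subsamples (default 10 replicates per size, without
replacement) show how fast estimates converge. `select_minimum()`
formalizes "accurate enough" as the smallest size with mean absolute
relative deviation and relative sd of replicate means both at most 10%.
Visual plateau inspection is the field's usual practice; an explicit
dual-tolerance rule was chosen so that runs are reproducible and the
criterion is configurable rather than implicit in a reader's eye. At the
full sample size the curve is exactly zero in both criteria — a
correctness check, not an approximation.

# Comparing the two views

Whether the N~H~/N~S~ choice changes conclusions is tested directly: the
per-species mean intraspecific distances (and the per-pair mean
interspecific distances) of the two views are compared with a
randomization analogue of a two-group one-way ANOVA. Labels are permuted
uniformly (default 10,000 iterations) and the add-one p-value
$(1 + \#\{F^{perm} \ge F^{obs}\})/(1 + N)$ is reported; when the number of
distinct assignments is at most 50,000 they are enumerated exhaustively
instead. The two views are treated as independent groups; a paired design
would be possible for the species present in both views but would silently
drop the others, so the unpaired form was kept. Null calibration
(rejection rate at 0.05 within [0.03, 0.08] across 500 null datasets) is
asserted in the acceptance suite.

# Species delimitation and concordance

To understand *why* species lack gaps, each genus' unique-haplotype view
is re-partitioned from the distance matrix alone. Candidate partitions
come from a single-linkage sweep — one partition per distinct merge
height, i.e. every clustering a distance threshold can produce. Each
partition with $2 \le k < n$ clusters is scored by two metrics in the
average-rank style of automatic-partitioning methods:

* relative gap width
  $W = \max\!\big(0, (\min d_{between} - \max d_{within}) / \bar d\big)$,
  scale-invariant by construction;
* a panmixia probability: the add-one permutation probability that random
  reassignment of sequences to clusters of the same sizes gives a
  mean-within / mean-between ratio at most the observed one.

Partitions are ranked by the average of the two metric ranks (ties get
average ranks); lower is better. Selection excludes implausibly fine
partitions (`n_clusters > 0.9 n`, i.e. nearly one species per sequence —
the 0.9 cap is this package's concrete stand-in for a qualitative
"plausible ranking" judgement), and score ties go to the partition
delimiting fewer species. These formulas are documented stand-ins at the
level of description above, not a reimplementation of any published tool's
internals; partitions produced by external software (ASAP, mPTP, ...) can
be imported with `import_partition()` and fed to the same concordance
stage.

Each recognized species is then classified against the selected (or
imported) partition into exactly one of five categories: *perfect
taxonomy*, *pure undersplit*, *impure undersplit*, *pure oversplit*,
*impure oversplit* — "pure" meaning a simple naming or synonymy change
would reconcile taxonomy with the partition. One corner case is worth
stating: a species that is both split across clusters *and* shares a
cluster with another species is an impure undersplit (the split takes
precedence). The acceptance suite proves exhaustiveness and mutual
exclusivity by brute force over all 203 set partitions of six elements
against independent per-category predicates.

# The simulator

`simulate_genus()` generates the data structure the audit assumes: a genus
root sequence (uniform over ACGT), species ancestors evolved from it to
expected depth `inter_depth`, haplotypes evolved from each ancestor to
expected depth `intra_depth`, all under the two-rate Markov process with
transition/transversion ratio `kappa` (default 2.0) whose stationary
estimator *is* the K2P distance — a model-consistent design, so estimator
bias never masquerades as simulator error. Redundant sampling multiplies
haplotypes into sequences (default: 1 + Poisson(1) copies each, a
realistic skew where most haplotypes are seen once or twice), verbatim
haplotype sharing between chosen species pairs reproduces the
shared-barcode failure mode, and optional missing end-blocks (`N` runs up
to 10% of the alignment at each end) emulate untrimmed alignment margins.

Default depths are `intra_depth = 0.01` and `inter_depth = 0.05`
substitutions/site — a 5x separation regime typical of genera where
barcoding is expected to work. Under the star phylogeny the closed-form
expectations are `2 * intra_depth` for the mean intraspecific distance and
`2 * (inter_depth + intra_depth)` for the interspecific one;
`expected_summaries()` returns them with a 15% Monte-Carlo tolerance band.

What the simulator deliberately does **not** model: coalescent genealogy
within species (a star tree has no shared internal branches, so simulated
intraspecific distance distributions are narrower than real ones),
selection, recombination, rate heterogeneity among sites, and nuclear
pseudogenes. Passing tests on simulated data therefore demonstrate that
the *pipeline arithmetic and decision rules* are correct under the stated
model — not that real crayfish-like datasets will show gaps; on real data
the difficult parts are precisely the features the simulator idealizes
away.

# Numerical and reproducibility choices

* Merge heights within 1e-12 are treated as tied in the single-linkage
  sweep; sequences are ordered lexicographically by id before clustering
  so tie-breaking is deterministic.
* A partition's cut height is the height of the first merge it refuses
  (cutting the dendrogram just below that merge), so a two-cluster
  partition of two tight groups carries the between-group height.
* Every stochastic stage takes an explicit seed; `run_full_analysis()`
  derives per-stage sub-seeds from one master seed and records them in the
  run log. Reruns with the same configuration are byte-identical, which is
  asserted in the tests.
* Percentages in report tables are rounded half-up to integers, distances
  to one decimal in percent units, matching the usual printed style of
  barcoding audits.
* Problem sizes used in the automated checks (5 species x 8 haplotypes per
  genus, 100-seed gap-recovery loops, 500 null datasets for calibration,
  alignment length 600 bp) were chosen as the smallest sizes at which the
  binomial/Monte-Carlo noise of each property is comfortably below the
  asserted margins.

This package exposes its functionality as documented R functions and this
vignette rather than a shell executable; `run_full_analysis()` plus
`write_genus_dataset()`/TSV exports cover scripted use end to end.

# A worked sketch

```{r example, eval = FALSE}
cfg <- sim_config(genus = "Demo", n_species = 5, haplotypes_per_species = 8,
                  intra_depth = 0.01, inter_depth = 0.05,
                  shared_haplotype_pairs = list(c(1, 2)))
sim <- simulate_genus(cfg, seed = 42)
run <- run_full_analysis(sim$dataset,
                         inclusion = inclusion_config(4, 8, 4),
                         seed = 42)
run$local_table        # species 1 and 2 lack gaps (shared haplotype)
run$gap_table          # genus means, gap flag, threshold ratio
run$concordance_table  # the shared pair is pooled by delimitation
```

# Known limitations

* The countable-difference collapse rule can chain distinct haplotypes
  through heavy missing data; the warning should be taken seriously in
  datasets with many short fragments.
* The delimitation scores are this package's own formalization; absolute
  score values are not comparable with any external tool's output, only
  the selected partitions are (via `import_partition()` both can be run
  through the same concordance classifier).
* All inference is single-locus by construction; mitochondrial
  introgression, incomplete lineage sorting and misidentified reference
  material violate the audit's assumptions in ways no amount of
  distance arithmetic can detect.
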
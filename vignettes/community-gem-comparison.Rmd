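---
title: "Comparing reference-guided and MAG-guided community metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing reference-guided and MAG-guided community metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commgem)
```

## The problem

A community genome-scale metabolic model is assembled from per-organism
draft models and used to predict the metabolites a microbial community can
produce. When the starting point is shotgun metagenomics, the per-organism
genomes can come from two places: *reference genomes* of the species called
by a taxonomic profiler (chosen by mean relative-abundance cutoffs), or the
*metagenome-assembled genomes* (MAGs) binned from the same reads (chosen by
completeness/contamination tiers, dereplicated at high identity). The choice
changes the community model: reference genomes are complete but may not match
the strains actually present; MAGs match the sample but are incomplete and
possibly contaminated. `commgem` implements both selection strategies, the
compartmentalized merge, the downstream census/validation/enrichment
metrics, and a synthetic-data generator that reproduces the *statistical
structure* of such an experiment at desk scale, so every step of the
comparison is testable against exact oracles.

## The synthetic world

The generator does not simulate sequences. It simulates the objects the
modeling pipeline actually consumes, with these stated properties:

- **Universal catalog** (`generate_universal_network()`): compounds are
  partitioned into seed compounds (5%), a shared core block
  (`core_fraction`, default 0.15 of the non-seed compounds), and module
  compounds distributed over `n_accessory_modules` pathway-like modules.
  Each non-seed compound gets one irreversible backbone reaction consuming
  only earlier compounds of its own partition, which guarantees — by
  construction, not by retry — that every biomass precursor is reachable
  from the seeds. Transporters (one per seed compound, in the core; the rest
  drawn per organism) move a compound between its cytosolic and
  extracellular roles. Remaining reactions are random conversions assigned
  to modules; they may dead-end, which is what gives models nonzero
  blocked-reaction percentages. A fraction `ext_id_fraction` (default 0.7)
  of compounds carries a KEGG-style external id; the complement is what
  produces ~30% "data loss" downstream.
- **Organisms** are the core plus `n_modules_per_organism` sampled accessory
  modules plus a random share of non-core transporters; one gene per
  non-spontaneous reaction. Shared core + distinct modules is the minimal
  mechanism that makes cumulative unique-metabolite curves saturate, which
  is the qualitative regime of real communities (metabolic redundancy).
- **MAGs** (`simulate_mag()`) drop source genes uniformly to a target
  completeness (completeness applies to genes, and a dropped gene drops its
  reaction — the simplest faithful mechanism for incomplete bins), then add
  foreign genes from other community members until the foreign fraction
  reaches the target contamination: `f` is the largest integer with
  `100·f/(kept+f) ≤ contamination`. Realized percentages are recorded and
  quality tiers are classified from them, never recomputed from sequence.
- **Abundances** are per-sample log-normal weights normalized to 100
  (`lognormal_sigma` default 1.5). The field does not agree on an abundance
  law for these communities; log-normal is a modeling choice made once,
  not an inference. Two groups of 15 samples mirror a two-donor,
  30-sample design.
- **Metabolomics** (`simulate_metabolomics()`) has one row per true
  exometabolome compound, loses external ids at `id_loss_rate` (default
  0.3), adds `n_host_extras` rows with ids absent from the catalog
  (host/diet metabolites), gives a small fraction of rows a replicate id
  (two ids, one metabolite), and applies per-cell missingness while keeping
  at least one measurement per row — missingness models sample dropout, not
  detection failure.

What the generator does **not** emulate: read-level noise, assembly and
binning artifacts, chimeric bins beyond the gene-level contamination proxy,
annotation error, strain pangenome structure, or compositional correlation
between taxa. A green test therefore establishes that the *pipeline
arithmetic and algorithms* behave as specified on data with the right
shape — it does not validate biological accuracy of any real-world model.

## Draft models, merging, census

A draft model contains the genome's mapped reactions plus all spontaneous
catalog reactions. A biomass precursor is included iff the model has at
least one reaction able to produce it; the rule stands in for
subsystem-gated biomass composition, and a genome producing *no* precursor
is an error rather than a silent zero-growth model. Bounds are ±1000
(reversible) or 0..1000 — magnitudes cancel in blocked/feasible
classification. Reference genomes per species are strain variants of the
sample organism (gene retention `reference_strain_retention`; default 1,
i.e. exact — see "Design choices"), and the candidate with the most
features wins, ties broken by lexicographic id.

Merging relabels member internals `c1..cn` and rewires every transporter's
extracellular side to the shared pool `e0`; one secretion exchange per `e0`
compound is added. Census definitions: *total predicted* counts compound
instances per member (a compound exported by three members counts three) —
the only reading under which totals vastly exceed uniques and scale with
taxa; *extracellular* counts distinct `e0` instances; *unique* counts
distinct base compound ids, compartment stripped, which makes the
between-approach Venn comparisons well defined. The per-member/global
alternative for shared-compartment counting is implemented behind
`census(..., shared_counting = "global")` because the convention is
genuinely ambiguous; the default is recorded in every report.

## The flux core

FBA is the LP `max c'v` s.t. `S v = 0`, `l ≤ v ≤ u`, solved by a dense
bounded-variable two-phase primal simplex written for this package
(`src/simplex.cpp`) because no LP solver package is available in the target
environment. Numerical choices: feasibility/optimality tolerance 1e-9;
Dantzig pricing switching permanently to Bland's rule after a run of
degenerate steps (anti-cycling); all bounds finite by construction. The
steady-state residual of any accepted solution must be ≤ 1e-6. Solutions
are cross-checked in the test suite against an independent solver
(scipy/HiGHS) on random instances, including infeasible ones.

FVA minimizes and maximizes each reaction's flux; *blocked* means both
extremes within τ = 1e-9 of zero, computed **without** an objective
constraint (`fix_objective_fraction = 0`), since blocked means "cannot
carry flux in any feasible state". The per-reaction LP sequence is
warm-started from the previous basis, and a blocked-only mode additionally
skips reactions already seen carrying flux in any solution — both standard
FVA accelerations that change nothing about the classification (asserted in
tests against the exact two-LP brute force).

Gapfilling searches for a minimal set of catalog reactions restoring
biomass flux on the medium. At ≤ 12 candidates (`exhaustive_limit`) the
search is exhaustive and certified minimal; above that, a greedy
scope-expansion heuristic (prefer the candidate bringing the most missing
biomass precursors, then the most new compounds, into the producible scope)
runs first, is verified by FBA, and is pruned reverse-greedily. The greedy
result is near-minimal but not certified — the tests compare its
cardinality against power-set search on small instances. The default
medium opens every catalog seed compound at uptake 10 flux units; real
pipelines rarely state their media, so the default is declared, not
inferred. Gapfilling never removes reactions, so censuses are non-decreasing
under it; fold changes are reported as `round(post/pre, 2)`.

## Validation and enrichment

Metabolomics is collapsed to presence/absence per group (positive,
non-missing in ≥ 1 sample), and presence includes replicate ids: a
metabolite confirmed through any of its ids counts once. For a predicted
unique set, `mappable` are compounds with external ids,
`data_loss_pct = 100·(unique − mappable)/unique`,
`confirmed_pct = 100·confirmed/mappable`, both reported to two decimals
(half-up, the way summary tables print). The identity
`confirmed_pct = 100·confirmed/(unique·(1 − data_loss/100))` is what lets
printed tables be audited from their integer rows; `validation_report()`
accepts either form of the denominator.

Over-representation uses the cumulative hypergeometric upper tail
`P(X ≥ k)` with `N` the background size, `K` the pathway's members in the
background, `n` the mapped test-set size; q-values are Benjamini–Hochberg
step-up (implemented explicitly; cross-checked against `p.adjust`);
significance is strictly `q < 0.05`. The background in synthetic mode is
all external-id-mappable catalog compounds — a declared decision, since
web enrichment services do not state theirs.

One consequence at desk scale deserves emphasis: a 30-member community
covers most of a 300-compound catalog, so test sets approach the background
and ORA p-values are near 1 by construction. Real studies sit in the
opposite regime (a ~1,500-compound list against a database of many
thousands), where most covered pathways are significant. The enrichment
machinery — including the phenomenon that merging the two approaches'
lists can push a split pathway over the threshold, changing within-group
inferences — is therefore exercised on constructed low-coverage cases in
the test suite rather than on the default pipeline world.

## Design choices made where the design was open

- **Zero-filled means**: mean relative abundance averages over *all* group
  samples, counting undetected species as 0. Below-detection handling is
  not standardized; zero-fill matches "mean per group over all available
  samples" and is asserted in tests.
- **Tier boundaries**: high is strictly `completeness > 90` and
  `contamination < 5`; medium is `≥ 50` and `< 10` minus high; reported
  "high and medium" counts are unions.
- **Dereplication proxy**: declared ancestry in synthetic mode, gene-set
  Jaccard with single-linkage in file mode. Average nucleotide identity is
  deliberately out of scope; the representative is the most complete
  member.
- **Strain deviation default**: `reference_strain_retention = 1`. With
  retention 1, a reference genome is a superset of any zero-contamination
  MAG of the same organism, making the containment property (MAG-guided
  unique set ⊆ reference-guided unique set at matched taxa, gapfilling
  off) exact — the regime the acceptance suite asserts in 20/20 seeds.
  Retention < 1 emulates public genomes deviating from sample strains; it
  breaks strict containment, which is precisely the caveat real pipelines
  face, and is covered by its own test.
- **Seeds**: one run seed; every stage derives a child seed from
  `(seed, stage label)` via a documented integer hash (`derive_seed()`),
  so stages can be re-run in isolation and all derived seeds stay below
  2^31.
- **Degenerate inputs**: empty genomes, biomass with zero producible
  precursors, contamination without a donor pool, unknown groups, and
  unfillable models all raise classed errors (`commgem_*`) rather than
  returning partial objects; a fully excluded condition yields an explicit
  empty census, and selections carry a reason for every dropped taxon
  (feeding the "detected (used)" bracketed reporting convention).

## Known limitations

- The simplex is dense; community-scale FVA with exact ranges is O(2·n)
  warm-started LPs and is intended for per-organism models (hundreds of
  reactions), not for community matrices with tens of thousands of columns.
- Greedy gapfilling is uncertified above the exhaustive limit and its
  scope heuristic ignores compartments, so it can temporarily overshoot
  before pruning.
- Community FBA uses the summed member biomass as its default objective;
  abundance-weighted objectives and dynamic community simulation are out
  of scope.
- The synthetic world's enrichment regime differs from database-backed
  enrichment as described above; treat pipeline-level q-values as
  plumbing, not biology.

Every empirical number quoted in this vignette and the README is computed
by the package's own tests, examples or acceptance script.
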
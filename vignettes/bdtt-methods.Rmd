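---
title: "Methods: time-sliced beta-diversity, ancient-DNA authentication, diet inference and copy-number estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-sliced beta-diversity, ancient-DNA authentication, diet inference and copy-number estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coproscope)
```

This vignette is the package's own account of its methods: the models, the
parameters that matter, the numerical conventions, and the limits of what
the synthetic validation can show.

## Setting

A coprolite metagenome offers two kinds of evidence at once: host reads
(mitochondrial, nuclear) and gut-microbial reads. The package chains four
analyses that exploit both — authentication of taxon assignments by damage
signatures, decomposition of between-host microbiome dissimilarity over
bacterial evolutionary time, prediction of the host's dietary niche from
the microbiome, and estimation of a host gene's diploid copy number from
read depth. Each stage consumes plain tabular or Newick inputs and each has
a seeded synthetic generator producing data of known structure, so the
whole chain is testable end to end without sequence data.

## Trees, ages and slicing

Calibrated trees are `ape::phylo` objects whose node ages are derived from
branch lengths: the root age equals the maximum root-to-tip path length and
tips sit at age 0. Newick carries no age annotation, so deriving ages from
path lengths is the only self-contained convention. Trees whose tips spread
by more than a relative tolerance of `1e-6` of the root age are rejected
outright: slicing an approximately ultrametric tree silently shifts clade
boundaries, and refusing the input is the only failure mode a user can
diagnose. Tips passing the check are snapped to age exactly 0 so downstream
comparisons `parent_age > slice_age >= child_age` are exact.

`slice_tree(tree, age)` assigns every leaf to the branch its lineage
occupies at the slice age; age 0 gives one clade per leaf, ages at or above
the root give a single clade. Clade ids are contiguous integers; collapsing
a hosts-by-taxa table sums member-leaf counts, so per-host totals are
conserved at every age (a tested invariant).

## Dissimilarities

Sørensen dissimilarity works on presence/absence:
`1 − 2a/(2a + b + c)`. A host with an empty profile is at distance 1 from
every non-empty host and is reported via an attribute; two empty hosts are
given distance 0 (identical composition) — the case is degenerate either
way and the choice only needs to be stated. Unweighted UniFrac divides the
branch length unique to either host by the branch length subtending the
union of their taxa. On an equal-branch star the two are linked exactly by
`sorensen = unifrac / (2 − unifrac)`, which the tests use as a cross-check;
both are also verified against brute-force oracles (set arithmetic; full
branch enumeration) and against `vegan`/`picante`.

## Permutation inference

All tests in the package share three conventions:

* **Seeding.** Every routine takes an integer seed; composite procedures
  derive independent sub-seeds per stream (`sub_seeds`), so results are
  invariant to stage order and reproducible from one global seed.
* **p-values.** `p = (1 + #{extreme permutations}) / (n_perm + 1)`, with
  ties counted as extreme. The floor is therefore `1/(n_perm + 1)`, but
  with few hosts a random permutation occasionally re-creates the observed
  partition, so the attainable floor for group-like alternatives sits
  slightly above it — the tests account for this.
* **Sidedness.** The Mantel test is two-sided on `|r|` by default (the
  direction of a correlation between arbitrary distance matrices is not
  privileged), with a one-sided option.

The Mantel statistic is the Pearson correlation of upper-triangle entries,
permuting rows/columns of the second matrix jointly. **Envelopes** for the
per-slice `R²` come from shuffling host labels of the factor matrix: with
fewer than 40 shuffles the band is the min/max of replicates (10 draws
cannot resolve 2.5/97.5 percentiles, so the historical 10-shuffle design
reads as a range); the default is 1000 shuffles with empirical 2.5/97.5
percentiles.

**PERMANOVA** partitions the Gower-centered distance matrix
(`G = −(1/2) J D² J`) against a hat matrix; the trace identities
`tr(HGH) = tr(GH)` (H idempotent) make permutation loops cheap. For
per-lineage association the predictor is itself a distance matrix, which
enters through its positive-eigenvalue principal coordinates — a db-RDA
style pseudo-F. The response is the single clade's presence/absence
mismatch distance; p-values are Benjamini–Hochberg adjusted within each
slice-by-factor stratum (the generic "FDR approach" is operationalized as
BH, the field default). A partition explaining all variation has residual
sum of squares exactly 0; the implementation maps it to an infinite
pseudo-F rather than letting floating-point noise produce a huge negative
one.

**Degenerate slices.** Near the root every host contains every surviving
clade and the dissimilarity matrix is constant; the correlation is
undefined and the profile records `NA` for that slice rather than erroring
or fabricating a 0.

## The BDTT profile and its nulls

`bdtt_profile` runs slice → collapse → Sørensen → Mantel + envelope for
each age and factor. The default age grid is an even 11-point sweep from 0
to the root age; any ascending list can be supplied. Two null models guard
the interpretation:

* **Envelope null** (host labels shuffled in the factor matrix): does the
  observed `R²` exceed what exchangeable hosts produce?
* **Leaf-shuffle null** (leaf labels permuted within the bacterial tree):
  breaks phylogenetic structure while preserving tree shape and leaf-level
  composition. Age-0 correlations are identical to the observed ones by
  construction — a tested exactness — and deeper correlations decay, so any
  deep signal surviving this null would indicate an artefact of the tree's
  hierarchical dependency.

## Synthetic communities and what they show

`simulate_community` plants the scale-disparity structure the profile is
meant to detect. Deep clades (defined by slicing at `eco_cutoff`, default
600 of a 1000-unit tree) are recruited largest-first into three roles until
a target leaf mass is reached (defaults: 45% phylogeny, 45% ecology, rest
noise):

* **Phylogeny role** — each leaf occupies every host within a random
  cophenetic radius of a focal host ("nested balls"), so co-occurrence
  decays with host distance; the clades themselves are made ubiquitous
  (any host missing a clade receives one member leaf), so the signal is
  strictly leaf-scale and dies out at old slices.
* **Ecology role** — clades alternate wolf/dog affiliation; leaves occur
  sparsely within the affiliated group (occupancy 0.4 at strength 1, half
  that in ancient hosts, zero outside), so the leaf-level signal is noisy
  but the within-clade union separates the groups cleanly at old slices.
* **Noise** — i.i.d. Bernoulli at the baseline rate (0.10).

At strengths (0, 0) every leaf collapses to baseline occurrence. Abundances
given occurrence are log-series (θ = 0.95) — Sørensen ignores them, but
tables look realistic. Effect strengths and occupancies are calibration
choices of this package (no published effect sizes exist for these
signals); they were fixed once so that the planted disparity is recovered
in well over 90% of seeds at the test's problem size (128 taxa, 10 hosts,
6 slice ages, 199 Mantel permutations, 200 envelope shuffles — sizes chosen
to keep the property suite fast while leaving statistical headroom).

What passing these tests shows: the pipeline detects a known,
generatively-planted scale disparity with controlled error rates. What it
does not show: robustness to compositional biases of real metagenomic
profiling (database incompleteness, damage-driven misassignment,
environmental contamination), to host tree misspecification, or to the
much larger taxon counts of real data.

## Ancient-DNA authentication

The damage profile is the per-position C→T fraction over reference-C sites
at 5′ positions 1–10. The degradation score of a read is a log-likelihood
ratio between the fitted position-dependent damage model and a
constant-baseline null, summed over reference-C sites: observed C→T
contributes `log(rate_i / b)`, a retained C contributes
`log((1 − rate_i)/(1 − b))`. The published PMD score additionally models 3′
G→A damage and base qualities; this 5′-only form keeps the score computable
from compact alignment summaries, and the conventional threshold (score
> 1) stays configurable. Rates are clamped to `[1e-9, 1 − 1e-9]` before the
ratio. The −Δ% statistic is computed on the edit-distance histogram of
score-filtered reads (`edit_distance_histogram(reads, score, min_score =
1)`), matching the convention that C→T% and −Δ% are evaluated on
damage-supporting reads; a flat histogram returns 0 with a `flat` flag.

Screening rule-sets: gut bacteria need > 500 assigned reads, ≥ 50 reads
with score > 1, −Δ% > 0.9 and an observed 5′ C→T signal; the score-read
bound is inclusive because published screening tables contain a taxon with
exactly 50 such reads, which passes. Eukaryotic dietary traces use > 100
reads with no score-read bound. "Showing patterns of C→T transition" is
operationalized as a position-1 rate strictly above a configurable floor
(default 0). All thresholds are fields of `screening_rules()`.

`estimate_damage_decay` recovers amplitude and decay by weighted
least squares on the log excess rate; weights `c_sites × excess²`
approximate the inverse variance of the log, which keeps deep positions
(tiny excess, large relative noise) from dominating.

## Diet inference

The diet matrix is the Euclidean distance between hosts' food-consumption
fraction vectors. Taxa whose presence-mismatch distance correlates with the
diet matrix (Mantel, p ≤ α, default α = 0.05; optional BH adjustment, off
by default because the selection is a screening step validated downstream
by cross-validation) feed a column-centered, unscaled PCA of
presence/absence — unscaled because all columns are already on the 0/1
scale, and scaling would inflate rare taxa. Only the first axis enters the
binomial logistic regression (probability 0 = wolf-like/carnivorous,
1 = dog-like/omnivorous); with a handful of hosts the classes are typically
separable and maximum likelihood diverges, in which case the fit switches
to a small ridge penalty (λ = 1e-3 on the slope) — threshold predictions
are unchanged, coefficients stay finite. Scores at exactly the 0.5
threshold are called omnivorous; the boundary convention is arbitrary and
documented.

Cross-validation enumerates all leave-1-out and leave-2-out splits (45 at
nine hosts) and refits the entire procedure — selection, PCA, regression —
inside each training fold. Fold-internal selection avoids leakage, and a
leakage variant (`select_on_full = TRUE`) exists only for comparison.
A granularity fact matters at this sample size: a training fold of 2 wolves
and 5 dogs admits only `choose(7, 2) = 21` distinct label partitions, so
even a perfectly diet-linked taxon cannot reach p ≤ 0.05 there; validation
on separable synthetic data therefore runs the selection at α = 0.1. Folds
whose training set contains a single class are skipped and reported; folds
selecting no taxon fall back to an intercept-only model (training class
frequency).

## Copy number

The read ratio is the binomial proportion `target/(target + control)`,
with a Wilson score interval (better small-count behavior than Wald; the
interval flavor is otherwise a free choice). Scaling to diploid copy
numbers anchors on a group of known copy number (wolves, 2): one factor
maps the anchor-group mean onto the anchor value, making the anchor mean
exact by construction.

Two scaling conventions are provided because they differ materially away
from the anchor. Under a Poisson read model the proportion is
`CN·L_t/(CN·L_t + 2·L_c)` — bounded and concave in CN — so scaling the
proportion linearly is exact at the anchor but compresses larger copy
numbers (about 2.4 recovered for a true 8 with matched 75 kb regions). The
default `"rate"` convention instead scales the target:control rate ratio
`target/control`, which is exactly proportional to CN; the
`"proportion"` convention is retained for comparison with the raw-ratio
description of read-depth approaches. Intervals map the Wilson bounds
through the same transform and, by default, add the anchor factor's
sampling variance on the log scale (delta method); without this the scaled
intervals under-cover whenever anchor and test hosts have comparable depth.
An optional length correction divides rates by `L_t/L_c` for designs with
unmatched regions (off by default: the canonical design matches ~75 kb
against 75 × 1 kb windows).

## Pipeline

`read_pipeline_config` validates a YAML config (mandatory seed, threshold
ranges, input paths) before any stage runs; `run_pipeline` executes
simulate → authenticate → bdtt → diet → copynumber, writing one TSV per
stage plus a manifest (seed, package version, input checksums). Outputs are
a pure function of the config; the determinism is tested byte-for-byte.
`inst/scripts/coproscope.R` is a thin shell wrapper with subcommands per
stage.

## Numerical conventions, collected

* Ultrametricity tolerance `1e-6` relative; offending trees rejected.
* Spearman ties: average ranks (R's default, used throughout clustering).
* Ward linkage is `ward.D2` (squared-distance update on the
  `1 − ρ` dissimilarity).
* Permutation tie tolerance `1e-12` when comparing statistics.
* PCoA axes with eigenvalues below `1e-8` of the largest are dropped;
  negative eigenvalues are reported, not hidden.
* Degradation-score rate clamp `1e-9`; logistic ridge `1e-3`.
* Constant lineage profiles are dropped from clustering with a warning;
  constant taxa are skipped in selection and association testing with a
  log entry.

## Limitations

* The degradation score is 5′-only and quality-blind; counts of
  score-thresholded reads are not comparable to quality-aware scorers
  read-for-read.
* The per-lineage association arrangement (clade mismatch distance vs.
  factor coordinates) is one of several defensible operationalizations; a
  per-lineage Mantel variant is available through the same machinery.
* With ten hosts, permutation granularity bounds attainable p-values;
  results at this sample size should lean on the envelope and null-model
  comparisons rather than raw p magnitudes.
* The synthetic generators emulate occurrence structure, damage decay and
  Poisson coverage — not sequence-level artifacts, contamination, or
  reference-database bias.
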
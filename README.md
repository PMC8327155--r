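# coproscope

Analytical machinery for **coprolite paleomicrobiomics**: given shotgun
metagenomes of ancient feces and a comparative panel of modern hosts, the
package answers four questions that recur in ancient gut-microbiome studies
of domestication —

1. **Are the taxon assignments genuinely ancient?** Authentication
   statistics for per-read alignment summaries: 5′ C→T deamination profiles,
   a per-read post-mortem degradation score (PMDS), the negative difference
   proportion (−Δ%) of edit-distance histograms, depth/breadth of coverage,
   and the screening rules that combine them.
2. **At which bacterial evolutionary depth does the microbiome track host
   phylogeny versus host ecology?** β-diversity through time (BDTT): a
   time-calibrated bacterial phylogeny is sliced at successive ages, taxa
   are collapsed into slice-defined clades, per-slice Sørensen dissimilarity
   is Mantel-correlated with host phylogenetic and ecological distance
   matrices under permutation envelopes, a leaf-shuffle null, per-lineage
   pseudo-F association with FDR control, Ward/Spearman clustering,
   principal coordinates, PERMANOVA and Procrustes tests.
3. **What did the ancient host eat?** A microbiome-based dietary-niche
   classifier: diet-correlated taxon selection against a Euclidean diet
   distance matrix, presence/absence PCA, binomial logistic regression on
   the first axis, exhaustive leave-1/leave-2-out cross-validation, and
   projection of the ancient sample.
4. **How many gene copies did the host genome carry?** A read-depth
   copy-number estimator (e.g. for the pancreatic amylase gene *AMY2B*):
   binomial target/(target+control) read ratios with Wilson confidence
   intervals, scaled against an anchor group of known copy number (wolves
   at *n* = 2).

Every stage is exercisable on synthetic data of known structure via seeded
generators (`simulate_calibrated_tree`, `simulate_community`,
`simulate_reads`, `simulate_coverage`), so the whole pipeline is testable
without any sequence download.

## The statistics in brief

* **Sørensen dissimilarity** between hosts *i*, *j* with `a` shared and
  `b`, `c` unique taxa: `d = 1 − 2a / (2a + b + c)`.
* **Unweighted UniFrac**: branch length unique to either host divided by
  the branch length subtending the union of their taxa.
* **BDTT**: for slice age *t*, each leaf maps to the branch its lineage
  occupies at *t*; clade counts are member-leaf sums; the per-slice Mantel
  `R² = r²` against each host factor is compared with a 95% envelope from
  host-label shuffles.
* **PMDS**: per-read log-likelihood ratio over 5′ positions 1–10,
  `Σ [ log(rate_i/b) if C→T, log((1−rate_i)/(1−b)) if C retained ]`,
  with `rate_i` the fitted deamination rate and `b` a baseline.
* **−Δ%**: `Σ max(0, n_i − n_{i+1}) / Σ |n_i − n_{i+1}|` over adjacent
  edit-distance bins; > 0.9 indicates the declining histogram expected of
  authentic ancient assignments.
* **Copy number**: with anchor ratios `r_w` (wolves, true copy number 2),
  the target:control rate ratio is scaled by `s = 2 / mean(odds_w)` so the
  anchor mean is exactly 2; intervals propagate anchor noise on the log
  scale.

## Worked example

Simulate a 10-host canid panel (4 wolves, 5 dogs, 1 ancient) with a planted
shallow phylogeny signal and deep ecology signal, then profile it:

```r
library(coproscope)

spec      <- community_sim_spec(seed = 1)
tree      <- simulate_calibrated_tree(spec$n_taxa, spec$tree_depth, seed = 1001)
host_tree <- simulate_calibrated_tree(10, 1, seed = 2001)
comm      <- simulate_community(tree, host_tree, spec)

factors <- list(phylogeny = comm$host_distance,
                ecology   = ecology_distance_matrix(comm$meta))
prof <- bdtt_profile(tree, comm$table, factors,
                     ages = c(0, 100, 500, 900),
                     n_perm = 999, n_shuffles = 1000, seed = 7)
print(prof$profile, digits = 2)
#>   age    factor n_clades    r    R2     p  env_lo env_hi
#> 1   0 phylogeny      128 0.91 0.837 0.001 2.1e-05   0.14
#> 2   0   ecology      128 0.15 0.023 0.239 1.7e-05   0.22
#> 3 100 phylogeny       82 0.86 0.742 0.001 4.1e-05   0.13
#> 4 100   ecology       82 0.27 0.072 0.055 1.3e-05   0.20
#> 5 500 phylogeny       15 0.16 0.025 0.268 1.4e-05   0.22
#> 6 500   ecology       15 0.66 0.437 0.002 2.1e-05   0.13
#> 7 900 phylogeny        2   NA    NA    NA      NA     NA
#> 8 900   ecology        2   NA    NA    NA      NA     NA
```

Read the table by factor: the **phylogeny** correlation is strong at young
slices (R² = 0.84 at the leaves, 0.74 at 100 My, both above the permutation
envelope, p = 0.001) and gone by 500 My, while the **ecology** correlation
is absent at the leaves and dominant at 500 My (R² = 0.44, p = 0.002) — the
planted scale disparity. At 900 My only two clades survive and every host
contains both, so the dissimilarity matrix is constant and the correlation
is reported as `NA` rather than a number.

Copy-number estimation on simulated coverage (wolves at true copy number 2,
dogs at 8, matched ~75 kb target and control regions):

```r
cc  <- simulate_coverage(coverage_sim_spec(seed = 42))
est <- scale_to_copies(cc, anchor_group = "wolf", anchor_cn = 2)
print(est[c(1, 5, 10), ], digits = 3)
#>        host   group ratio ratio_lower ratio_upper copy_number cn_lower cn_upper
#> 1     wolf1    wolf 0.500       0.488       0.513        2.04     1.93     2.16
#> 5      dog1     dog 0.797       0.791       0.803        8.00     7.63     8.38
#> 10 ancient1 ancient 0.492       0.479       0.505        1.97     1.86     2.09
```

The wolf anchor group averages exactly 2 by construction; the dog's planted
copy number 8 is recovered inside its 95% interval, and the ancient host is
correctly placed at the wolf-like value.

A full synthetic demo of all stages runs from one config:

```r
run_pipeline(read_pipeline_config(list(seed = 42, outdir = "demo")))
```

which writes `authenticate.tsv`, `bdtt_profile.tsv`, `diet_predictions.tsv`,
`copy_number.tsv` and a `manifest.tsv` (seed, version, checksums). The same
pipeline is reachable from a shell via the wrapper in
`inst/scripts/coproscope.R`.

## Documentation

The methods vignette (`vignettes/bdtt-methods.Rmd`) describes the models,
their assumptions, every tunable threshold with its default and rationale,
what the synthetic generators do and do not emulate, and known limitations.
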
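# tbiconn

Graph-theoretic analysis of structural brain connectomes across traumatic
brain injury (TBI) severity, packaged as a reusable, fully tested R
pipeline.

## The problem

Diffuse axonal injury after TBI damages white-matter connections throughout
the brain. Treating the brain as a weighted network — nodes are the 90
regions of a cortical/subcortical parcellation, edge weights are
tractography streamline counts — lets that diffuse damage be quantified
with graph measures and compared across severity groups (healthy controls,
mild TBI with admission GCS 14–15, moderate-severe TBI with GCS 3–13). The
analysis asks three questions:

1. **Dose-response:** do global network measures decline monotonically with
   injury severity?
2. **Hubs:** which regions are network hubs (top 10% of group-ranked
   betweenness centrality, 9 of 90 nodes), and does hub membership change
   with severity?
3. **Cognition:** is regional network efficiency coupled to cognitive
   change scores (post- minus pre-injury), and does injury sever that
   coupling?

Because such clinical cohorts are confidential, the package includes a
synthetic cohort generator with known ground truth; every analysis stage is
validated by recovering what the generator planted.

## What is computed

Networks are built from raw count matrices by symmetrization, diagonal
zeroing, a noise threshold (connections with fewer than 10 streamlines are
set to zero), and total-fiber normalization. On the resulting weighted
network `W`, with shortest-path distances `d_ij` over edge lengths
`l_ij = 1/w_ij`:

- strength `s_i = Σ_j w_ij` (also on the raw-count scale),
- global efficiency `E = mean over i≠j of 1/d_ij` (disconnected pairs
  contribute 0) and its per-node (nodal) version,
- characteristic path length (mean `d_ij` over reachable pairs),
- weighted clustering coefficient (geometric-mean form on max-scaled
  weights),
- local efficiency (efficiency of each node's neighborhood subgraph),
- betweenness centrality (Brandes' algorithm, shared multiplicities).

The statistics layer provides one-way ANOVA (from raw data or — exactly —
from per-group means/SDs/sizes, which are sufficient statistics), Fisher's
LSD post-hoc comparisons, pooled two-sample t tests, Benjamini–Hochberg FDR
control per analysis family, and Pearson correlations with cognitive change
scores.

## Worked example

Reproduce a published group comparison exactly from its printed summary
statistics (group means/SDs of raw-count strength in the left superior
frontal region, n = 22/12/10):

```r
library(tbiconn)
tab <- hub_region_summaries()
rows <- subset(tab, region == "Frontal sup L" & measure == "strength")
anova_from_summary(rows$mean, rows$sd, rows$n)
#> One-way ANOVA: F(2,41) = 6.842, p = 0.003
```

`F(2,41) = 6.842, p = 0.003`: the three severity groups differ in strength,
and the printed p-value is recovered to its printed precision because the
one-way decomposition depends on the data only through these summaries.

Run the full pipeline on a synthetic cohort (22/12/10 subjects, 90 nodes,
graded edge attenuation 1 / 0.9 / 0.75):

```r
report <- run_pipeline(pipeline_config(seed = 7))
report
#> Severity-analysis report: 44 subjects
#>   hub sets: control (9), msTBI (9), mTBI (9)
#>   shared hubs: 9 | union: 9
#>   global measures significant after FDR: strength_raw
report$stats_global[, c("measure", "F", "p", "q", "significant")]
#>             measure         F            p            q significant
#> 1        clustering  2.946296 6.374296e-02 9.561444e-02       FALSE
#> 2 global_efficiency  1.418141 2.537920e-01 2.537920e-01       FALSE
#> 3      strength_raw 18.822527 1.587834e-06 4.763502e-06        TRUE
```

Each group has exactly 9 hubs; under purely diffuse (untargeted)
attenuation all three groups keep the same hub set, and the dose-response
appears where it should: in raw-count strength (F(2,41) = 18.8, significant
after FDR within the three-test global family), while normalized
efficiency/clustering are unaffected by a uniform count rescaling.
Targeted hub disconnection is simulated with
`generate_disrupted_cohort()`, which removes the disrupted node from the
affected group's hub set and produces the control-driven
efficiency–cognition correlation structure (see the vignette in
`vignettes/severity-connectome-analysis.Rmd`).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/tbiconn.R simulate --out-dir cohort/ --seed 1
Rscript inst/cli/tbiconn.R run-all --input-dir cohort/ --out-dir results/
```

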
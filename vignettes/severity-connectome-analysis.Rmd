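---
title: "Graph-theoretic analysis of structural connectomes across TBI severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of structural connectomes across TBI severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbiconn)
```

## The scientific problem

Traumatic brain injury (TBI) frequently produces diffuse axonal injury:
widespread damage to white-matter connections rather than a single focal
lesion. A natural way to quantify such diffuse damage is to treat the brain
as a network — nodes are anatomical regions of a parcellation, edges are
white-matter connections weighted by the number of tractography streamlines
between region pairs — and to compare graph-theoretic summaries of that
network across injury severities. The working hypothesis is a *dose-response*
relationship: network measures are highest in healthy controls, intermediate
in mild TBI (Glasgow Coma Scale 14–15 at admission), and lowest in
moderate-severe TBI (GCS 3–13), and damage to network *hubs* — regions
carrying a disproportionate share of shortest paths — degrades communication
efficiency in a way that tracks cognitive decline.

`tbiconn` implements this analysis as a reusable, fully tested pipeline:

1. **Network construction** from raw streamline-count matrices.
2. **Weighted graph measures**: strength, global/nodal/local efficiency,
   characteristic path length, clustering coefficient, betweenness
   centrality.
3. **Hub identification** from per-group ranked betweenness.
4. **Group statistics**: one-way ANOVA (raw or from printed summary
   statistics), Fisher's LSD post-hoc comparisons, Benjamini–Hochberg FDR,
   and Pearson correlations with cognitive change scores.
5. **A synthetic cohort generator**, because the cohorts that motivated the
   analysis are confidential: every downstream stage is validated against
   simulated data with known ground truth.

## Network construction

A subject's raw matrix holds streamline counts between all region pairs of a
90-region parcellation. `build_network()` applies, in order:

* **Symmetrization.** Tractography cannot distinguish fiber direction, so
  matrices should be symmetric; asymmetries within a relative tolerance of
  `1e-6` (file round-trip noise) are averaged away, anything larger is
  treated as a data error. Symmetrization precedes thresholding so that the
  threshold sees the averaged counts.
* **Diagonal zeroing.** Self-connections are meaningless here.
* **Noise thresholding.** Connections with fewer than 10 streamlines are set
  to zero. The threshold is expressed in raw streamline units, which is why
  it is applied *before* normalization; both the value and the ordering are
  configurable.
* **Total-fiber normalization.** Every entry is divided by the sum of the
  upper triangle (each anatomical connection counted once), making the
  upper-triangle weights sum to 1. The normalizer is stored, so raw counts
  are always recoverable (`raw_counts()`).

A consequence worth stating explicitly: a *uniform* multiplicative change in
all of a subject's counts cancels under this normalization. Group
differences in overall tract yield therefore live in the **raw-count
strength** (`node_strength(net, raw = TRUE)`, magnitudes of order 10^4 for
realistic counts), while the normalized weights carry the *relative*
topology. The pipeline reports both; group comparisons of strength use the
raw scale, matching the magnitudes on which such comparisons are
conventionally reported.

## Graph measures

All measures operate on weighted undirected networks, with shortest paths
computed over edge lengths $l_{ij} = 1/w_{ij}$ (strong connections are
short) — the convention of the standard brain-connectivity toolboxes; a
$-\log w$ mapping is available via the `map` argument.

* **Strength** $s_i = \sum_j w_{ij}$.
* **Shortest paths** by Dijkstra's algorithm from every source; unreachable
  pairs are infinite.
* **Global efficiency** $E = \frac{1}{n(n-1)}\sum_{i \ne j} 1/d_{ij}$, with
  unreachable pairs contributing 0 (the measure excludes infinitely long
  paths), so it is well defined on fragmented networks.
* **Characteristic path length**: mean $d_{ij}$ over *reachable* ordered
  pairs; it errors if no pair is reachable.
* **Nodal efficiency**: the per-node version
  $E_i = \frac{1}{n-1}\sum_{j \ne i} 1/d_{ij}$; its mean equals global
  efficiency.
* **Clustering coefficient** (weighted, geometric-mean/Onnela form): with
  weights scaled by the network maximum,
  $C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
  $k_i$ the binary degree, $C_i = 0$ for $k_i < 2$. A plain verbal
  definition of clustering ("the fraction of neighbors that are neighbors of
  each other") is binary; we use the weighted form implemented by the
  toolbox ecosystem this analysis builds on, since the networks are
  weighted.
* **Local efficiency**: global efficiency of the subgraph induced by each
  node's neighbors, 0 below two neighbors.
* **Betweenness centrality** by Brandes' algorithm on the same lengths:
  endpoints excluded, equal-length shortest paths share multiplicity.
  Floating-point length ties are resolved with a relative tolerance of
  `1e-12`.

Every one of these is verified against independent brute-force oracles
(Floyd–Warshall distances, triple-loop clustering, explicit neighborhood
subgraphs, exhaustive simple-path enumeration for betweenness) on hundreds
of random small graphs, to `1e-10`, and cross-checked against igraph.

Two per-node "efficiency" notions circulate in this literature. Regional
group comparisons default to **local efficiency** (the neighborhood
measure), which is what "local" analyses conventionally report; **nodal
efficiency** is what the cognition coupling uses (a hub's ability to reach
the rest of the network is the mechanistically relevant quantity for
cognition). Both are computed; `regional_efficiency = "nodal"` switches the
tabulated one.

`normalize_measures()` applies per-measure min–max scaling across the cohort
so measures with different native scales can be displayed together. The
scaling is affine within measure, so ANOVA F statistics, p-values and
Pearson correlations are unchanged by it — it is presentation, not
statistics.

## Hub identification

For each group, per-subject betweenness vectors are averaged node-wise,
nodes are ranked 1..90 ascending (90 = highest betweenness; ties broken by
node index so the ranking is deterministic), and the top 10% —
$\lfloor 0.10 \times 90 \rfloor = 9$ nodes — are classified as hubs.
`hub_overlap()` reports the hubs shared by all groups and those unique to
each. Two open choices are resolved as follows and kept configurable:

* **Aggregation**: ranking is on the *mean of per-subject betweenness
  vectors* (not the betweenness of a group-average network); averaging the
  subject-level measure treats each subject as one observation, consistent
  with the group statistics downstream.
* **The 10% rule** is an operational convention, not a discovered threshold;
  `fraction` is an argument everywhere it matters.

## Group statistics

Classical equal-variance forms throughout: one-way ANOVA, Fisher's LSD
post-hoc pairwise t tests on the pooled within-group mean square (LSD
applies no multiplicity adjustment by construction), and pooled two-sample
t tests. Welch variants are deliberately not provided, matching the
framework in which such analyses are conventionally reported.

`anova_from_summary()` deserves a note: per-group means, SDs and sizes are
*sufficient statistics* for the one-way decomposition
($SS_b = \sum_g n_g(\bar x_g - \bar x)^2$,
$SS_w = \sum_g (n_g - 1) s_g^2$), so printed summary tables can be
re-analyzed exactly even when the raw data are unavailable — this is how the
package reproduces published group comparisons from their printed summaries.
With group sizes 22/12/10 the degrees of freedom are (2, 41).

Multiple testing is controlled per analysis family with the
Benjamini–Hochberg step-up rule at $\alpha = 0.05$: the three global tests
form one family; the hub-region comparisons one family (regions in any
group's hub set × three measures); the 90-region local comparisons one
family per measure. Each family's size is recorded alongside its q-values.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
emulated study conditions:

| parameter | default | why |
|---|---|---|
| `n_nodes` | 90 | 90-region parcellation (cerebellum excluded) |
| `group_sizes` | 22 / 12 / 10 | control / mTBI / msTBI retained samples |
| `edge_density` | 0.3 | typical deterministic-tractography connectome density |
| `mean_count` | 500 | gives raw strengths of order 10^4, the published magnitude |
| `attenuation` | 1 / 0.9 / 0.75 | graded diffuse edge loss producing the dose-response |
| `dispersion` | 0.02 | negative-binomial count noise, CV ≈ 15% per edge |
| `subject_sigma` | 0.12 | between-subject log-normal variability of overall tract yield |
| `cognition_slope`, `cognition_noise_sd` | 1, 1 | control coupling with population r = 1/√2 ≈ 0.71 |
| `cognition_group_shift` | −2 | mean post-injury decline in TBI change scores |
| `n_control_cognition` | 8 | controls with available cognitive scores |

Construction: a *template* connectome is drawn once per cohort — edge
presence Bernoulli(`edge_density`), counts negative-binomial around
`mean_count`, and a randomly placed core (15% of nodes, core-core counts
boosted 3×) that concentrates shortest paths and yields a stable set of
high-betweenness template hubs; draws are repeated until the template is
connected. Each subject's matrix is then the template with (i) a group
attenuation factor on every edge, (ii) optionally an extra factor on edges
incident to targeted hub nodes in targeted groups, (iii) a subject-level
global scale factor, and (iv) integer negative-binomial noise
(variance $\mu + \phi\mu^2$); `dispersion = 0` degenerates to rounded
means, which is what the exactness tests exploit. GCS is drawn uniformly
within each group's legal range (14–15 mild, 3–13 moderate-severe), and age
and time-since-injury around the published group summaries.

**Cognition.** The template node with the highest betweenness is designated
the *target region* (the analogue of a parietal hub like the precuneus).
For scored controls, the change score (post- minus pre-injury) is
`slope * z + noise`, where `z` is the subject's target-region nodal
efficiency standardized across scored controls; for TBI subjects the slope
is forced to zero and the change score is a negative shift plus noise —
coupling exists in controls only.

**Focal disruption.** `generate_disrupted_cohort()` models hub
disconnection: it locates the target region on a pilot draw and regenerates
the cohort (same seed, hence identical template and untargeted subjects)
with that node's edges further attenuated in chosen groups. Two standard
scenarios use it: factor 0.5 in msTBI only (does the hub drop out of the
msTBI ranking while remaining a control hub?) and factor 0.8 in both TBI
groups (the cognition scenario). The latter matters statistically: under
total-fiber normalization a purely uniform attenuation leaves TBI efficiency
distributions unchanged, and 8 coupled controls among 30 scored subjects
cannot by themselves produce a significant pooled correlation — the pooled
association arises, as in the data being emulated, from TBI subjects having
*both* lower target-region efficiency (disconnection) *and* lower change
scores. The generator makes that mechanism explicit instead of hiding it in
a correlation target.

**What the generator does not emulate:** lesion geometry, spatially
structured (non-exchangeable) edge noise, realistic anatomical topology
beyond a core-periphery sketch, age or scanner effects, and any coupling of
cognition to measures other than the target region's nodal efficiency.
Passing recovery tests therefore demonstrates that the *pipeline* detects
the effects it is designed to detect at realistic sizes — not that real
lesioned brains behave like the simulator.

## Numerical choices and degenerate inputs

* Weight→length: `1/w`; `-log w` available (requires weights ≤ 1).
* Path-length ties: relative tolerance `1e-12` in Brandes accumulation.
* Disconnected pairs: contribute 0 to efficiency, are excluded from CPL;
  an entirely unreachable network errors on CPL and on normalization
  (degenerate all-zero matrix).
* Constant measure cells (e.g. a degree-1 region with identically zero
  clustering) are skipped with a warning in group comparisons and
  correlations rather than producing NaN statistics.
* Rank ties break by node index; no randomness anywhere in the analysis
  half — all stochasticity lives in the generator and is seed-controlled.
* Missing cognition scores: flagged `NA`, listwise-deleted within the
  correlation family only.

## Problem sizes used in the validation suite

The packaged tests validate measures on random graphs of up to 8 nodes
(hundreds of draws against brute-force oracles), and the recovery properties
on replicated 90-node, 44-subject cohorts: 50 dose-response cohorts and 200
null cohorts for the strength ANOVA power/calibration pair, and 20
replicates each for the hub-disruption and cognition-coupling recoveries.
These sizes give Monte-Carlo margins comfortably inside the asserted bounds
(e.g. a binomial SD of ~1.5 percentage points for the null rejection rate at
200 replicates) while keeping the full suite quick to run.

## Known limitations

* The equal-variance statistical framework is assumed, not tested
  (no Levene/Shapiro–Wilk stage, no Welch fallback, no age-adjusted
  ANCOVA variant).
* Hub comparison across groups is descriptive (rank order and set
  membership); no inferential test on hub membership is attempted.
* The generator's template is a statistical sketch; its hub identities are
  arbitrary node indices, not anatomical claims.
* Modularity, rich-club and small-world statistics are out of scope.
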
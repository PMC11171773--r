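---
title: "Modeling temporal causal signaling with tcsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling temporal causal signaling with tcsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsnet)
```

# The model

`tcsnet` asks, for a biological process sampled as a time series: *which
genes initiate each wave of transcriptional change, which transcription
factors carry it out, and along which network routes does the signal
travel?* The unit of analysis is the *segment* — a pair of adjacent
timepoints — and the substrate is a signed prior knowledge network (PKN)
whose edges carry a regulatory sign (activation / repression / unknown), a
mechanism (transcriptional regulation, protein–protein interaction,
metabolic, gene–gene correlation, or the artificial "virtual" edges that
decompose protein complexes into members), and an influence-factor (IF)
reliability score. Edges with IF below 0.86 are flagged low-confidence but
never deleted: flagging preserves the network's integrity while letting
path search skip unreliable conduits.

## Stage 1 — primary regulatory drivers

A driver announces itself by dysregulating its network neighborhood: the
joint expression distribution of each incident edge changes between the two
timepoints. For an edge (i, j), every sample becomes a 2D point
(expression of *i*, expression of *j*). Each timepoint's point cloud is
augmented with its per-gene mean as a pseudo-sample (and, for unreplicated
designs, the cross-timepoint midpoint), guaranteeing at least three points
per side. The clouds become Gaussian-mixture densities — one isotropic
kernel per point — evaluated on the *sample-pair lattice*, the Cartesian
product of all observed values of gene *i* and gene *j*; the densities are
floored at δ = 1e-12, renormalized, and compared by the symmetrized
discrete Kullback–Leibler divergence.

Three numerical policies matter here, all of which exist because replicate
groups are tiny (typically n = 3):

* **Bandwidth.** Silverman's rule is applied per axis to the *within-group*
  dispersion (root mean group variance, guarded by the mean group IQR),
  not to the pooled points: pooling would let the very shift under test
  inflate the bandwidth and cap its own divergence. On top of the local
  rule sits a cohort-level floor — Silverman's constant times the median
  per-gene within-group sd — which stops a coincidentally tight replicate
  group from shrinking its kernels until ordinary noise looks divergent.
  This moderation plays the same role for kernel densities that variance
  moderation plays in small-sample differential expression. A scalar
  multiplier (`bw_adjust`) remains available.
* **Degenerate geometry.** When the pooled 2×2 covariance of a cloud is
  rank-deficient or has condition number above 1e8 (collinear points,
  identical replicates), the points are rotated to principal axes and the
  degenerate axis receives seeded jitter of 1e-3 times the dominant sd.
* **The floor.** δ = 1e-12 keeps the log-ratios finite; it also means the
  statistic saturates for fully separated clouds. The lattice value is
  therefore a *rank* statistic, always interpreted against a null computed
  identically — not an estimate of the continuous divergence. The package
  also evaluates on an arbitrary regular grid (`edge_kld(grid = ...)`),
  and in that configuration it agrees with a brute-force fine-grid oracle,
  which is how the numerical machinery is validated in the test suite.

Significance comes from a permutation null: 10,000 random unordered gene
pairs that do not share an edge in the selected view, scored by exactly the
same pipeline. The empirical p-value uses add-one smoothing,
p = (1 + #{null ≥ observed}) / (1 + N), so p is strictly positive and the
downstream logarithm is always defined. Per-gene aggregation is Fisher's
χ² = Σ −2 ln p over incident edges; because edges sharing a gene are
dependent, Brown's correction rescales the reference distribution using
the Kost–McDermott polynomial approximation of cov(−2 ln pᵢ, −2 ln pⱼ)
from the Pearson correlation of the two partner genes' expression
profiles. Partner correlations are estimated on the *full* time-series
profiles rather than the six samples of one segment: a correlation from
six points has a standard error near 0.45, and feeding that noise into
Brown's correction randomly deflates the degrees of freedom of hub genes.
Duplicate edges between the same gene pair (multiple sources or
mechanisms) are collapsed before aggregation so a single piece of evidence
is not counted twice.

## Stage 2 — transcription-factor effects

Each regulator with outgoing transcriptional edges is evaluated twice,
under an *activated* and a *repressed* pseudo state. The state and the
edge sign determine the predicted direction of each target (activated ×
activation → up, repressed × activation → down, and so on; unsigned edges
predict either direction, configurable to strict). Over the PKN node
universe of size n (the transcriptional + virtual view after complex
expansion), the contingency table counts a = state-consistent DEG targets,
b = remaining pattern-matching DEGs in the PKN, c = remaining targets,
d = the rest. For regulators whose outgoing edges carry mixed signs the
"pattern-matching" margin is the union of DEG directions predicted through
any of the regulator's edge signs; single-sign regulators reduce to the
obvious margin.

The p-value is the one-sided hypergeometric upper tail, computed from the
log-factorial form of the tail sum with the summation index running while
all factorial arguments remain non-negative (k up to min(b, c)). Tests are
BH-corrected across the doubled regulator × state family. DEGs themselves
come from per-gene Welch t-tests with BH FDR ≤ 0.1 and |fold change| ≥ 1.5
(inclusive comparisons, so boundary genes are kept); with fewer than two
replicates on a side, p-values are undefined and fold-change-only calling
engages rather than failing.

## Stage 3 — signaling paths and temporal pruning

BFS collects *all* minimum-length directed paths from every significant
driver to every significant TF. The path view uses transcriptional,
metabolic and virtual edges forward, PPI edges in both directions (complex
signaling is directionless), excludes correlation edges (statistical, not
causal, conduits) and skips low-confidence edges unless asked otherwise.
Sign consistency along a path is deliberately *not* enforced: regulator
activity and expression can decouple, so a sign-consistency filter would
discard real routes; this is a known limitation of path-level
interpretation. All tied shortest paths are kept because the temporal
statistics depend on path multiplicity; a driver that is itself a
significant TF contributes its trivial single-node path.

Across segments, a node's frequency is its number of path memberships
(a node on three paths counts three — multiplicity preserves hub
weighting). Nodes in the top 10% of total frequency (ceiling count,
boundary ties included) are kept. So are significant *callback
regulators*: nodes that terminate a path in segment e and originate one in
segment r with 0 < r − e ≤ 5, whose frequency Z-test in the reuse segment
— z = (observed − mean)/sd with the node's cross-segment mean and
population sd, one-sided normal p < 0.05, with the convention z = 0, p = 1
when sd = 0 — rejects chance reuse. The kept edges are path-view edges on
at least one collected path with both endpoints kept.

## Stage 4 — summarization

For visualization the pruned network is clustered into *hypernodes* by
Louvain modularity optimization on the undirected kept-edge graph, with
edges inside a shared regulon or complex up-weighted (default boost 2,
applied once even when both memberships hold) so functionally coherent
units co-cluster; resolution defaults to 1 and the partition is
deterministic under the recorded seed. Hyperedges aggregate the underlying
kept edges between two hypernodes with a unanimity-based sign summary.
The GO information-flow view selects, per segment, biological-process
terms by a greedy coverage rule over ancestor-propagated annotations:
candidates covering more than half the DEG set are excluded as overly
general, then the term adding the most uncovered DEGs is picked repeatedly
until the best candidate adds fewer than 3 genes or overlaps covered genes
by more than half (ties: smaller term, then lexicographic id). Nodes are
(term, segment) pairs; adjacent segments are linked with weight equal to
their shared covered genes. The stopping thresholds have no single
principled value, so they are configuration values with the stated
defaults.

# The synthetic benchmark

The generator emulates the shape of the data the model targets without any
external database. `generate_network()` grows a preferential-attachment
directed regulatory core (signs 0.7/0.3 activation/repression, IF scores
Uniform(0.5, 1)), adds a correlation layer only between co-regulated
target pairs (mimicking co-expression resources at toy scale), reports
regulons as the out-neighborhoods of the highest-degree regulators, and
adds small complexes with PPI edges among members. `simulate_series()`
draws per-gene baselines from Normal(10, 1) — the mean-10 log2 convention
— and plants `n_drivers = 5` driver cascades: the driver shifts by
δ (default 2) at its onset segment, the shift walks one regulatory edge
per segment (sign-aware, flipping across repression edges), and the
terminal TF's regulon responds already in the onset segment, reflecting
that regulator *activity* crosses a cascade faster than the 30-minute
sampling interval while intermediate *expression* lags. When feasible one
cascade terminus is re-used as a later driver, planting a callback event
within the 5-segment window. Replicate noise is i.i.d. Normal(0, 0.25)
by default.

Two study-design choices deserve emphasis. Planted drivers are sampled
among regulator-like genes (at least two transcriptional targets and four
total interactions): the statistic aggregates evidence over incident
edges, so a two-edge gene is undetectable by construction and would
benchmark the generator, not the method. And pure driver-recovery
experiments (`tf_response = FALSE, path_length = 0`) perturb only the five
drivers, because with 200 genes a full cascade legitimately shifts dozens
of regulon members whose neighborhoods *are* dysregulated — they are true
positives of the edge statistic, not errors, and belong in the pipeline
benchmark rather than the driver-ranking benchmark.

What passing these benchmarks does **not** show: robustness to the noise
structure of real arrays (probe effects, dye bias, batch), to incomplete
or wrong PKN edges beyond the IF flags, or to expression-independent
regulation (post-translational activation), all of which the synthetic
model idealizes away.

# Problem sizes, determinism and runtime policy

Every stochastic step — null-pair sampling, degenerate-cloud jitter,
Louvain refinement, the generator itself — draws from seeds derived from
one root seed recorded in the run manifest, so a pipeline run is
reproducible byte for byte. The shipped test-suite and acceptance
experiments use reduced but statistically adequate problem sizes chosen as
the package's own benchmark design: 1,000-draw nulls (the default for real
analyses remains 10,000), 200-gene networks with 600–2,000 edges, 10–20
seed replicates for recovery rates, and exhaustive FET validation over all
135,751 contingency tables with n ≤ 40.

# Known limitations

* With n = 3 replicates the KLD edge test leans heavily on the bandwidth
  moderation described above; very heterogeneous per-gene noise scales
  would weaken the cohort floor's premise.
* The permutation null is contaminated when a large fraction of genes
  shift simultaneously (global stress responses): observed edges then
  compete against partially-shifted null pairs and edge p-values compress
  upward. Gene-level aggregation absorbs much, but not all, of this.
* Callback detection is index-based over segments and assumes uniform
  sampling intervals.
* The FET universe is the PKN node set; regulators with targets outside
  the expression platform inherit a conservative bias.
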
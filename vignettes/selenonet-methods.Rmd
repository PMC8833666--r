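---
title: "Interactome merging, hub centrality and clinical statistics for selenoprotein networks"
author: "SelenoNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SelenoNet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SelenoNet)
```

# Scope

Triple-negative breast cancer (TNBC) lacks the three receptor targets
that guide therapy in other breast cancer subtypes, so prognostic
biomarkers are actively sought among co-regulated gene families.  One
family of interest is the 25 human selenoproteins; network analysis of
the protein–protein interactions around dysregulated selenoproteins can
nominate coordinating "hub" proteins (such as the SELENOS partner
VCP/p97) whose combined expression with a selenoprotein may carry
prognostic information.

SelenoNet implements that analysis as a reusable, testable pipeline:

1. **interactome** — parse and merge multi-source interaction edge lists
   into one undirected simple graph with per-edge provenance, and report
   its small-world statistics;
2. **expression** — group-mean profiling, fold-change gene selection,
   cross-dataset consensus direction calls, and `2^-ddCq` qPCR
   quantification;
3. **subnetwork** — map gene panels onto the interactome and extract
   seed neighborhoods with induced edges, plus hub-to-seed shortest
   connection paths;
4. **hubcentrality** — eleven topological measures per node and a
   consensus hub ranking;
5. **clinical_stats** — IHC intensity tabulation and Pearson
   correlations, combined two-gene expression splits, and
   Kaplan–Meier/log-rank survival comparison;
6. **synthetic data** — generators for every input type with recorded
   ground truth, so each downstream stage can be validated without
   external downloads.

# The interactome model

Interaction records are reduced to an undirected, simple, unweighted
graph over uppercase gene symbols: direction, interaction type and
detection-method metadata are discarded because every downstream measure
is defined on the topology alone.  Merging takes the union of unordered
pairs across sources, drops self-loops (counted in the merge log),
collapses duplicates, and unions provenance so that every edge lists all
sources that reported it.  The merge is idempotent and order-invariant,
properties the test suite asserts directly.

Identifier normalization is trim + uppercase only.  No alias resolution
is attempted — interaction databases disagree on synonyms, and silent
remapping is worse than none — but a user-supplied synonym table is
applied when given (e.g. mapping the occasional `BRAC1` typo to
`BRCA1`).

Three input dialects are parsed: Cytoscape SIF (one source node, a
relation token, one or more targets per line), plain two-column TSV, and
a minimal tab-separated MITAB-like dialect in which the two symbol
columns are chosen by index.  Full PSI-MI controlled-vocabulary parsing
is out of scope.

## Network statistics

For a graph with $n$ nodes, $m$ edges and degree sequence $d_i$:

* density $= 2m / (n(n-1))$;
* average neighbors $= 2m/n$;
* heterogeneity $= \mathrm{sd}(d)/\bar d$ (population standard
  deviation), zero exactly when the graph is regular;
* characteristic path length $=$ the mean shortest-path distance over
  all unordered **connected** pairs.  Disconnected pairs are excluded
  (and the component count reported) so the statistic stays finite on
  fragmented interactomes.

Path length is exact (all-sources BFS) up to a configurable node limit,
3000 by default; above it, a recorded number of uniformly sampled source
nodes is used and the sampling seed is stored in the result.  Source
sampling is unbiased for the pair-averaged distance; the tests check
agreement with the exact value on graphs below the limit.

# Expression analysis

Fold changes ratio **linear-scale group means**, matching how mean
expression profiles are compared in cell-line compendia:
$\log_2\!\mathrm{FC}(g) = \log_2 \frac{\bar x_{g,\mathrm{case}} + c}{\bar x_{g,\mathrm{ref}} + c}$
with pseudocount $c = 0$ by default.  Zeros with $c = 0$ produce an
explicit `undefined` status plus a warning rather than an infinite
value; a small pseudocount is the documented escape hatch.  Averaging on
the log scale was rejected because the downstream selection rule is
stated on ratios of means.

The selection threshold defaults to $|\log_2\mathrm{FC}| \ge 1$ — the
conventional two-fold rule used for calling qPCR fold changes
significant — and the same cutoff is reused for network gene selection,
since no separate cutoff is documented for that step.  Up- and
down-regulated lists are returned sorted by $|\log_2\mathrm{FC}|$
descending, ties by symbol.

Consensus across datasets is deliberately conservative: a gene is
consensus-up only if at least `minAgreement` tables call it up **and no
table calls it down**; any opposition yields `discordant`.  The call is
invariant to table order.

## Relative quantification (`2^-ddCq`)

Technical replicates are averaged per (sample, gene) first; then
$\Delta Cq$ is the group mean target Cq minus the group mean
housekeeping Cq, $\Delta\Delta Cq = \Delta Cq_{\mathrm{case}} -
\Delta Cq_{\mathrm{ref}}$, and the fold change is $2^{-\Delta\Delta Cq}$.
Significance uses the same $\pm 1$ log2 rule.  Replicate-variance
testing (e.g. t-tests on replicate $\Delta Cq$) is intentionally out of
scope; the rule operates on fold-change magnitude only.

# Sub-network extraction

"First/second order" neighborhoods are interpreted as hop distance
$\le 1$ or $\le 2$ from any seed, with **induced closure**: every parent
edge whose endpoints are both selected is retained.  This matches the
neighborhood-selection semantics of interactive network tools, and the
alternative (path-tree expansion without closure) is not used anywhere.
Duplicate seeds collapse; seeds absent from the parent network are
logged and skipped — extraction fails only when *no* seed maps, mirroring
how a 25-gene panel with a few unmapped members still defines a usable
sub-network.

Hub-to-seed connection paths are all distinct shortest paths of at most
`maxLen` (default 2) edges, sorted lexicographically by intermediate
labels; direct interactions appear as length-1 paths.  Every reported
path is re-verifiable as shortest by BFS distance, which the tests do.

# The eleven centrality measures

The measures follow the CytoHubba conventions; since the original
descriptions leave constants implicit, each constant here is explicit,
configurable, and recorded in the `CentralityTable` metadata.

| measure | definition | parameters / conventions |
|---|---|---|
| degree | neighbor count | — |
| MNC | size of the largest connected component of the open neighborhood $G[N(v)]$ | isolated node: 0 |
| DMNC | $E_c/V_c^{\,\varepsilon}$ of that component | $\varepsilon = 1.7$; 0 when MNC $\le 1$; size ties broken toward more edges |
| MCC | $\sum_{C \ni v} (|C|-1)!$ over maximal cliques $C$ | bare edges contribute 1 each, so an edgeless-neighborhood node scores its degree; enumeration refused above a node/clique budget |
| EPC | mean size of $v$'s component under random edge retention | per realization: one threshold $t \sim U(0,1)$, i.i.d. edge weights $w_e \sim U(0,1)$, keep $w_e \ge t$; $K = 1000$ default; seed recorded; Monte-Carlo SE attached |
| BottleNeck | number of BFS shortest-path trees in which $v$ has more than $n_s/4$ strict descendants ($n_s$ = nodes reachable from the root) | tree parents tie-broken to the lexicographically smallest predecessor, making the score deterministic |
| eccentricity | max distance within $v$'s component | ranked **ascending** in hub lists: a small maximum distance is centrality, a large one peripherality |
| closeness | harmonic, $\sum_w 1/d(v,w)$ | unreachable nodes contribute 0 |
| radiality | $\sum_w (\Delta + 1 - d(v,w)) / (n_c - 1)$, $\Delta$ = component diameter | per component; isolated node: 0 |
| betweenness | $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over unordered pairs | Brandes accumulation over one BFS per source |
| stress | number of shortest paths with $v$ interior | same BFS pass |

The five shortest-path measures are computed by a single hand-written
Brandes-style BFS per source.  This is deliberate: the test oracle
(exhaustive enumeration over a distance matrix with layered path
counting, cross-checked against igraph's betweenness) stays a fully
independent route, and the suite asserts exact equality on dozens of
random graphs.

Degenerate inputs follow one convention everywhere: an isolated node
scores 0 on all geodesic measures, 0 on MNC/DMNC/MCC/BottleNeck, and
exactly 1 on EPC (it is always its own component).

## Consensus hub ranking

Each measure contributes a top-$k$ list ($k = 10$ default; scores
descending, eccentricity ascending, ties by symbol).  A node is a
consensus hub when it appears in at least `minMeasures` (default 6)
lists; consensus hubs are ordered by number of supporting measures,
then by mean rank **across the supporting measures**, then symbol.  The
combination rule is this package's construction — published hub lists
rarely document their exact aggregation — so its parameters are embedded
in the `HubReport`.  Mean rank is taken over supporting measures only
because a node that 10 measures call a top hub should not be demoted by
its rank under the one measure that structurally cannot favor hubs
(DMNC prefers small dense neighborhoods; a true hub's neighborhood is
large and sparse).

# Clinical statistics

IHC staining intensities are ordinal 1 (weak) / 2 (moderate) /
3 (strong), tabulated per tumor grade (2 or 3).  Marker–marker,
marker–grade and marker–Ki67 associations use product-moment (Pearson)
correlation with the two-sided t-test
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ df; grade is treated as the
numeric values 2 and 3.  Pearson on ordinal scores follows the original
analysis design; p-values are reported at full precision and star
thresholds (0.05 / 0.01 / 0.0001) are labels only.  (The published star
legends are themselves inconsistent between 0.001 and 0.01 for `**`;
the package never rounds a p-value into a star.)

The combined two-gene signature is the mean of per-gene z-scores with a
median split: above the median is `high`, everything else — including
exact median ties, counted and reported — is `low`.  The split is
invariant to monotone affine rescaling of either gene.  Survival curves
are product-limit (Kaplan–Meier) estimates and the two-group comparison
is the standard log-rank test (chi-square, 1 df), computed with the
survival package; the test suite re-derives the statistic from the
observed/expected hypergeometric table independently.

# Synthetic data: what it emulates, and what it does not

Every generator returns a `SyntheticTruth` carrying the planted
parameters, the seed (which reproduces the output byte-for-byte) and
all remaining settings.

**Interactome.**  A preferential-attachment backbone (`attach = 2`
edges per node) gives the heavy-tailed degree distribution
characteristic of protein interaction networks; planted hubs are wired
to a uniform random 40% of all nodes (at least the contractual 20%), a
strength chosen so that a planted hub dominates the degree distribution
and the distance-based measures at the 100-node scale used in
validation.  Node labels are shuffled before use so that label order
carries no information about attachment order — downstream symbol
tie-breaks must not systematically favor any node class.  The edge set
is split over `nSources` overlapping sources (one primary source per
edge plus a second for a chosen fraction), emulating partially
redundant interaction databases; the union is the backbone exactly.

**Expression.**  Log-uniform baselines, multiplicative planted effects
$2^{\mathrm{lfc}}$ on non-reference samples, and log-normal noise
(`noiseSD` in log2 units), so values stay positive, noiseless ratios
recover planted fold changes exactly, and log2 fold-change errors are
symmetric.

**qPCR.**  Planted effects lower the case-group target Cq by one cycle
per log2 unit; the housekeeping gene is flat across groups.  Replicate
jitter defaults to 0.1 cycles — a convention for a well-behaved assay,
not a published value, as replicate noise magnitudes are rarely
reported.

**IHC.**  Two latent standard-normal scores with correlation
`latentRho`, a shared additive `gradeShift` for grade-3 patients, and
two thresholds mapping latents to intensities 1/2/3.  Discretizing to
three categories attenuates correlation, and the grade shift adds
shared variance, so the ordinal correlation is a non-trivial function
of the latent one.  The defaults (`latentRho = 0.9`,
`gradeShift = 1.5`, thresholds $-1.8$ and $1.0$, Ki67 means/SDs of
28.9/13.3 for grade 2 and 44.9/15.8 for grade 3, a 10:20
grade-2:grade-3 composition) were calibrated once so a 30-patient
cohort's expected ordinal marker–marker Pearson correlation is about
0.77, the regime of interest for a coordinated biomarker pair.

**Survival.**  Two correlated expression values per patient, group
assignment by the same combined-split rule the analysis uses (so
recovery is closed-loop testable), exponential event times with the low
group's median at `baseMedianMonths` (60) and the high group's hazard
multiplied by `hazardRatio`, and censoring as an independent
Bernoulli(`censorRate`) mark with a uniform censoring time before the
event — the stated censoring fraction is hit exactly in expectation.

**Not emulated:** RNA-seq count models and normalization chemistry,
batch effects, inter-rater disagreement in IHC scoring, covariate
structure in survival.  Passing tests therefore demonstrate the
*pipeline's* correctness and calibration on data with the assumed
statistical structure, not robustness to the technical artifacts of any
particular real dataset.

# Validation scales and numerical choices

The validation suite exercises: exact-equality oracles for the
shortest-path measures on 50 random graphs of up to 20 nodes and for
MCC (all-subset clique enumeration) up to 12 nodes; the analytic EPC
expectation (a single edge keeps probability $1/2$, so a two-node graph
scores $1.5$) at $K = 10^5$ within three Monte-Carlo standard errors;
closed-form BottleNeck cases; hub recovery over ten replicate 100-node
interactomes; 500-replicate fold-change recovery at
$n = 20/20$, noise 0.25; 500 30-patient IHC cohorts; and 200
200-patient survival cohorts at hazard ratio 2.5.  These sizes make the
whole suite run in a few minutes on one core while keeping every
Monte-Carlo bound far from its decision boundary.

Numerical conventions worth knowing: group-mean direction calls use a
relative tolerance ($10^{-9}$) so floating-point equality never decides
a direction; fold-change tables propagate `NA` log2 fold changes as
`undefined` rather than dropping genes; all ranking tie-breaks are
lexicographic and therefore deterministic; every Monte-Carlo routine
takes an explicit seed and never perturbs the caller's RNG state.

# Known limitations

* Hub-consensus "first place" on a single simulated graph is
  stochastic at realistic settings: the planted hub is in the top-10 of
  at least 9 of 11 measures essentially always, but degenerate-measure
  ties (notably eccentricity, whose integer range on small-world graphs
  is tiny) let a strong backbone node occasionally match its support
  count.  Validation therefore asserts first place over a majority of
  replicates, not on every graph.
* At $n = 30$, a true correlation of 0.77 yields $p < 10^{-4}$ in
  roughly 85–90% of cohorts, not more: the sampling spread of $r$
  (Fisher z SD $\approx 1/\sqrt{27}$) puts a non-negligible mass below
  the $r \approx 0.655$ needed for that p-value.  Larger detection
  rates at this sample size imply a true correlation above 0.8.
* MCC is exact but exponential-worst-case; the clique budget refuses
  pathological inputs instead of silently truncating.
* The characteristic-path-length sampler assumes reasonably homogeneous
  component structure; on graphs dominated by many small components the
  exact mode should be forced.
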
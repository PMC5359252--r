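---
title: "Detecting latent differential connectivity networks"
author: "latentconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latent differential connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentconn)
```

## The problem

Group comparisons of functional connectomes usually take one of two forms:
edge-by-edge mass-univariate testing, which pays a severe multiple-testing
price over the $\binom{n}{2}$ edges and ignores how affected edges are
organized, or global graph metrics, which discard edge-level localization
entirely. `latentconn` implements a middle path: it searches for *latent
subnetworks* — node sets that were not prespecified — in which a high
proportion of edges differ between groups and the affected edges form an
organized topology (a clique, or a k-partite structure in which
between-set edges carry the differences while within-set edges do not).
Statistical significance is then assigned at the *network* level by a
max-statistic permutation test, which controls family-wise error over the
combinatorially many candidate subgraphs.

The intended data are two groups of subjects, each represented by a
symmetric Fisher-Z functional connectivity matrix over a shared
parcellation (e.g. 90 regions of a whole-brain atlas, hence 4005 edges).
The pipeline starts at ROI level: either precomputed matrices or ROI
$\times$ time signal matrices from which Pearson correlations are computed
and Fisher-Z transformed (`correlationToZ()`). All image preprocessing is
upstream and out of scope.

## The evidence graph

For each unordered node pair $(i, j)$ a two-sample $t$ test compares the
subjects' Fisher-Z values between groups, giving a two-sided p-value
$p_{ij}$, and the edge receives the weight

$$W_{ij} = -\log(p_{ij}) \ge 0.$$

The weighted adjacency matrix $\mathbf{W}$ is the sole input to network
detection. Choices worth stating explicitly:

* **Pooled vs Welch.** The default is the pooled-variance Student $t$,
  the minimal reading of "two-sample t test"; `varEqual = FALSE` switches
  to Welch. The ambiguity is surfaced as a flag rather than silently
  fixed.
* **Log base.** Natural log by default, base 10 via `logBase = 10`. A
  base change rescales every weight (and the global-mean threshold) by
  the same positive constant, so detection node sets and permutation
  p-values are unchanged — a property the test suite checks.
* **Underflow.** p-values are clipped at the smallest positive double
  before the log (with a message recording how many were clipped), so
  $W$ is always finite.
* **No edgewise multiplicity correction.** Multiplicity is handled
  entirely at the network level by the permutation test; thresholding
  edges first would discard exactly the weak-but-organized signal the
  method exists to find.

## The network score

A candidate network is a node set $S$ with a topology. Its scoring edges
are all within-$S$ pairs (clique) or all between-set pairs of a partition
of $S$ (k-partite). The network statistic is the centered sum

$$\mathrm{score}(S) = \sum_{e \in \text{scoring}(S)} (W_e - \lambda).$$

Under the null reading that differentially expressed edges are scattered
randomly through the graph, a subgraph of typical edges scores about 0
with $\lambda$ at the global mean of $W$, which makes the permutation
max statistic comparable across subgraph sizes. The exact objective the
original community-detection formulation optimizes is not public; this
centered-sum score is this package's own, deliberately simple and
brute-force-verifiable, realization of the same enrichment idea, and the
test suite pins the optimizer to exhaustive search on small graphs rather
than to any external implementation.

### The dispersion margin on $\lambda$

`detectionConfig()` sets $\lambda = \mathrm{mean}(W) + \gamma\,
\mathrm{sd}(W)$ with `lambdaGamma` $\gamma = 1$ by default; $\gamma = 0$
recovers the plain global mean. The margin is not cosmetic. Under the
null, $W = -\ln p$ is unit-exponential, so candidate single-node
additions to a size-$m$ subgraph have gains distributed like
$\Gamma(m, 1) - \lambda m$; with $\lambda$ at the plain mean the maximum
of these gains over the remaining nodes stays positive up to subgraph
sizes far beyond any planted structure, and a local optimizer steadily
absorbs background nodes (the familiar degeneracy of mean-centered dense
subgraph objectives — the same reason parsimony penalties exist in
community detection). One standard deviation of margin makes the expected
cost of an average node strictly positive at realistic sizes while
leaving genuinely enriched edges ($W$ of tens) untouched. On small
hand-built examples where every "background" edge is itself heavy, the
margin can exceed the signal — for such toy graphs, and for noise-free
didactic weights, use $\gamma = 0$ or a fixed $\lambda$.

## Detection

**Clique stage** (`detectCliqueNetworks()`): greedy seed-and-grow with
multiple restarts. Seeds are the top `nRestarts` (default 20) heaviest
edges; the search alternates the best single-node addition and the best
single-node removal until no move improves the score, with ties broken
toward the smaller node index. Every accepted move strictly increases the
score, so the search terminates; each extraction removes at least
`minSize` (default 3) nodes, so the extraction loop terminates. Extracted
networks are node-disjoint. The procedure is deterministic given
$(\mathbf{W}, \text{config})$.

**k-partite stage** (`detectKPartiteNetwork()`): for each $k$ in
$2..k_{\max}$ (default 3), Kernighan–Lin-style single-node relabeling
from `nRestarts` random balanced initializations maximizes the
between-set score over partitions of the node set into $k$ nonempty sets.
The largest score wins; ties go to the smallest $k$ (parsimony). If
nothing scores above 0 the degenerate no-network result (`NULL`) is
returned.

**Combination** (`detectAll()`): the clique stage discovers node sets;
each set with $\ge 4$ nodes is rescored k-partitely and the k-partite
reading is kept only when it strictly beats the clique score on the same
nodes. This is how a planted bipartite network is found in practice: its
heavy between-set edges make the node set attractive to the clique stage,
and the rescoring then identifies the partition. The residual graph (all
unassigned nodes) also gets one k-partite attempt, which catches
structures too diffuse for the clique stage; with the default margin this
attempt certifies essentially never under the null. Whether k-partite
detection should reconsider clique nodes or only residual nodes is not
externally fixed; `detectAll()` does both and keeps the better reading
per node set.

## Permutation inference

`permutationTest()` permutes subject group labels (preserving group
sizes) $B$ times. In each permutation the *entire* pipeline — edgewise
tests, $\lambda$, clique extraction, k-partite rescoring — is re-run with
identical configuration, and the maximum detected network score is
recorded (0 when nothing is detected). Re-running detection inside every
permutation is what makes the reference distribution honest about
selection: the observed score of a *searched-for* network is compared
against the best score the same search achieves on exchangeable data.
Each observed network receives the add-one estimator

$$p_k = \frac{1 + \#\{b : \max_b \ge \mathrm{score}_k\}}{B + 1},$$

which is never zero and lies in $[1/(B+1), 1]$. All observed networks are
compared against the same permutation maxima (a suprathreshold
collection; no step-down refinement). $B = 999$ is a sensible default for
real analyses; calibration and power experiments in the test suite use
$B = 99$, the smallest round count that resolves $\alpha = 0.05$
comfortably. $B < 19$ is refused outright.

Per-permutation seeds are pre-drawn from the main seed, so results do not
depend on execution order and identical `(sample, config, B, seed)` give
identical p-values.

## The synthetic generator

`simulateConnectomes()` emulates the analysis-ready object the pipeline
consumes: two groups of symmetric Fisher-Z matrices. Edge $(i,j)$ of a
subject in group $g$ is drawn independently as
$\mathcal{N}(\mu_0 + \Delta_{g,ij},\ \sigma^2)$, where $\Delta$ is the
planted shift (applied to group B; group A is the reference, so
$\delta < 0$ means hypoconnectivity in the case-like group) on the
affected edges of the planted networks — all within-set pairs for a
clique, exactly the between-set pairs for a k-partite network — and 0
elsewhere. Defaults: $n = 90$ nodes, $48 + 65$ subjects (a typical
single-site case/control split), $\mu_0 = 0.3$ and $\sigma = 0.3$ on the
Fisher-Z scale, chosen so edge values stay in the range real resting-state
connectomes occupy. No published effect sizes exist for the networks this
method targets, so planted `delta` values are calibration choices;
$\delta = 0.6$ at $\sigma = 0.3$ with 40 + 40 subjects (per-edge
$t \approx 9$) is used as the "clearly detectable" reference condition in
the power checks, and smaller deltas probe the detection margin.

What the generator deliberately does *not* reproduce: cross-edge
correlation (edges are independent given group means, which matches the
exchangeability the permutation test relies on and keeps analytic oracles
exact), scanner artifacts, motion, site effects, or heavy-tailed subject
variation. Passing tests on this generator therefore demonstrate
correctness of the statistics and algorithms under the stated model, not
robustness to everything real data can do. Cross-edge dependence is
available through `simulateTimeSeries()`, which samples correlated
Gaussian series whose population correlation matrix is
$\tanh(\text{Fisher-Z means})$ — verified positive definite before
sampling, with configuration errors naming the offending planted delta —
and exercises the `correlationToZ()` front-end.

## Numerical and design details

* **Improvement threshold.** Local-search moves must improve the score by
  more than $10^{-9}$; together with strict increase this prevents cycling
  on ties.
* **Symmetrization.** Input matrices asymmetric by less than $10^{-6}$
  are symmetrized as $(M + M^\top)/2$; larger asymmetries are errors.
  The stored representation keeps one value per unordered edge, so
  symmetry is exact thereafter.
* **Degenerate inputs.** Zero within-group variance in both groups at an
  edge is an error naming the edge; constant ROI signals and $|r| = 1$
  are errors in the correlation front-end.
* **Group order.** The first label in the manifest (or factor levels) is
  the reference group A; direction labels in reports are built from the
  actual group names (`"TC>ASD"`), never hardcoded.
* **Validation classifier.** `classifyLOOCV()` trains an SVM (RBF or
  linear kernel, cost 1, kernel width at the `e1071` default, per-feature
  standardization estimated on each training fold) on subject-level
  Fisher-Z values over the detected networks' scoring edges. By default
  the feature edges are the full-sample detections — mirroring the common
  but leaky practice of validating selected features — while
  `nested = TRUE` re-runs detection inside every training fold for an
  honest estimate. Which edges feed the classifier (union of all
  certified networks' edges) and the standardization are explicit
  choices, stated here because no external convention fixes them.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run entirely on synthetic data
at the package's reference conditions: oracle-equivalence on 100 random
graphs of up to 10 nodes against exhaustive subset/partition enumeration;
family-wise type-I calibration over 200 pure-null simulations (90 nodes,
20 + 20 subjects, $B = 99$), judged against the exact binomial 95% band
around $\alpha = 0.05$; power and recovery over 50 seeds of a planted
8-node clique ($\delta = 0.6$, $\sigma = 0.3$, 40 + 40 subjects); and
bipartite partition recovery over 20 seeds. The acceptance script repeats
the core quantities at comparable sizes and additionally analyses one
study-patterned sample (90 nodes, 48 + 65 subjects, a 20-node clique, an
8-vs-11 bipartite network with mixed hypo/hyper edges, and a weak 5-node
clique that is expected to miss certification).

## Known limitations

* The score is a stand-in for an unpublished objective; only its
  *behavior* (oracle equivalence, calibration, power) is guaranteed, not
  equivalence to any other implementation.
* Greedy + restarts is a local search: on adversarial weight
  configurations it can fall short of the exhaustive optimum (observed in
  well under 5% of random small graphs, by under 1% relative score).
* Detected networks are node-disjoint by construction; overlapping
  networks and richer topology families (rich-club, hypergraphs) are out
  of scope.
* The permutation test's exchangeability assumption means covariate
  imbalance between groups (age, motion) must be handled upstream.

## A worked example

```{r example, eval = FALSE}
library(latentconn)

cfg <- generatorConfig(
  nNodes = 90, nSubjectsA = 40, nSubjectsB = 40,
  planted = list(plantedClique(1:8, 0.6)), seed = 11)
out <- simulateConnectomes(cfg)

ev <- edgewiseTests(out$sample)
nets <- detectAll(weightMatrix(ev))
res <- permutationTest(out$sample, nets, B = 99, seed = 5)
summarizeInference(res)

rep <- classifyLOOCV(out$sample, scoringEdges(resultNetworks(res)[[1]]))
rep
```
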
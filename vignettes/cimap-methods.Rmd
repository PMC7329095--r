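---
title: "Stabilised CI-maps: models, policies and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilised CI-maps: models, policies and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimapr)
```

# The problem

Given a table of categorical observations, we want the undirected graph
whose missing edges encode conditional independences supported by the data
— a conditional-independence map (CI-map) — and, from it, a directed
acyclic graph (DAG) that can serve as the structure of a Bayesian network.
Constraint-based search of this kind is statistically fragile: thousands of
tests are run, their order matters, and both spurious edges (false
positives) and missed edges (false negatives) accumulate.  `cimapr`
implements a stabilised PC-style pipeline: mutual-information G-tests,
weakest-first ordering, three false-discovery-rate (FDR) schedules, an
optional power-based test-skipping policy (false-negative reduction, FNR),
BIC-scored orientation, and bootstrap selection of a representative CI-map
around a target variable.

# The independence machinery

For a pair $(X, Y)$ and a conditioning assignment $A$, the test statistic
is the likelihood-ratio (G) statistic over the contingency table,

$$G = 2 \sum_{i,j,a} O_{ij|a}\,\ln\frac{O_{ij|a}}{E_{ij|a}},$$

with expected counts $E$ formed from the margins within each conditioning
slice.  $G$ is asymptotically $\chi^2$ with
$df = (|X|-1)(|Y|-1)\prod_k |A_k|$ and is linked to the plug-in conditional
mutual information in bits by $G = 2N\ln(2)\,I$; the package asserts this
identity to $10^{-9}$ relative error in its tests.  Numerical conventions:
$O\ln(O/E)$ is taken as 0 when $O = 0$; a conditioning slice with zero
total is skipped; `df` is **not** reduced for empty slices (the printed
formula is unconditional).  p-values use the central $\chi^2$ asymptotics
only — no exact or permutation fallback.

Two rules can skip a test, in which case the PC default applies and the
edge is kept:

* **Reliability (rule of thumb).** If $N/df < 5$ the $\chi^2$
  approximation is not trusted.  We apply the rule per test with the
  conditional `df` of the test about to run; `category_budget()` applies
  the same rule as a pre-flight guard when choosing how many quantile bins
  a continuous feature can afford.  The budget's default worst case is the
  unconditional pairwise $df = (c-1)^2$; an optional `cond_vars` argument
  inflates it by $c^k$.  With two conditioning variables a 239-row cohort
  caps at three categories, which is the regime the spectra tables here
  are meant to emulate.
* **FNR.** With an enabled `fnr_config(alpha, beta, w)`, a test is skipped
  whenever its `df` exceeds the largest `df` at which a level-$\alpha$
  $\chi^2$ test still has power $1-\beta$ against noncentrality
  $\lambda = N w^2$ (Cohen's chi-squared power formulation — it uses
  exactly the stated ingredients $N$, $\alpha$, $\beta$, $w$).  As
  $w \to 0$ the threshold reaches 0, every test is skipped and the graph
  stays complete; the effect-size scan driver shows the resulting false
  positive blow-up.

# The skeleton search

`cimap()` runs a level-wise PC search from the complete graph.  All
order-dependence is pinned down so that the output is invariant to the
input column order:

* node order: ascending average pairwise unconditional MI (weakest first),
  ties by name;
* edges within a level: ascending unconditional MI of the edge, ties by
  the name pair;
* conditioning subsets: lexicographic in the weakest-first node order,
  first from one endpoint's neighbourhood and then the other's, with
  duplicate subsets tested once.

The per-edge p-value retained for multiple-testing control is the
**maximum** p-value over all tests performed on that edge — the most
conservative evidence of dependence.  The Benjamini–Hochberg step-up over
these per-edge p-values treats dependence (small p) as the discovery;
edges that are not discoveries are pruned, recording as separating set the
conditioning set of their weakest-evidence test.  The three schedules are
`basic` (one pass after convergence), `interleaved` (a pass after each
conditioning-set size) and `mini` (individual tests never prune; only the
per-level pass does).  Skipped tests carry no p-value and never enter the
pass.

A consequence worth knowing: under the max-p convention the `basic` and
`interleaved` passes can never remove an edge that survived individual
testing, because every surviving edge has all its p-values below
$\alpha$, so the largest order statistic always satisfies the step-up
condition at rank $m$.  Only `mini` gives the FDR pass real pruning work.
We keep the convention because it is the conservative reading of per-edge
evidence and because the schedules are then exactly comparable; the
benchmark driver (`fdr_comparison()`) indeed finds the three schedules
statistically indistinguishable, which is also the conclusion the method
reaches on benchmark networks.

## What a false positive costs, structurally

A removal opportunity for a null pair is a conditioning set, reachable
from the endpoints' adjacency sets, that actually separates the pair.
Each separating test leaves the edge in place with probability
$\approx \alpha$.  A marginally dependent null pair with a *single*
reachable separating set is therefore a false positive in roughly 5% of
runs at $\alpha = 0.05$ — and a spouse pair of an unshielded collider is
always in this situation, since every conditional test is
collider-opened.  Exact-recovery experiments in this package use chain
fixtures, where every null pair has at least two separating sets; the
recovery tests then sit at the $\alpha^2$ scale per pair.  This is a
fixture feasibility condition, not a tuning knob: no fixture choice can
push collider spouse pairs below the $\alpha$ floor.

# Orientation and scoring

`orient_v_structures()` orients every unshielded triple $X - Z - Y$ as a
collider $X \to Z \leftarrow Y$ iff $Z$ is absent from the recorded
separating set of $(X, Y)$.  Conflicting claims are resolved
deterministically: triples are processed in sorted name order and the
first claim on an edge wins; a claim that would close a directed cycle is
skipped.  `rule_closure()` applies the four standard orientation rules to
a fixpoint; the closure is idempotent and is checked in the tests against
both a second, independently structured implementation and an exhaustive
enumeration oracle (all acyclic orientations consistent with skeleton and
collider pattern) on small graphs.

`extend_to_dag()` makes the remaining undirected edges directed by
sweeping nodes in a chosen order — descending average MI for TSF
(strongest first), ascending for TWF, or a seeded permutation — orienting
each node's undirected edges away from it, with an acyclicity check after
every orientation that reverses the edge on violation (reversal cannot
itself create a cycle, so progress is guaranteed).  Node-level ordering by
average incident-edge MI is our resolution of an underdetermined point
(the alternative is edge-level ordering); orientation runs from earlier to
later nodes.

`bic_score()` is the maximum-likelihood log score with the
$\tfrac{\ln N}{2}\,\mathrm{Dim}_G$ penalty, $\mathrm{Dim}_G =
\sum_v (|v|-1)\prod_{p \in \mathrm{pa}(v)} |p|$, with the
$0\ln 0 = 0$ convention (no pseudocounts), so scores are finite and
non-positive and all members of an I-equivalence class (same skeleton and
colliders) score identically.  `cimap_to_dag()` scores the TSF extension
as a baseline and then `max_iter` seeded random orders, returning the
best; identical DAGs are score-cached, the returned score is monotone in
`max_iter` for a fixed seed stream and never below the baseline.  Random
extension can create *extra* colliders relative to the PDAG — that is
precisely why random restarts can beat the TSF baseline, and why the
node-order experiment reports best/worst-of-$k$ distributions.

# Bootstrap selection around a target

`bootstrap_cimaps()` learns one CI-map per N-out-of-N resample, with
replicate seeds derived from the master seed by a counter-based split (so
replicate $k$ is stable no matter how many replicates are requested).
`association_histogram()` tallies, per node, the percentage of maps in
which it is adjacent to the target (first order) or at graph distance
exactly two (second order; the two sets are disjoint within a map, so the
two percentages for a node sum to at most 100 — complementary percentages
between the two orders are the signature of nodes swapping positions).
`hierarchical_filter()` then keeps the maps exhibiting the most frequent
first-order connection, then the next, then second-order connections
(first order is exhausted before second — our reading of an ambiguous
prose description), ignoring nodes below a 10% prevalence cutoff,
stopping when a single map remains or all survivors have equal edge sets.
Deterministic tie-breaks: frequency ties by node name; a filter step that
would empty the collection is skipped; several equal survivors resolve to
the earliest replicate; if no node reaches the cutoff at the first step
the modal map by exact edge-set equality is returned with a warning.
`most_representative_cimap()` composes the three stages; with a
multi-category label, run it once per binary category indicator, one
target per map.

# The synthetic spectra generator

`synth_mrs_table()` emulates the tabular shape of a small single-voxel
MRS cohort: 239 subjects by default, ten features named after the
clinically relevant signals (ML, Lac, Ala1, Ala2, NAA, PCr, Cho, Tau,
Gly/m-Ins, Glx), a binary class column, Gaussian noise with exchangeable
correlation 0.3 (a mild shared-intensity coupling; an arbitrary full
correlation matrix can be supplied), and per-feature class shifts in
noise-SD units (default: one dominant feature at 1.5, one at 0.8, one at
0.4, the rest null — a dominant-plus-secondary association profile).
What it does **not** emulate: spectral physics (peak overlap, baseline,
phasing), heavy-tailed intensity noise, class-conditional covariance
changes, or multi-class label structure.  Passing the recovery tests
therefore shows the pipeline finds planted mean-shift associations at
realistic cohort sizes; it says nothing about robustness to those
unmodelled features of real spectra.

Continuous features are discretised by `discretize_quantiles()`
(equal-frequency bins; ties at a cut go to the lower bin, making the
binning deterministic, order-free and monotone), with the category budget
above deciding how many bins the sample size affords.

# Problem sizes and defaults

The shipped defaults are the recommended setup: $\alpha = 0.05$, FDR
`basic`, FNR disabled (the effect size needed to make FNR help must be
tuned to the dataset and sample size, and a mis-set value inflates false
positives — the scan drivers exist to show exactly this).  Bootstrap
default is $b = 400$ replicates; the packaged tests and the acceptance
script run $b = 50$ over 20 pipeline repetitions, which already
concentrates the top first-order percentage to within a few points.
Benchmark-scale experiments (tens of thousands of observations on
27–37-node networks, 100-dataset score distributions, sample-size scans
to $10^5$) are supported by the same drivers but are exercised at reduced
sizes in the test suite: recovery at $n = 10^4$ on an 8-node fixture,
d-separation agreement at $n = 2\times 10^4$ on 5-node chains, 20-dataset
score orderings.  The published statistics for the Insurance and ALARM
repository networks (e.g. 27 nodes, 52 edges, 984 parameters, average
Markov blanket 5.19) are asserted by a conditional test that runs when
the corresponding BIF files are placed under
`tests/testthat/networks/`; they are not redistributed with the package.

# Known limitations

* Stable-PC-style majority sepsets, conservative PC, FCI/latent variables
  and CPDAG algorithms are out of scope.
* The FDR schedules realise one concrete reading (BH step-up over
  per-edge max-p) of a loosely specified family; other readings prune
  more aggressively.
* The FNR threshold uses the standard noncentral-$\chi^2$ power model;
  published df thresholds derived from other power conventions need not
  match it exactly.
* Near-deterministic conditional distributions (e.g. symmetric-Dirichlet
  CPTs at small concentration) produce genuine conditional
  near-independences on true edges; no test-based method recovers such
  edges, and the random-network tests assert exactly that boundary.
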
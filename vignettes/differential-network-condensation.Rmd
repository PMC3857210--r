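---
title: "Differential network condensation and K/L active-subgraph mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential network condensation and K/L active-subgraph mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcondense)
library(dplyr)
```

# The problem

Two-group expression studies — for example responders versus non-responders
to a chemotherapy regimen — are usually summarized gene by gene. Gene-level
testing misses a complementary signal: a *pair* of interacting proteins can
change its joint activity substantially even when neither gene alone passes
a differential-expression filter. `netcondense` implements two
network-level views of such data on top of a confidence-filtered
protein-interaction network:

1. **Link-score condensation** — score every network interaction by the
   change in the product of its endpoints' mean expression between the
   groups, then *condense* the network to the k most up- and k most
   down-regulated interactions.
2. **K/L active-subgraph mining** — binarize per-case differential
   expression into an indicator matrix and search for the largest connected
   subgraphs whose genes are "active" in all but at most L case samples,
   allowing at most K inactive exception genes per subgraph
   (individual-node-exception semantics).

Both views are complementary by design: condensation ranks *interactions*
and tolerates non-significant endpoint genes; the K/L model insists on
per-case activity and exposes cohort heterogeneity through the L parameter.

# The link score

For an interaction $(i, j)$ with strictly positive group-mean intensities
$\bar{x}^{A}, \bar{x}^{B}$ (reference and case group respectively):

$$
LS_{ij}
 = \log_2 \frac{\bar{x}^{B}_i\,\bar{x}^{B}_j}{\bar{x}^{A}_i\,\bar{x}^{A}_j}
 = \underbrace{\log_2 \frac{\bar{x}^{B}_i}{\bar{x}^{A}_i}}_{\text{fold change of } i}
 + \log_2 \frac{\bar{x}^{B}_j}{\bar{x}^{A}_j}.
$$

The score is symmetric in the endpoints, antisymmetric under swapping the
groups, and invariant to a common rescaling of all intensities. Modelling
interaction strength as proportional to the product of the partners'
abundances (a mass-action view), $LS$ is the log2 fold change of that
strength. A difference-of-products variant
(`compute_link_scores(method = "difference")`) is provided for comparison;
it is *not* scale-invariant and is never the default.

Group means are taken on the **linear** intensity scale and the logarithm is
applied inside the score. Whether historical cohorts averaged log- or
linear-scale values is usually undocumented; taking linear means is the
package's fixed choice, and users who prefer log-scale averaging can
transform before calling `group_means()`.

## Condensation, testing, components

`select_top_links()` keeps the `k_up` edges with the largest positive and
the `k_down` edges with the most negative scores (default 16 + 16, a size
that yields subnetworks of a few dozen genes on genome-scale networks).
Ties are broken by the canonical edge identifier so results are
reproducible; requesting more edges of a sign than exist clamps with a
warning. Up-edges must have $LS > 0$ and down-edges $LS < 0$: a zero score
carries no direction and is never selected.

Interaction-level significance uses the per-sample analogue of the score,
$a_s = \log_2 x_{i,s} + \log_2 x_{j,s}$, compared between groups with a
two-tailed Welch t-test. Welch is the default because the two groups are
typically unbalanced (e.g. 182 vs 48) with no reason to assume equal
variances; Student's pooled test is available via `var_equal = TRUE`.
Gene-level testing applies the same test to single-gene log2 values and
reports the *fraction* of tested genes that are significant — the statistic
that contrasts interaction-level with gene-level signal in a condensed
subnetwork. Benjamini-Hochberg adjustment is applied **across the supplied
item set** (the selected edges, or the subnetwork's genes); that matches the
usual reporting of a condensed subnetwork as a self-contained object.
Passing the full network's edge or gene universe instead simply means
calling the test functions with the larger set.

# Preprocessing contract

The preprocessing chain is fixed as: quantile normalization at probe level,
probe-to-gene collapsing by arithmetic means, then group means. Quantile
normalization (delegated to `limma::normalizeQuantiles`, `ties = TRUE`)
forces every sample to the identical value distribution — the across-sample
means of the rank-ordered values — with tied values receiving the mean of
the rank-means they span, a deterministic, order-independent policy.
Probes mapping to more than one gene are dropped before collapsing (only
the many-probes-to-one-gene direction is well defined); unmapped probes are
dropped with a reported count. Missing values are rejected rather than
imputed, and zero or negative intensities on the linear scale are an error
unless an explicit floor (`read_expression(floor = )`) is requested —
silent clamping is a frequent source of irreproducibility.

Identifier matching between expression and network is exact and
case-sensitive. Alias resolution depends on annotation-file versions and is
deliberately out of scope; the mapped-gene and dropped-edge counts are
reported so a user can notice namespace mismatches immediately.

The confidence filter keeps an interaction when **any** selected evidence
channel (experimental, database, textmining by default) reaches the
threshold (default 0.85). This is the literal reading of an "or" over
channels; a combined-score mode, $1 - \prod_c (1 - s_c)$, is available via
`combined = TRUE` for users who prefer a single aggregate confidence.

# The indicator matrix and the K/L model

After per-sample standardization (mean 0, variance 1 per sample; sample
variance with divisor $n-1$), each case sample's value for gene $i$ is
compared against the reference group's gene-wise mean $m_i$ and standard
deviation $s_i$:

$$ z_{ic} = \frac{x_{ic} - m_i}{s_i}, \qquad
   \text{indicator}_{ic} = \mathbf{1}\{|z_{ic}| \ge \Phi^{-1}(1 - \alpha/2)\} $$

with $\alpha = 0.05$, i.e. $|z| \ge 1.959964$. The test is two-tailed —
activity means *differential* expression in either direction — and genes
with zero reference variance get all-zero rows with a warning rather than
propagating infinities. Under the null the activation rate is close to
$\alpha$; it runs slightly above it because $m_i$ and $s_i$ are estimated,
and per-sample standardization couples genes within a sample. Both effects
shrink with the number of reference samples and genes.

A gene is **active** at level L when its indicator row has at most L zeros
among the case samples. A valid solution of the K/L model is a connected
induced subgraph containing at least one active gene and at most K inactive
(exception) genes, maximal with respect to its gene count. Requiring at
least one active gene makes "no gene is active" produce an empty result for
any K — exception-only subgraphs say nothing about the cases. Network genes
absent from the indicator matrix are treated as inactive exception
candidates.

## Solvers

The original tooling for this model searches with an ant-colony
metaheuristic. What matters scientifically is the constraint model and the
behavior of K and L, not the metaheuristic's trajectory, so `netcondense`
ships two transparent solvers with identical constraint semantics:

* `solve_ines_exact()` — a branch-and-bound enumeration of connected
  induced subgraphs. Each subgraph containing at least one active node is
  generated exactly once (enumeration is rooted at its smallest active
  node, with earlier active roots forbidden), and branches that would
  exceed the K budget are pruned — exact because feasibility is
  anti-monotone in adding inactive nodes. The enumeration is exponential in
  the worst case; the solver refuses instances above 25 nodes (and guards
  with an internal cap of 200,000 enumerated subsets), which is exactly the
  regime where it serves as the reference for the greedy solver and for
  tests.
* `solve_ines_greedy()` — from each active seed gene, visited in a
  seed-controlled random order, repeatedly add the feasible neighboring
  gene that most benefits the growing solution: active genes first, then
  genes adjacent to the most not-yet-included active genes, then the
  lexicographically smallest. Growth stops when no feasible neighbor
  remains. Every greedy solution satisfies the constraints by construction
  and is additionally checked by an independent validator in the tests.

Solutions are deduplicated to distinct node sets and ranked by size, then
total active indicator entries, then lexicographic node-set key — a total
order, so results are deterministic given a seed. `min_L_for_size()`
exploits that the optimum size is monotone non-decreasing in L and binary
searches for the smallest L reaching a target size (with the greedy solver
the answer is approximate from above, since greedy sizes are lower bounds).

# Over-representation analysis

`enrich()` is a generic, database-free replacement for proprietary
functional-enrichment tools: one-sided hypergeometric upper-tail
probabilities $P[X \ge \text{overlap}]$ per gene set, BH adjustment across
sets, with the background defaulting naturally to the annotated network's
gene universe — the sampling frame from which the subnetwork methods draw.
Depletion is deliberately not tested. Gene sets are read from GMT files.

# The synthetic generator

`simulate_study()` generates the benchmark conditions used throughout the
tests: a connected random network (100 genes, 250 edges by default; an
Erdős–Rényi G(n, m) graph — a deliberately structure-free null; a
preferential-attachment option exists for degree-skewed networks), and a
two-group matrix of 182 reference vs 48 case samples. Per-gene baseline
log2 intensities are Normal(8, 1.5), shared across samples; per-entry noise
is Normal(0, 0.3) on the log2 scale; the matrix is exported linear
($2^{\text{value}}$). The group sizes mirror a realistic unbalanced cohort,
the baseline spread matches typical microarray log-intensity ranges, and an
endpoint effect of 1.5 log2 units with $\sigma = 0.3$ puts planted
interactions (link score $\pm 3$) far outside the null score spread
($\approx 0.07$ at these group sizes) — a regime where recovery should be
essentially perfect, which is what the acceptance suite verifies.

Planted edges (8 up + 8 down by default) shift *both* endpoints by
$\pm$effect in a **carrier subset** of the case group,
$|\text{carriers}| = \text{round}(\text{carrier\_fraction} \cdot n_B)$,
drawn independently per edge (or shared, to mimic a coherent case subtype).
Carrier fractions below 1 emulate case heterogeneity: at
`carrier_fraction = 0.25` each planted gene is active in roughly 12 of 48
cases, so every gene fails the activity test at L = 10 and the K/L search
returns an empty result, while L near 38 readmits the planted genes — the
qualitative empty-then-populated pattern that motivates exploring L.

Two generator details deserve justification:

* **Unconfounded planting.** Planted edges have pairwise disjoint endpoints
  and, within each direction, form an *induced matching*: no other network
  edge connects two same-direction endpoints. An incidental edge between
  two up-shifted genes would have exactly the planted score, making
  edge-level precision/recall ill-defined. This is a property of the truth
  construction, not a relaxation of the recovery task.
* **Named RNG streams.** Every operation draws from its own stream derived
  from the user seed, so adding an operation to the generator never
  perturbs the draws of existing ones, and identical seeds give
  bit-identical outputs.

What the generator does **not** emulate: probe-level effects (saturation,
background, cross-hybridization), batch effects, gene-gene correlation
beyond the planted shifts, and heavy-tailed noise. Passing the recovery
benchmarks therefore demonstrates correctness of the algorithms under their
stated model, not performance on real cohorts — on real data the
interesting failure modes are annotation mismatch, correlated noise and
partial carriage, of which only the last is modelled (via
`carrier_fraction`).

# Numerical choices and degenerate inputs

* Quantile-normalization ties: mean of the spanned rank-means.
* Standard deviations use divisor $n-1$ everywhere.
* Top-k ties: stable order by $(-LS, \text{edge id})$ for up and
  $(LS, \text{edge id})$ for down.
* Connected components are reported sorted by decreasing size, then by
  lexicographically smallest member.
* Constant sample columns are an error in `standardize_samples()` (named in
  the message); zero-variance reference genes yield all-zero indicator rows
  with a warning.
* Empty networks after filtering are returned (with a warning), not
  errors; disjoint identifier namespaces are errors.
* An empty selection has undefined precision, reported as `NA`.

# Problem sizes in the tests

The test and acceptance suites run at desk scale: random score tables up to
30 edges (1,000 replicates), solver cross-validation on 200 random graphs
of 8–12 nodes against full connected-subset enumeration, 100 replicates of
the 100-gene/250-edge/230-sample recovery scenario, and a 60-gene null
calibration with 2,880 indicator entries. These sizes were chosen so every
oracle (exhaustive enumeration, closed-form tails, hand computations)
remains exact; the package itself handles genome-scale inputs through the
greedy solver and vectorized scoring.

# Known limitations

* The exact K/L solver is for small instances only; on large networks the
  greedy solver provides valid but not provably optimal solutions, and
  `min_L_for_size()` inherits that approximation.
* BH adjustment within a selected subnetwork conditions on the selection;
  network-wide adjustment (supply the full edge set) is the conservative
  alternative.
* Identifier handling is exact-match; users must harmonize namespaces
  upstream.
* The indicator z-test treats reference parameters as known; with few
  reference samples the activation rate runs above the nominal level.
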
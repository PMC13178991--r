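---
title: "Models and methods in netbackbone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in netbackbone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbackbone)
```

## The problem

A network backbone is a sparse unweighted subgraph that retains only the
edges judged "important". Importance is model-relative: statistical models
compare each edge weight with its expectation under a null model and keep
significant edges; structural models keep edges that matter for the
network's topology. `netbackbone` implements both families for three kinds
of input — weighted networks, bipartite networks whose projection is the
object of interest, and unweighted networks — behind a single
auto-detecting `backbone()` wrapper. This vignette records the models, the
conventions and numerical choices behind them, and what the test suite
does and does not establish.

## Weighted networks

Let $w_{ij}$ be the weight of edge $(i,j)$, $k_i$ node $i$'s degree and
$s_i = \sum_j w_{ij}$ its strength.

**Global threshold** keeps edges with $w_{ij} > t$, strictly ("larger
than"); ties are excluded. It is blind to multiscale structure: in a
system where one hub moves ten times the volume of another, a global cut
at the mean keeps only the busy region.

**Disparity filter.** Under the null, node $i$'s strength is split
uniformly at random among its $k_i$ edges (order statistics of a uniform
sample), so the fractional weight $f_{ij} = w_{ij}/s_i$ exceeds its
observed value with probability $p = (1 - f_{ij})^{k_i - 1}$. Each edge
gets two endpoint p-values; the edge-level p-value is their **minimum**
(retain if either endpoint finds the edge surprising), matching common
practice; a max rule is available via `rule = "max"`. A degree-one
endpoint is uninformative: we adopt the $0^0 = 1$ convention, so pendant
edges are never retained on statistical evidence alone. Because the null
is continuous, the lower tail is the complement of the upper tail.

Two consequences worth knowing. First, a node whose edges all carry equal
weight has endpoint p-value $((k-1)/k)^{k-1} \ge e^{-1} \approx 0.37$ for
every edge — near-equal-weight hubs can never pass conventional $\alpha$
levels, no matter how heavy their edges are. Second, on the bundled
two-hub toy (`gen_hub_spoke()`), the only edge that is dominant from
anyone's perspective is the bridge (it carries more than half of the weak
hub's strength), so the $\alpha = 0.05$ disparity backbone is exactly the
bridge. A reading of that toy in which every spoke survives at
$\alpha = 0.05$ is analytically impossible under these formulas; the suite
asserts the correct bridge-only behavior and checks hub-and-spoke
preservation at a liberal $\alpha$ instead.

**LANS** replaces the parametric null with the node's own empirical
distribution: $p = \#\{l : f_{il} \ge f_{ij}\}/k_i$, an *inclusive* upper
tail (it counts the edge itself, so $p \ge 1/k_i$, and ties at a node give
$p = 1$). The inclusive form is a valid, conservative p-value; a strict
variant (ties scoring zero) exists in the wild but can declare every edge
of an equal-weight node significant, which we consider undesirable.

**MLF** treats the total integer weight $T = \sum w$ as $T$ independent
units, each landing on pair $(i,j)$ with probability
$q_{ij} = s_i s_j / (2T^2)$ (two independent strength-proportional stub
draws), so $w_{ij} \sim \mathrm{Binomial}(T, q_{ij})$ with inclusive
tails. Weights must be positive integers; no silent rounding is performed
(rescale explicitly if needed). Unlike disparity and LANS, whose p-values
are invariant to global weight rescaling, MLF is deliberately not: $T$
changes.

## Bipartite projections

For a binary agents-by-artifacts incidence $B$ with row marginals $r_i$,
column marginals $c_k$ and fill $f$, the projection weight
$P_{ij} = \sum_k B_{ik} B_{jk}$ counts shared artifacts. Raw $P_{ij}$ is
noisy precisely because of the marginals, so the null models condition on
them, with increasing strictness:

* **fixedfill**: only $f$ is constrained; cells are i.i.d.
  Bernoulli$(f/mn)$ and $P_{ij} \sim \mathrm{Binomial}(n, (f/mn)^2)$.
* **fixedrow**: row marginals exact; holding $j$'s artifacts fixed, $i$'s
  $r_i$ artifacts are a uniform draw, so $P_{ij}$ is hypergeometric
  (population $n$, successes $r_j$, draws $r_i$) — symmetric in the pair.
* **fixedcol**: column marginals exact; artifact $k$ is shared by a given
  pair with probability $c_k(c_k-1)/(m(m-1))$, independently across
  artifacts, giving a Poisson–binomial overlap.
* **SDSM**: both marginals constrained *on average* via the bipartite
  configuration model (below); artifact $k$ contributes
  Bernoulli$(p_{ik} p_{jk})$ and the overlap is Poisson–binomial.
* **FDSM**: both marginals constrained *exactly*; the null is sampled.

The fixedfill and fixedcol forms are the independent-cell conditioned
variants; exact conditioning on $f$ is possible but was not adopted — each
form is validated against its own simulation oracle (shuffled columns,
i.i.d. fills), not against any external implementation bit-for-bit.

**BiCM.** The maximum-entropy distribution over binary matrices with given
expected marginals has cell probabilities
$p_{ik} = x_i y_k / (1 + x_i y_k)$. `bicm_fit()` solves for the factors by
damped fixed-point iteration on the *reduced* system of distinct degrees
(rows or columns with equal marginals share factors), after exactly
peeling boundary rows/columns (empty or full get $p = 0/1$, with the
remaining effective marginals adjusted). Convergence is declared when the
largest marginal residual is at most `tol` (default `1e-8`);
non-convergence after `max_iter` sweeps is an error that reports the
residual rather than returning a silently bad fit.

**Poisson–binomial tails.** Exact tails use a dynamic-programming
convolution with the count axis capped at the observed value (mass beyond
the cap is absorbed), so cost is $O(n \cdot \mathrm{obs})$; this is run
for up to 8192 artifacts, which keeps both the toy scale and a
Senate-sized study (3035 artifacts) exact. Beyond that, a
continuity-corrected normal approximation with a first-order skewness
term is used; at $n = 100$ it agrees with the exact tail to better than
$10^{-3}$ in the suite.

**FDSM sampling.** Matrices with both marginals fixed are sampled with
curveball trades (`fastball_sample()`): pick two rows, pool the columns
held by exactly one, reshuffle the pool preserving row sums. The chain is
serial — each retained sample is `trades_per_sample` (default
`max(100, 5m)`) trades past the previous one — and starts at the observed
matrix, itself a valid state, so no separate burn-in is used. P-values are
add-one: $p = (1 + \#\{P^*_{ij} \ge P_{ij}\})/(1 + \text{trials})$, which
avoids exact zeros and makes $p \in [1/(\text{trials}+1), 1]$. Fixing
`seed` fixes the backbone exactly. Successive samples are not perfectly
independent; the spacing default makes residual autocorrelation negligible
at the matrix sizes tested (uniformity over the enumerated 4×4 state space
passes a chi-square check in the suite), but it is a tunable, not a
guarantee, for much larger matrices.

All projection models score *every* agent pair, not only pairs with
positive projection weight: under `signed = TRUE` a pair sharing
suspiciously few artifacts is retained as a negative edge. The removal
percentage is always reported relative to the positive-weight projection
edges.

## Unweighted networks

Unweighted backbones follow a four-step pipeline: **escore** assigns each
edge a structural score; **normalize** optionally converts scores to local
ranks; **filter** keeps edges by threshold, global proportion, or per-node
degree quota; **umst** optionally unions the result with the union of
maximum spanning trees. Named models are preset combinations — e.g. local
sparsification (`lspar`, the default) is jaccard scores, local ranks, and
the degree filter.

Documented conventions, chosen once:

* **Closed neighborhoods** for jaccard/meetmin/geometric
  ($N[i] = N(i) \cup \{i\}$), so edges inside a clique score 1 and
  adjacent pendant pairs score above 0. The hypergeometric score uses
  *open* overlap with population equal to the node count.
* **Sequential local ranks** 1..$k_i$, ties broken by the neighbor's
  position in the node order — determinism over hash order. (Dense,
  tie-sharing ranks are an alternative convention; they interact with the
  quota below and were not adopted.)
* **Degree quota** $\lceil k_i^e \rceil$: node $i$ nominates its
  best-ranked $\lceil k_i^e \rceil$ edges and an edge survives when
  *either* endpoint nominates it. This guarantees minimum degree ≥ 1 on
  every non-isolated node.
* **Proportion filter** keeps the top $\lfloor e \cdot |E| \rfloor$ edges
  globally, ties broken by stable edge order; its parameter is the
  fraction *retained* (worth stating because removal percentages are the
  common way results are reported).
* **Quadrangle support** is the 4-cycle count through an edge, normalized
  by the geometric mean $Q_{ij}/\sqrt{Q_i Q_j}$ (counting 4-cliques
  instead is a known variant and scores systematically lower on sparse
  graphs).
* **Simmelian redundancy**: tie strengths are triangle counts (or the
  quadrangle coefficient for the quadrilateral variant); each node ranks
  its neighbors by strength; the redundancy of $(i,j)$ is the maximum over
  prefix sizes $k \ge 1$ of the Jaccard coefficient between the two top-$k$
  neighbor sets, each endpoint excluded from the other's list (so a bridge
  between two cliques scores 0 and every edge of $K_4$ scores 1).
* **UMST membership** uses the exact characterization: an edge belongs to
  some maximum spanning forest iff its endpoints lie in different
  components of the strictly-higher-scoring subgraph. With `umst = TRUE`
  a connected input yields a connected backbone.
* **skeleton** is seeded uniform-random scores plus the proportion filter;
  it exists for methodological comparison and warns when used without a
  seed, since it is otherwise irreproducible by design.

## Retention and significance

`retain_edges()` keeps an edge when its (optionally multiple-test
adjusted) upper-tail p-value is strictly below $\alpha$. Signed retention
splits the two-tailed test as $\alpha/2$ per tail — the conventional
reading; the alternative (doubling the smaller tail) is noted but not the
default. Discrete nulls use inclusive tails on both sides, so
$p_\mathrm{upper} + p_\mathrm{lower} \ge 1$ and an edge can receive at
most one sign. Corrections are fixed to none / bonferroni / holm / bh /
by (with `"fdr"` accepted as the customary alias for bh), implemented via
`stats::p.adjust` and validated in the suite against hand-coded step-up /
step-down oracles. Inclusive discrete tails make retention conservative:
empirical type-I error is at or slightly below $\alpha$.

## Synthetic generators: the stated world

* `gen_sbm()` (60 nodes, three blocks of 20, $p_{in} = 0.75$,
  $p_{out} = 0.25$) emulates a dense graph with planted communities; the
  expected edge count is 727.5.
* `gen_bipartite_blocks()` (30 agents × 75 artifacts, three matched
  blocks). The membership probabilities are **not** externally given; they
  were calibrated once by pilot simulation so that the stated qualitative
  behavior — SDSM and FDSM backbones at $\alpha = 0.05$ recover the three
  planted communities essentially always — holds robustly. A first
  candidate (0.35/0.08) leaves SDSM with almost no power (a handful of
  significant edges out of ~360 pairs: within-block overlaps sit well
  inside the null spread); the adopted defaults $p_{in} = 0.65$,
  $p_{out} = 0.04$ give 50/50 seeds perfect recovery for both models, with
  FDSM always retaining at least as many edges as SDSM (it is the more
  powerful null). The values are arguments, not constants.
* `gen_hub_spoke()` builds the two-scale weighted toy: bridge weight
  exactly $(\mathrm{high}+\mathrm{low})/2$, spoke weights jittered by a
  small *positive* multiplicative factor, which pins the mean edge weight
  strictly above the bridge so the mean-threshold backbone is
  deterministically the high-volume region.
* `gen_preferential_attachment()` grows a Barabási–Albert-style graph
  (default $m = 3$, a package choice giving a dense hub-dominated toy);
  $m = 1$ yields a tree.

All generators are deterministic under a fixed seed and leave the global
RNG stream untouched otherwise.

What a green suite establishes: the implementations agree with independent
oracles (closed forms, quadrature, exhaustive enumeration, Monte Carlo) at
small scale, the pipeline invariants hold, and the stated-world toys
reproduce the expected qualitative structure. What it does not establish:
behavior on networks far larger than the toys (FDSM mixing, RNA tail
accuracy in extreme tails), performance of fixedrow/fixedcol/fixedfill as
*good* nulls (they are known to be worse than SDSM/FDSM and are included
for methodological comparison), or agreement with any other package's
tie-break-level choices.

## Known limitations

* Undirected, simple networks only; multi-edges must agree in weight and
  are merged; self-loops are dropped (and counted in the load report).
* FDSM cost grows linearly in trials × trades; the defaults suit
  hundreds-of-nodes inputs, not millions.
* The refined normal approximation for >8192-term Poisson–binomials has
  absolute, not relative, accuracy guarantees — extreme tail p-values
  (say below $10^{-6}$) lose relative precision there.
* Narrative percentages are formatted round-half-even to two decimals
  with trailing zeros trimmed; the underlying result object always keeps
  full precision.
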
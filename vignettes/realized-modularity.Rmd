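---
title: "Realized modularity: measuring partition quality a posteriori"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Realized modularity: measuring partition quality a posteriori}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(realmod)
```

## The problem

Community detection methods optimize different criteria and, on the same
network, routinely return both different modularity values and different
module compositions. Their internal scores cannot be compared across
methods, so choosing among competing partitions calls for a goodness-of-fit
that is evaluated *after* nodes have been assigned to modules and is
agnostic to how the assignment was produced.

`realmod` implements such a measure, the **realized modularity**. For a
network with $E$ interactions of which $W$ join two members of the same
module,

$$Q_R = \frac{W}{E}, \qquad Q'_R = 2\,Q_R - 1 .$$

$Q_R = 1$ when no between-module links exist; $Q_R = 1/2$ (i.e. $Q'_R = 0$)
when between-module interactions are as numerous as within-module ones; and
$Q'_R < 0$ flags a partition whose "modules" exchange more interactions with
the rest of the network than among themselves. Under balanced random module
assignments $Q'_R$ is centered on 0 (a property we verify only for balanced
bisections: with many small random modules the within-module pair pool
shrinks and the expectation drops below 0, so the centering claim is
restricted to the two-equal-modules case in our tests).

The package pairs this with the Newman–Girvan modularity

$$Q = \sum_m \left( e_{mm} - a_m^2 \right),$$

where $e_{mm}$ is the fraction of edges with both endpoints in module $m$
and $a_m$ the fraction of edge endpoints attached to $m$, so the two views —
optimization criterion and realized edge ratio — can be reported side by
side for any partition.

## Data model and conventions

Networks are plain-text edge lists (one interaction per line, `#` comments,
extra columns ignored with a warning). Several conventions are deliberate
and affect counts:

- **Directed edges everywhere $E$ or $W$ is counted.** Food webs are
  directed adjacency matrices; a reciprocal pair $a \to b$, $b \to a$ counts
  as two interactions. Whether reciprocal predator–prey links should be
  collapsed before counting is genuinely ambiguous; we count them twice and
  flag the choice here so users with symmetric data can pre-symmetrize.
- **Self-loops (cannibalism) are retained.** A loop is a within-module edge
  for $Q_R$, contributes 1 to generality and 1 to vulnerability (2 to
  degree), and contributes both endpoints to its module in $Q$.
- **Bipartite incidence matrices** (host–parasite) are transformed to
  directed unipartite networks with one edge per nonzero cell, row → column,
  so every interaction is preserved exactly once. Only binary matrices are
  accepted: interaction strengths are out of scope.
- **Undirected projections** (`symmetrize()`) are used by community
  detection and $Q$; $Q_R$ is always computed on the network's native edge
  set.

Partitions are total node → module maps; labels are canonicalized to
$0..k-1$ by first appearance so partitions from tools with different label
alphabets compare equal.

## The Louvain reference detector

`louvain()` is a from-scratch implementation of the two-phase greedy
modularity optimization: phase 1 sweeps nodes in seeded-random order, moving
each to the neighboring community with the largest strictly positive gain in
$Q$; phase 2 aggregates communities into super-nodes (internal weight
becomes self-loops); the phases repeat until a pass improves $Q$ by less
than `tol = 1e-8` — the numeric floor we give to "until modularity ceases to
increase". Three choices matter for reproducibility:

- sweep order is a seeded shuffle per pass (the method is order-sensitive
  and we want bit-identical runs under a fixed seed);
- ties among equal-gain moves go to the lowest community label;
- `restarts = k` runs independent seeded restarts and keeps the best-$Q$
  partition (a single run is the default; how many restarts practitioners
  should use is an open question, so it is exposed rather than fixed).

The returned `q_trace` (one $Q$ per pass, evaluated on the original graph)
is non-decreasing by construction, and the final entry equals
`newman_girvan_q()` of the returned partition — an invariant the test suite
checks, along with exhaustive-enumeration oracles on graphs with up to 8
nodes (Louvain's $Q$ never exceeds the true maximum and attains it on most
small instances).

## The degree-profile null model

Observed modularity must be confronted with what networks of the same
degree structure produce by chance. For each node we record its generality
$g$ (successors), vulnerability $v$ (predecessors) and degree $d = g + v$;
each ordered pair then receives an independent Bernoulli edge with

$$P(i \to j) = \frac{1}{2}\left(\frac{g_i}{d_i} + \frac{v_j}{d_j}\right),$$

with zero-degree terms contributing 0 and self-pairs sampled only when the
source network itself contains loops. The expected replicate edge count is
$\sum_{i,j} P(i \to j)$, and the test suite verifies the Bernoulli process
against it.

One property of this model deserves emphasis: **it does not, in general,
conserve the expected number of edges of the source network.** A node with
only successors paired with a node with only predecessors is forced to
$P = 1$ regardless of network size, and on strongly modular graphs (where
most nodes have $g/d \approx v/d \approx 1/2$) the model approaches a dense
Erdős–Rényi limit with $P \approx 1/2$. We implement the formula verbatim
because it is the model the significance pipeline is defined with; the
constant-ratio Erdős–Rényi reduction is part of the test suite so the
behaviour is documented rather than hidden. For users who prefer a
size-normalized variant, `normalization = "size"` replaces the degree
denominators with the node count $n$; the default stays with the
degree-profile form.

Replicates with fewer than 2 edges are *discarded and counted*, never
resampled (resampling would condition the ensemble on a minimum density);
`null_ensemble()` reports the discard count, and per-replicate seeds are
derived deterministically from the master seed so ensembles are exactly
reproducible.

## Significance summaries

`summarize_null()` reduces an ensemble to null means and variances of $Q$
and $Q'_R$, percentile confidence intervals (default 90%: the 5th–95th
percentiles with linear interpolation), the deltas
$\Delta Q = Q_{emp} - \bar Q_{null}$ and
$\Delta Q'_R = Q'_{R,emp} - \bar Q'_{R,null}$, and outside-CI flags. A
percentile interval was chosen over a normal approximation because both
statistics are bounded and their null distributions are often skewed; the
estimator choice is ours and is stated rather than assumed standard.

`classify()` turns a report into one of five verdicts. The four signed
verdicts (`more-modular-both`, `less-modular-both`, and the two conflicted
quadrants, of which a low-$Q$/high-$Q'_R$ network — modules denser inside
than toward the rest of the graph, yet "not modular" by the optimization
criterion — is the interesting one) require *both* statistics to fall
outside their intervals; if only one flag fires the verdict is
`indistinct`. The label set is closed, so a partially significant outcome
maps to the conservative label rather than to a new one.

## Synthetic generators and what they do (not) show

Two generators make every pipeline stage testable without external data:

- `planted_partition(sizes, p_in, p_out)` draws each within-module pair
  with `p_in` and each between-module pair with `p_out` (anti-modular specs
  `p_out > p_in` are refused). Benchmarks use 4 modules × 25 nodes with
  `p_in = 0.3`, `p_out = 0.01` — a strongly modular, sparse regime in the
  size range of large food webs.
- `fixture_network(n_edges, n_within, sizes)` places exact counts uniformly
  among feasible pair slots; the worked example (36 edges, 31 within,
  4 modules of 9) reproduces the textbook arithmetic
  $Q_R = 31/36 \approx 0.86$, $Q'_R \approx 0.72$ on every seed. Only the
  $(W, E)$ statistics of that example are reproducible — the underlying
  drawing (and hence its Louvain $Q$) is not published, so no test asserts
  a specific $Q$ for it.

These generators emulate block-homogeneous degree structure. Real food webs
and host–parasite networks have heavy-tailed degrees, trophic ordering and
forbidden links, none of which the planted model produces; a passing suite
therefore demonstrates correctness of the measures and machinery, not that
any empirical network class will show a particular $Q'_R$ regime. The
connectance sweep used in testing (fixed `p_in/p_out = 2`, connectance
0.05–0.5, the widest ratio feasible with `p_in <= 1` across that range)
checks one qualitative contract — $Q'_R$'s rank correlation with
connectance is weaker in magnitude than $Q$'s — not any quantitative
correlation value, which would require a large empirical compendium.

## Numerical choices and degenerate inputs

- Edgeless networks: all measures refuse them ($Q_R$ is $0/0$).
- Replicate ensembles need ≥ 2 retained replicates to be summarized.
- Louvain convergence: `1e-8` per-pass improvement floor; per-move gains
  must exceed `1e-12` (guards against oscillation on floating-point ties).
- `q_prime()` clamps inputs within `1e-12` of the $[0,1]$ boundary and
  rejects anything farther out.
- Node identifiers are opaque strings; all stored edge sets are sorted
  lexicographically, so equal networks have identical representations.
- Problem sizes in the tests (e.g. 200 null replicates for the planted
  benchmark, 1000 edge-count replicates at 50 nodes, exhaustive oracles at
  $n \le 8$) were chosen so each statistical check has at least 3-standard-
  error resolution while the whole suite stays quick to run.

## A worked run

```{r example}
fx <- fixture_network(36, 31, sizes = c(9, 9, 9, 9), seed = 1)
realized_modularity(fx$network, fx$partition)

pp <- planted_partition(c(25, 25, 25, 25), p_in = 0.3, p_out = 0.01,
                        directed = TRUE, seed = 11)
det <- louvain(pp$network, seed = 11)
det
adjusted_rand_index(det$partition, pp$partition)
```

```{r nulltest, eval = FALSE}
# the full significance pipeline (a few seconds at 200 replicates)
null_test(pp$network, replicates = 200, seed = 11)
```

## Known limitations

- Weighted interactions, multigraphs and GraphML/GML input are out of
  scope; only binary edge lists and 0/1 incidence matrices are read.
- Alternative detectors (walktrap, spinglass, edge betweenness, ...) are
  supported only through partition-file import, not reimplemented.
- The degree-profile null model's connectance inflation (above) means its
  ensembles answer "is this partition more realized-modular than this
  model's graphs", not "than equally dense random graphs"; use
  `normalization = "size"` when density matters more than per-node profiles.
- Edge-list files cannot represent isolated nodes, so partitions written
  alongside generated edge lists are restricted to connected nodes.
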
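---
title: "Methods: envelope pruning of modularity partition ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope pruning of modularity partition ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(champr)
```

## The model

For a weighted undirected network with adjacency $A_{ij}$, node strengths
$k_i = \sum_j A_{ij}$ and total weight $m = \tfrac12\sum_i k_i$,
modularity with the configuration null model and resolution parameter
$\gamma$ is, up to the constant prefactor $1/2m$,

$$Q_\sigma(\gamma) \;=\; \sum_{i,j}\bigl(A_{ij} - \gamma\,\tfrac{k_ik_j}{2m}\bigr)\,\delta(c_i,c_j)
\;=\; \hat A_\sigma - \gamma \hat P_\sigma ,$$

with the sums running over **ordered** node pairs including $i=j$. The
package drops the $1/2m$ prefactor throughout so that the coefficients
$\hat A_\sigma,\hat P_\sigma$ are exact finite sums of the input weights;
`modularity_normalized()` restores it for reporting. A self-loop stored
with weight $w$ follows the usual undirected convention
($A_{ii}=2w$, contributing $2w$ to $k_i$ and $w$ to $m$); removal of
self-loops, where a data set calls for it, is an explicit preprocessing
step (`drop_self_loops()`), never implicit.

For a multilayer network in supra-adjacency form — state nodes are
(node, layer) pairs — the generalization is

$$Q_\sigma(\gamma,\omega) = \hat A_\sigma - \gamma \hat P_\sigma + \omega \hat C_\sigma ,$$

where $\hat P$ uses the per-layer configuration null $k_ik_j/2m_l$
(block-diagonal across layers; a layer with no intralayer weight
contributes nothing) and $\hat C$ sums the within-community interlayer
coupling. Only this null model is implemented; directed, signed and
bipartite variants are out of scope, as are more than the two parameters
$(\gamma,\omega)$.

Each partition is thus a line in $(\gamma,Q)$ or a plane in
$(\gamma,\omega,Q)$. Given any finite ensemble, the best available
modularity at each parameter point is the pointwise maximum — the upper
envelope — and a partition is worth keeping exactly when it owns a
non-empty piece of that envelope. Everything in this package follows from
that observation; notably, the pruning is agnostic to how the input
partitions were produced.

## Envelope construction

**One parameter.** `champ_prune_1d()` iterates forward from
`gamma_start`: the optimal line there is found by direct argmax of
$Q(\gamma_{\text{start}})$ (ties: smaller $\hat P$, then lower id), and
the next transition is the smallest crossing
$\gamma^* = (\hat A_1-\hat A_2)/(\hat P_1-\hat P_2)$ beyond the current
one, considering only lines with smaller $\hat P$ (no other line can
overtake at larger $\gamma$). When several lines pass through one
transition point the smallest-$\hat P$ line takes over (then lowest id —
the remaining exact tie is a genuine convention, and it is documented
rather than guessed around). Domains are half-open $[\gamma_p,
\gamma_{p+1})$, so a transition point belongs to the incoming domain.
Consequences tested as invariants: $\hat A$ and $\hat P$ strictly
decrease along the admissible sequence, each admissible partition owns
exactly one simply connected interval, and the domains tile the range.

The direct argmax at `gamma_start` (rather than "maximum $\hat A$", which
is the same thing only at $\gamma_{\text{start}} = 0$, the default)
keeps the envelope correct when a caller starts the analysis elsewhere.

**Two parameters.** `champ_prune_2d()` computes each plane's domain by
clipping the parameter box with the halfplanes
$Q_k - Q_j \ge 0$ against every other plane (Sutherland–Hodgman on convex
polygons). This is mathematically the same upper envelope that the dual
convex-hull / halfspace-intersection formulation yields; the incremental
clipping route was chosen because it needs no external geometry engine,
its cost ($O(n^2)$ clips for $n$ planes) is negligible at realistic
ensemble sizes, and every domain is produced directly as a convex CCW
polygon. The contract — agreement with a dense grid argmax — is what the
tests enforce, independent of the construction route.

Partitions admissible somewhere in the enlarged quadrant
$[0, 10\,\gamma_{\max}]\times[0, 10\,\omega_{\max}]$ but not in the user
box are reported separately (`out_of_box`). The 10× factor is this
package's choice of enclosing region; the truly unbounded problem is not
attempted.

**Numerical choices.** Crossings are compared with absolute tolerance
$10^{-12}$ on $\gamma$ and sub-tolerance domains are dropped; the inputs
are exact sums of edge weights, so crossings are well-conditioned and a
tighter-than-sqrt-eps tolerance is safe. In 2-D, polygon vertices are
merged below $10^{-9}$ and domains with area below $10^{-9}$ are dropped;
domain adjacency uses convex polygon intersection with tolerance
$10^{-7}$ and requires a shared segment longer than $10^{-6}$ (domains
meeting at a point are not adjacent). Records with exactly identical
coefficients are collapsed to the lowest-id representative and reported
as co-optimal — they are partitions of equal merit at every scale, and
keeping both would create zero-width domains. Degenerate inputs (empty
ensembles, non-finite coefficients, inverted boxes) raise errors rather
than guesses.

## Adjusted mutual information

Partition similarity uses AMI with max normalization,

$$\mathrm{AMI}(X,Y) = \frac{\mathrm{MI}(X,Y) - E(\mathrm{MI})}
{\max(H(X),H(Y)) - E(\mathrm{MI})},$$

in natural logs, with $E(\mathrm{MI})$ computed by the exact closed-form
hypergeometric sum over cell counts with both marginals fixed (no Monte
Carlo). The tests verify this expectation against the brute-force average
of MI over all $n!$ node permutations for $n\le 7$, and the full score
against scikit-learn's max-normalized implementation. Conventions for
degenerate inputs: two single-community partitions are identical, so AMI
is 1; if exactly one is single-community, MI and $E(\mathrm{MI})$ vanish
and the formula yields 0. Other normalizations (sqrt, sum) and other
indices (ARI, VI, NMI) are out of scope.

Three comparison views are provided: the pairwise AMI matrix ordered by
envelope domains, the border-weighted neighbor-averaged AMI over a 2-D
domain map (weights proportional to shared border lengths; domains with
no neighbor are undefined and returned as `NA`), and the layer-averaged
AMI of a multilayer partition against per-node metadata labels
(unweighted mean of per-layer AMIs).

## Sweeps and the built-in heuristic

`run_sweep()` mirrors the standard protocol: a uniform parameter grid
inclusive of both endpoints, several runs per grid point, and a random
node-order permutation per run so that an order-sensitive heuristic can
reach different local optima at the same parameters. Per-run seeds are
derived from (master seed, grid index, run index) by a fixed mixing
scheme, so a sweep is reproducible run-for-run regardless of execution
order. The output is deduplicated by canonical membership (labels
relabeled 0..K−1 in first-appearance order), with multiplicities and
first-occurrence provenance retained.

The built-in `greedy_louvain()` maximizes $\sum_{ij} B_{ij}
\delta(c_i,c_j)$ for the dense matrix $B = A - \gamma P + \omega C$ by
local moves (strict improvement only, so the objective is monotone)
followed by community aggregation, repeated to convergence. It is
deliberately minimal: deterministic given its seed, correct for both
single-layer and multilayer inputs, and $O(n^2)$ in memory — suitable
for the package's tests and for modest empirical networks, not a
replacement for optimized Louvain/GenLouvain implementations, which plug
in through the heuristic callable contract.

## Synthetic benchmarks

`planted_partition_graph()` draws the classic planted-partition model:
equal blocks, independent Bernoulli edges with probabilities `p_in`
within and `p_out` between blocks. `planted_multilayer()` stacks such
layers over the same node set, lets each node keep its block label into
the next layer with probability `persistence`, and couples consecutive
appearances of a node with identity interlayer edges of weight
`coupling` — the nearest-neighbor temporal coupling typical of
longitudinal data.

These generators emulate the *geometry* the method relies on —
recoverable ground truth, a resolution scale at which it is optimal,
temporal persistence — but not several features of real data: degree
heterogeneity, weighted or locally clustered edges, unbalanced
communities, nodes entering/leaving layers. Passing the recovery tests
therefore demonstrates the correctness of the pruning and comparison
machinery, not that any particular empirical network has recoverable
communities. The recovery test conditions (n = 80, four blocks,
`p_in` = 0.9, `p_out` = 0.05) sit far above the detectability threshold
by design, so that recovery is stable under a fixed seed.

## Problem sizes

The test-suite and acceptance-script studies use: random coefficient sets
of 5–500 lines against 10,000-point grid oracles (1-D) and 10–200 planes
against 200×200 grids (2-D); exhaustive oracles at $n\le 7$ nodes
(permutation AMI) and 6 nodes (all 203 set partitions, for the greedy
optimizer); and planted studies with 60–80 nodes, 21 γ grid points × 5
runs (single-layer) and 20 nodes × 4 layers on an 8×5 (γ, ω) grid × 2
runs (multilayer). These sizes make every oracle exact or dense while
keeping each study a matter of seconds; the algorithms themselves have no
such limits — envelope cost depends on the ensemble size, not the
network size.

## Known limitations

* Hard partitions only: overlapping communities and background nodes are
  not representable.
* The pruned subset is only as good as its input ensemble; a partition
  that is near-optimal everywhere but nowhere maximal is discarded.
* Only the (per-layer) configuration null model; one interlayer coupling
  parameter; at most two parameter dimensions.
* `greedy_louvain()` uses a dense $n\times n$ matrix; use an external
  heuristic for large networks.
* Interval arithmetic is double precision; ensembles engineered with
  near-identical coefficients below the stated tolerances may merge or
  drop hairline domains.
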
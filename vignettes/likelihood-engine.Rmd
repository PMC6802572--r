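---
title: "The prunewave likelihood engine: models, scheduling, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The prunewave likelihood engine: models, scheduling, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(prunewave)
```

## The model and the computation

`prunewave` computes the likelihood of a multiple sequence alignment on a
phylogenetic tree under reversible continuous-time Markov models of
character substitution. For a site pattern $x$ and a rooted binary tree
with branch lengths $t_e$ (expected substitutions per site), the site
likelihood is

$$L(x) = \sum_{c} w_c \sum_{i} \pi_i \, \mathrm{Pr}(x \mid \text{root}=i,
r_c),$$

where $\pi$ are the equilibrium frequencies, and $(r_c, w_c)$ are relative
rates and weights of discrete rate categories. The inner probability is
computed by the pruning (sum-product) recursion: each internal node $v$
carries a *partial likelihood array* $p_v[x, c, i]$, the probability of
the tip data below $v$ given state $i$ and category $c$, combined from its
children through edge transition matrices

$$p_v[i] = \Big(\sum_j P^{(1)}_{ij} \, p_{u_1}[j]\Big)
           \Big(\sum_k P^{(2)}_{ik} \, p_{u_2}[k]\Big).$$

Transition probabilities come from the eigendecomposition of the rate
matrix: $P(t, c) = E \, \mathrm{diag}(e^{\lambda_k r_c t}) \, E^{-1}$.
For reversible models the decomposition is obtained from the symmetric
similarity transform $\mathrm{diag}(\sqrt{\pi})\, Q \,
\mathrm{diag}(1/\sqrt{\pi})$, which guarantees a real spectrum (one zero
eigenvalue, the rest negative). Rate matrices are always normalised to
one expected substitution per unit time at equilibrium so that branch
lengths are comparable across models. Arbitrary (possibly
non-reversible) rate matrices are accepted; they take a dense
matrix-exponential route instead, with derivative matrices formed as
$QP$ and $Q^2P$.

Log-likelihood derivatives with respect to one edge length use the edge
factorisation

$$L(x) = \sum_c w_c \sum_i \pi_i \, \bar p[x,c,i] \sum_j P_{ij}(t)\,
p[x,c,j],$$

with $\bar p$ the "outside" partials of the tree minus the child subtree
(obtained by rerooting at the parent end of the edge and traversing), and
$P$ replaced by $dP/dt$ and $d^2P/dt^2$ for the derivative terms. Per
site, $\partial_t \ln L = L'/L$ and $\partial_t^2 \ln L = L''/L -
(L'/L)^2$; weighted sums over patterns give the totals. This
factorisation was chosen because it is directly testable against central
finite differences and against the closed-form two-taxon solution.

## Buffers, patterns, and partitions

The engine mirrors the buffer-store design used by accelerated
phylogenetic libraries: an *instance* owns tip buffers, internal partials
buffers, eigensystem slots, transition-matrix slots, per-subset category
and frequency slots, pattern weights, and per-pattern scale accumulators,
all addressed by integer indices (`create_instance()`,
`set_instance_data()`, `update_transition_matrices()`,
`update_partials()`, `calculate_root_log_likelihood()`). The high-level
`tree_loglik()` drives this machinery end to end for one call.

Identical alignment columns are collapsed into weighted unique patterns
per partition subset (`compress_patterns()`); the likelihood over
patterns weighted by multiplicity equals the likelihood over sites, and
all kernels run on the compressed axis. Partition-defined subsets share
one instance, occupying contiguous ranges of the pattern axis with their
own models, frequencies, rate categories and an optional per-subset
relative rate multiplier applied to branch lengths. Partials are stored
state-fastest, then category, then pattern, so per-subset evaluation is a
contiguous range slice and splitting patterns across workers is trivial.

Tips are encoded compactly (one state index per pattern, with a sentinel
for fully missing data contributing factor one) unless a sequence
contains partial-ambiguity IUPAC codes, in which case that tip is
upgraded automatically to 0/1 indicator partials, which represent
ambiguity exactly.

## Traversal scheduling and rerooting

A postorder operation list is the classic schedule. The *wavefront* plan
groups operations into reverse level-order waves by height above the
tips: wave $k$ holds the internal nodes whose longest path to a
descendant tip, counted in internal nodes, is $k$. This is the unique
grouping in which every operation in a wave has all inputs ready, so a
wave is a batch of mutually independent work; the wave count equals the
internal-node height of the tree (exactly $k$ for a balanced $2^k$-tip
tree). Execution order within a wave is deterministic (subset-major,
then node id), and results are identical — bitwise — whether a plan is
executed postorder or wave by wave.

Because a reversible model's likelihood does not depend on root
placement, the root can be moved to reduce the height.
`reroot_for_concurrency()` searches all $2n-3$ edge rootings
exhaustively (each height evaluated in linear time) and returns a
minimum-height rooting, ties broken by the lowest candidate edge index.
An exhaustive search was preferred over a heuristic because $n$ is small
at interactive scale and optimality is directly testable: an 8-tip
caterpillar drops from 7 waves to 4.

## Numerical choices

- **Gamma discretization.** Equal-probability categories use conditional
  *means* computed through the incomplete-gamma function, renormalised so
  the weighted mean rate is exactly one; means (rather than medians) have
  the exact mean-one property and are standard in the client programs
  this engine emulates. A median variant sits behind a flag. Default
  category count is 4, the conventional compromise between resolution
  and cost.
- **Round-off clamping.** $P(t)$ entries that round off slightly negative
  (at the $10^{-12}$ scale) are clamped to zero when matrices are built,
  preventing log-domain failures downstream.
- **Rescaling.** Two policies only: `none` and `always`. With `always`,
  after each partials operation every pattern's entries are divided by
  their maximum across states and categories and the log of that maximum
  is accumulated per pattern; the site log-likelihood adds the
  accumulated logs, making the procedure exactly neutral in exact
  arithmetic. Deep trees with saturated data can drive raw per-pattern
  likelihoods to exact zero in double precision (e.g. 500 tips evaluated
  under strongly skewed frequencies push per-site log-likelihoods below
  $\ln$ of the smallest subnormal, about $-745$); the rescaled path stays
  finite there. Dynamic "rescale only when needed" policies exist in the
  wild but are harder to verify; the simple pair makes the cost/benefit
  explicit.
- **Determinism.** The serial kernel, the state-count-4 unrolled
  ("vectorized") kernel, and the threaded kernel perform the identical
  floating-point operation sequence per pattern; patterns are
  independent, threads write disjoint blocks, and reductions run in
  fixed pattern order. Results are therefore bitwise identical across
  implementations and worker counts — a hard contract, enforced by the
  benchmark's cross-check before any ranking is reported.
- **Worker count.** With `max_workers = "auto"` the thread count is
  $\min(\lceil \text{patterns}/512 \rceil, \text{cores})$ — it grows with
  problem size up to the core count, and a user cap is honoured. 512
  patterns per worker keeps per-thread work well above scheduling
  overhead.
- **Finite-difference verification.** Tests compare analytic $d_1$
  against the second-order central difference with $h = 10^{-5}
  \max(t,1)$, and $d_2$ against the fourth-order five-point stencil with
  $h = 10^{-3} \max(t,1)$: with a simple three-point stencil at small
  $h$, double-precision cancellation in the curvature estimate would
  exceed the comparison tolerance, so the higher-order stencil is used
  to keep truncation and round-off simultaneously small.

## The synthetic-data generator

`random_tree()` grows a topology by attaching each new tip to a
uniformly chosen attachment point (any edge or above the root), which
makes every labeled rooted topology equally likely, and hence every
labeled unrooted topology too (each has exactly $2n-3$ rootings). This
was chosen over coalescent-style random pair joins because pair joining
is demonstrably *not* uniform on unrooted topologies for $n \ge 6$, and
uniformity is the property the test suite verifies (chi-square over all
105 six-tip topologies). Branch lengths are i.i.d. exponential; the
default mean of 0.1 substitutions/site reflects a typical interspecific
nucleotide alignment.

`simulate_alignment()` draws a category and a root state per site and
propagates states root-to-tips through the exact transition matrices.
The scaling harness (`run_synthetictest()`, CLI `synthetictest`)
simulates data for a 128-tip tree under HKY ($\kappa = 2$, frequencies
$(0.3, 0.2, 0.2, 0.3)$, gamma $\alpha = 0.5$ with 4 categories), then
evaluates the base problem plus 10 parameter variations — one random
nearest-neighbour interchange, branch lengths jittered by
$U(0.8, 1.25)$, category rates/weights jittered and renormalised,
pattern weights redrawn — across replicate seeds and pattern counts
$10^2$–$10^4$, timing every evaluation and cross-checking
implementations bitwise.

What the generator does *not* emulate: indels (sequences are generated
aligned), selection or rate autocorrelation along the sequence,
non-stationary or non-reversible base composition drift, and alignment
error. Passing tests therefore demonstrate correctness of the
likelihood machinery on model-generated data, not robustness of
inference to model violation on real data.

## Problem sizes

The shipped verification uses sizes chosen to exercise every code path
while keeping a desktop run short: exhaustive-enumeration oracles up to
6 tips and 3 categories (ancestral-state sums grow as $4^{n-1}$), 50
random 64-tip trees for schedule equivalence, 16-tip instances for
derivative checks, a 500-tip tree for underflow behaviour, and the
128-tip harness up to $10^4$ unique patterns. All random inputs are
seeded; every stochastic operation accepts an explicit seed.

## Known limitations

- Branch-length optimisation, tree proposals and MCMC are deliberately
  out of scope: the engine evaluates likelihoods and derivatives; search
  belongs to client code.
- Single precision is not offered; all guarantees are stated for IEEE
  doubles.
- The benchmark harness generates nucleotide (4-state) problems;
  automatic implementation selection for other state counts therefore
  falls back to the serial kernel. Explicit `impl` selection always
  works for any state count.
- Non-reversible models lose the fast eigendecomposition route and the
  rerooting invariance that justifies `reroot_for_concurrency()`.
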
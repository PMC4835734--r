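---
title: "Predicting SIR epidemic thresholds on networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SIR epidemic thresholds on networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epithreshold)
```

## The model

We consider the discrete-time susceptible-infected-recovered (SIR) model
on a simple undirected network of N nodes. One uniformly random seed node
starts infected, all others susceptible. States update synchronously: at
each step every infected node transmits to each susceptible neighbour
independently with probability $\beta$, then recovers with probability
$\gamma$; a node infected at step $t$ is infectious from step $t+1$. The
process absorbs when no infected nodes remain, leaving a final epidemic
size $r = R_\infty/N \in [1/N, 1]$. The control parameter is the
effective spreading rate $\lambda = \beta/\gamma$; simulations use the
$\gamma = 1$ convention, so $\lambda = \beta$. Note that with
$\gamma = 1$ every infected node is infectious for exactly one step, so
the final-size process coincides with bond percolation at occupation
probability $\beta$ — a useful source of exact reference values (e.g. a
$k$-regular tree-like network has threshold $1/(k-1)$).

Three theoretical predictors of the threshold $\lambda_c$ are implemented:

* **MFL** (mean-field-like), from degree moments alone:
  $\lambda_c^{MFL} = \langle k\rangle/(\langle k^2\rangle - \langle
  k\rangle)$. Assumes statistically equivalent nodes within a degree
  class, no dynamical correlations, infinite size.
* **QMF** (quenched mean-field): $\lambda_c^{QMF} = 1/\Lambda_A$ with
  $\Lambda_A$ the adjacency spectral radius. Uses the full quenched
  topology but ignores dynamical correlations between neighbours.
* **DMP** (dynamical message passing): $\lambda_c^{DMP} = 1/\Lambda_M$
  with $\Lambda_M$ the leading eigenvalue of the non-backtracking
  operator, which forbids immediate retransmission back along the
  arriving edge and thereby captures part of the dynamical correlation
  structure. Exact on trees-like (locally tree-like) graphs.

Two exact relationships anchor the test suite: $\lambda_c^{QMF} \le
\lambda_c^{DMP}$ on every graph (the non-backtracking radius never
exceeds the adjacency radius), and on uncorrelated networks
non-backtracking centrality is degree-proportional, which collapses
$\Lambda_M$ onto $\langle k^2\rangle/\langle k\rangle - 1$ and makes the
MFL and DMP predictions coincide.

## Numerical threshold: the relative-variance peak

The simulated ("accurate") threshold is located by sweeping $\lambda$
over a grid, simulating an ensemble of final sizes per grid point, and
taking the argmax of the relative variance

$$\chi(\lambda) = \frac{\langle r^2\rangle - \langle r\rangle^2}
{\langle r\rangle^2},$$

whose peak marks the point of maximal relative fluctuation — the
size-dependent critical point. Ties resolve to the smallest $\lambda$,
and an argmax on a grid endpoint is flagged (the sweep range was too
narrow). No smoothing is applied before the argmax: the raw-grid
estimator is simple and auditable, and its resolution is the grid step.

A design note on the normalization: a susceptibility-style variant
$N(\langle r^2\rangle - \langle r\rangle^2)/\langle r\rangle$ is widely
used for locating critical points and is available via
`chi_statistic(..., normalize = "susceptibility")`. For the *final-size*
observable of the SIR model the two variants are **not**
argmax-equivalent: dividing by $\langle r\rangle$ versus $\langle
r\rangle^2$ reweights the supercritical side, and in finite systems the
susceptibility peak sits above the relative-variance peak. We verified on
a 6-regular random graph (N = 5000, exact threshold $1/(k-1) = 0.2$) that
the relative-variance peak recovers the exact value on a 0.01-step grid
— this check is part of the acceptance tests — and therefore made the
relative variance the default locator.

Default sweep grid: 25 geometrically spaced points spanning $[0.25, 4]
\times \lambda_c^{MFL}$, clamped to $\beta \le 1$ — centred where theory
predicts the transition, with uniform resolution in $\log\lambda$.

## Synthetic networks

`generate_configuration_network()` produces the uncorrelated scale-free
benchmark: degrees drawn i.i.d. from $P(k) \propto k^{-\nu_D}$ on
$[k_{\min}, k_{\max}]$ with $k_{\min} = 3$ and the structural cutoff
$k_{\max} = \lfloor\sqrt{N}\rfloor$, which suppresses degree-degree
correlations (measured $|r| < 0.05$ at $N \ge 10^4$ in the property
tests); stub matching follows, with self-loops and multi-edges removed
rather than rejection-sampled (the count of removed edges is recorded on
the graph; the bias vanishes at the structural cutoff for large N).
Degree exponents 2.1 (diverging second moment, k-core-localized regime)
and 3.5 (finite second moment, hub-localized regime) are the two
benchmark settings.

`rewire_assortativity()` tunes the Pearson degree-degree correlation by
greedy degree-preserving double-edge swaps (Xulvi-Brunet–Sokolov style):
a proposed swap is accepted only if it moves $r$ strictly toward the
target while keeping the graph simple; only the endpoint-degree
cross-moment changes under a swap, so each proposal is O(1). Tolerance
0.01, budget in sweeps of E proposals, best-effort return with a warning
if the target is unreachable.

What the generator does **not** emulate: clustering, community structure,
core-periphery layering and degree correlations of real networks — the
structural covariates against which real-world prediction errors are
stratified. Passing tests on configuration networks therefore validate
the predictors in their home regime (locally tree-like, uncorrelated);
they do not certify accuracy on clustered or assortative real networks,
which is precisely the question the comparison engine
(`build_record`, `binned_errors`, `closest_frequency`) is built to
answer per network.

## Spectral computations

$\Lambda_A$ comes from a dense symmetric eigendecomposition below 600
nodes and a sparse Lanczos iteration (tolerance $10^{-10}$, cap $10^4$
iterations) above. $\Lambda_M$ uses the sparse 2N×2N block companion
form $[[A, I-D],[I, 0]]$ of the non-backtracking operator — never the
dense 2E×2E edge matrix, which is kept only as an independent oracle
(`nb_edge_oracle`, capped at 2000 edges) and agrees with the block form
to $10^{-8}$ across the test suite.

Two numerical subtleties:

* The block matrix is non-symmetric, and its Perron root is defective on
  cycles (and near-defective nearby): backward-stable solvers split such
  a root into a pair straddling the true value by about
  $\sqrt{\varepsilon_{mach}} \approx 10^{-8}$. The eigenvalue selector
  works in a magnitude window of $10^{-6}$, requires the chosen root to
  be real within $10^{-6}$, and averages the split cluster, which cancels
  the leading error (cycles come back to $\Lambda_M = 1$ at
  $10^{-15}$).
* The node-space non-backtracking centrality (first N components of the
  2N eigenvector) is *not* read off the non-symmetric eigenvector, which
  a defective root contaminates with generalized-vector directions.
  Instead it solves the equivalent symmetric problem: given $\mu =
  \Lambda_M$, the block eigen-equations reduce to $(A - (D-I)/\mu)\,x_1
  = \mu\, x_1$, and $x_1$ is the well-conditioned Perron vector of that
  shifted symmetric matrix. The vector is sign-fixed nonnegative and
  L2-normalized; its inverse participation ratio $\sum_i v_i^4$
  quantifies localization.

Trees are rejected by `nb_leading()` with an explicit no-cycle error
(non-backtracking walks die out; the DMP threshold is undefined), and
downstream records carry the DMP fields as missing rather than imputed.

## Localization classes and stratification

Networks are classified by where the adjacency Perron vector localizes:
**LHN** (hub-localized) when $\Lambda_A$ is strictly closer to
$\sqrt{k_{\max}}$, **LKN** (k-core-localized) when closer to $\langle
k^2\rangle/\langle k\rangle$; an exact tie goes to LKN with a flag (the
choice is arbitrary but fixed and surfaced). Error curves are binned on a
$\Delta x = 0.1$ lattice anchored at 0 — windows $(x - \Delta x/2, x +
\Delta x/2)$ at multiples of $\Delta x$ — with empty bins reported empty,
not as zero error. The closest-method label minimizes absolute error;
since all methods share the same positive $\lambda_c$ denominator,
relative error induces the same winner (unit-tested). Ties at
floating-point resolution break lexicographically DMP < MFL < QMF,
flagged.

Two conventions in the comparison engine mirror undefined quantities
honestly: records with undefined DMP (trees) or undefined assortativity
(regular graphs) are excluded from the affected analysis with logged
counts rather than imputed.

## Simulator conventions

The within-step micro-order is transmit-then-recover: an infected node
transmits from its current-step contact set and may then recover in the
same step. The synchronous scheme fixes the macro-dynamics but not this
micro-order, so it is switchable (`order = "recover-first"`, under which
a node recovering this step does not transmit) to probe sensitivity; at
$\gamma = 1$ the recover-first order trivially kills every outbreak at
the seed, which the tests use as a sanity check of the switch. A newly
infected node never recovers in the step it is infected. The compiled
ensemble simulator and a pure-R single-realization reference
implementation (which can return the full S/I/R trajectory) follow the
same conventions and are cross-checked statistically in the tests.

All stochastic operations take explicit seeds and are bit-reproducible:
the compiled code draws from R's RNG stream, and chi sweeps derive one
stream per grid point as `seed + index - 1`.

## Problem sizes and tolerances in the shipped checks

The test-suite scales are the package's chosen desk scales: closed-form
fixtures up to a few hundred nodes; oracle equivalence on 20 random
configuration networks of 150 nodes; the MFL/DMP degeneracy at
$N = 3\times10^4$ (threshold within 5%); threshold recovery on 6-regular
graphs at $N = 5000$, 2000 realizations per 0.01-grid point, three master
seeds, $\pm 0.05$; size scaling over $N \in \{10^3, 3\times10^3, 10^4\}$
at 2000 realizations per point. Ensemble sizes trade statistical
resolution against runtime; production analyses should raise
`n_realizations` (the simulator is O(edges touched) per realization and
compiled).

## Known limitations

* Asynchronous (Gillespie) dynamics, SIS comparisons and time-resolved
  outputs beyond a debugging trajectory hook are out of scope.
* The greedy modularity partition is a reproducibility choice, not an
  optimality claim; Q depends on the partitioner, so the algorithm and
  seed are reported with it.
* The chi-peak threshold is size-dependent by construction; it estimates
  the finite-network critical point, not the thermodynamic limit.
* On networks whose giant component is a tree the DMP route is undefined
  and only MFL/QMF compete.
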
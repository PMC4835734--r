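# epithreshold

Tools for predicting and validating the epidemic threshold of the
susceptible-infected-recovered (SIR) model on networks.

## The problem

On a network, a disease spreading with per-contact transmission probability
β and per-step recovery probability γ has an epidemic threshold in the
effective spreading rate λ = β/γ: below it outbreaks stay microscopic,
above it a finite fraction of the network is eventually infected. Three
families of theory predict that threshold from increasing amounts of
topological information:

- **MFL (mean-field-like)** — from the degree distribution only:
  λ_c^MFL = ⟨k⟩ / (⟨k²⟩ − ⟨k⟩);
- **QMF (quenched mean-field)** — from the full adjacency matrix A:
  λ_c^QMF = 1/Λ_A, the reciprocal of the adjacency spectral radius;
- **DMP (dynamical message passing)** — from the non-backtracking
  structure: λ_c^DMP = 1/Λ_M, where Λ_M is the leading eigenvalue of the
  non-backtracking matrix, computed here via the sparse 2N×2N block
  companion form [[A, I − D], [I, 0]].

Which prediction should a practitioner trust? The package answers this
empirically: a compiled discrete-time synchronous SIR simulator produces
final-size ensembles, the relative variance
χ = (⟨r²⟩ − ⟨r⟩²)/⟨r⟩² of the final epidemic size r peaks at the
size-dependent numerical threshold, and the comparison engine tabulates
each predictor's error, stratifies it by structure (assortativity r,
clustering c, modularity Q, k-core, eigenvector localization), and reports
which method lands closest. Synthetic benchmarks come from a built-in
uncorrelated configuration-model generator (power-law degrees, structural
cutoff k_max = ⌊√N⌋) with degree-preserving rewiring to tune assortativity.
Real networks enter as plain whitespace-separated edge lists.

Intended users: network epidemiologists and network-science researchers
comparing spectral threshold theory with stochastic simulation.

## Worked example

```r
library(epithreshold)

g <- generate_configuration_network(5000, 3.5, seed = 42)
fit <- epidemic_thresholds(g, gamma = 1, n_realizations = 2000,
                           seed = 42, name = "config-nu3.5")
summary(fit)
```

```
SIR epidemic thresholds for 'config-nu3.5' (N = 5000, E = 10719)
  MFL (degree moments):     lambda_c = 0.1883
  QMF (adjacency spectrum): lambda_c = 0.1214
  DMP (non-backtracking):   lambda_c = 0.1930
  numerical (chi peak):     lambda_c = 0.1883

Structure: <k> = 4.288, <k^2> = 27.06, k_max = 57, max k-core = 3
  assortativity r = -0.0115, clustering c = 0.0015, modularity Q = 0.4990
Localization: LHN (Lambda_A = 8.235 vs sqrt(k_max) = 7.550, <k^2>/<k> = 6.310)
  IPR(adjacency) = 0.08622, IPR(non-backtracking) = 0.001789

Errors vs numerical threshold 0.1883 (closest: MFL)
  MFL: abs 0.0000 rel 0.000 | QMF: abs 0.0669 rel 0.355 | DMP: abs 0.0047 rel 0.025
```

Reading the output: on this uncorrelated scale-free network (degree
exponent 3.5) the MFL and DMP predictions nearly coincide — the expected
degeneracy on uncorrelated networks, where non-backtracking centrality is
degree-proportional — and both sit on the simulated χ-peak threshold,
while the QMF value underestimates it badly because the adjacency
eigenvector localizes on the hubs (the network classifies as LHN, with a
correspondingly large adjacency IPR). `coef(fit)` returns the four
thresholds; `plot(fit)` draws the χ curve with all four marked;
`simulate(fit)` draws fresh final-size ensembles at the fitted threshold.

A command-line front-end over the same functions ships in
`inst/scripts/epinet.R` (subcommands `generate`, `metrics`, `spectral`,
`predict`, `sir`, `find-threshold`, `compare`; every run writes a JSON
manifest of its inputs and seeds).

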
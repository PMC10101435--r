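---
title: "Clustering whole networks by spectral density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering whole networks by spectral density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netspectra groups *whole graphs* — not vertices — by the similarity of
their connectivity structure. The motivating applications are collections
of functional brain networks (one network per time window or per subject)
and collections of molecular graphs, where the scientific question is
"which networks were generated by the same kind of wiring process?", and
where natural sampling fluctuation means two networks from the same
process are never identical.

This vignette explains the model and the algorithms, the tunable
parameters and their defaults, the numerical choices, and what the
package's synthetic benchmarks do and do not demonstrate.

## The spectral density as a graph summary

A simple undirected graph $G$ with $|V|$ vertices is represented by its
adjacency matrix $\mathbf A$, whose eigenvalues
$\lambda_1 \ge \dots \ge \lambda_{|V|}$ are real. The *spectral
distribution* places mass $1/|V|$ at each eigenvalue:

$$\rho_G(\lambda) = \frac{1}{|V|} \sum_{j=1}^{|V|} \delta(\lambda - \lambda_j).$$

Two properties make this a good summary of connectivity structure. It is
invariant under vertex relabelling, so no vertex correspondence between
networks is needed; and different random-graph families (Erdős–Rényi,
geometric, regular, small-world, scale-free) produce visibly different
limiting spectral shapes, so the density carries information that simple
centrality summaries (degree and friends) miss — a random 20-regular
graph and a 20-neighbour ring lattice have identical degree sequences but
very different spectra.

`spectral_density()` smooths the point masses with a Gaussian kernel. The
bandwidth follows a fixed rule: the eigenvalue spread
$\lambda_1 - \lambda_{|V|}$ divided by the Sturges bin count
$\lceil 1 + \log_2 |V| \rceil$. The smoothed curve is evaluated on a
shared grid and renormalised so its trapezoid-rule area is exactly 1.

Numerical choices here, made once and kept:

* The kernel-regression view of smoothing a normalised histogram and a
  plain kernel density estimate with the same bandwidth coincide up to
  grid discretisation once the curve is renormalised to unit area; the
  package implements the KDE form.
* Grids extend 3 bandwidths beyond the extreme eigenvalues (Gaussian
  tails beyond $3\sigma$ carry 0.3% of mass, removed by the final
  renormalisation), with 512 points by default (`n_points`); resolution
  mainly trades divergence accuracy against memory, and 512 points keep
  discretisation error well below the sampling noise between graphs.
* A degenerate spectrum (all eigenvalues equal, e.g. the empty graph)
  would give bandwidth 0; it falls back to
  $\max(|\lambda_1|, 1) \times 10^{-3}$.
* All integrals are trapezoid-rule sums on the grid.

## Comparing densities: KL, JS, and a metric

With densities on a common grid, dissimilarity is measured by the
Kullback–Leibler divergence

$$KL(\rho_1 \,|\, \rho_2) = \int \rho_1(\lambda)\,
  \log\frac{\rho_1(\lambda)}{\rho_2(\lambda)}\, d\lambda,$$

computed as a discrete KL: both curves are converted to probability
masses (density × trapezoid weight, renormalised) before the sum, which
guarantees nonnegativity by the Gibbs inequality. Natural logarithms are
used throughout. If $\rho_1$ has mass where $\rho_2$ is zero the
divergence is $+\infty$; values below $10^{-300}$ are treated as exact
zeros, so "zero" means genuine numerical underflow of the Gaussian tail,
not a small number.

KL is asymmetric and suited to cases with a clear reference (a model
density). For symmetric comparisons the Jensen–Shannon divergence
averages the two KLs to the equal-weight mixture; it is finite, bounded
by $\log 2$, and its square root satisfies the triangle inequality —
`spectral_distance()` is therefore a true metric and is the distance the
clustering uses.

## K-means for graphs of one size

`kmeans_graphs()` clusters same-size graphs: centroids are arithmetic
means of member densities, distances are $\sqrt{JS}$, and each pass
reassigns graphs greedily in a seed-controlled random order, updating the
two affected centroids immediately after every move. A pass with no move
terminates the restart. Because the greedy order matters, the algorithm
runs `n_restarts = 10` independent restarts and keeps the one with the
largest overall silhouette, computed from the pairwise
$\sqrt{JS}$ matrix between the graphs themselves (a true metric), not
from distances to centroids.

Three places where the published procedure is silent and the package
fixes behaviour:

* **Ties.** A graph moves only on a *strict* improvement. With exact
  ties — e.g. bit-identical graphs — a "lowest index wins" rule would
  move every member of the higher-indexed cluster each pass, endlessly
  triggering empty-cluster repairs, and the no-move convergence test
  could never pass.
* **Empty clusters.** If a move empties a cluster, the graph currently
  farthest from its own centroid is moved in.
* **Initialisation.** The initial random assignment is a shuffled
  balanced allocation, so no cluster starts empty.

The same-size restriction is fundamental, not an implementation limit: a
graph has as many eigenvalues as vertices, so densities of different-size
graphs differ because of size alone and their mean is not meaningful.

## Fitting a random-graph model: the KL-minimising estimator

For a graph $G$ assumed to come from model family $M$ with parameter
$\theta$, the estimator is

$$\hat\theta = \arg\min_\theta KL(\rho_G \,|\, \rho_{M(\theta)}),$$

searched over a finite grid of candidate $\theta$ values. Closed-form
spectral densities are unknown for most models, so $\rho_{M(\theta)}$ is
a Monte-Carlo estimate: the mean density of `n_mc = 50` (default)
independent draws from $M(\theta)$ *at the target graph's own size*. The
KL grid is built from the union of the graph's spectrum and every
Monte-Carlo spectrum, so all densities are fully supported on it.
`select_model()` extends the same criterion across model families,
choosing the family whose best grid point attains the smallest KL.

Monte-Carlo streams are derived deterministically from the master seed
and $(\theta, n)$, and the spectra are cached on that key — the EM
algorithm below re-evaluates them heavily and is infeasible without the
cache. Default grids are a compromise between resolution and cost; the
Erdős–Rényi default `seq(0.05, 0.5, 0.025)` separates parameter gaps of
0.05 (the hardest case in the package's benchmarks) at roughly half the
cost of a 0.01-step grid over (0, 1), and every estimator accepts a
user-supplied grid when finer resolution is wanted.

## gCEM: clustering graphs of different sizes

`gcem()` is a classification-EM scheme in which each cluster is a
random-graph model. Per iteration:

1. **E-step.** For each graph $G_i$ and cluster $k$, compute
   $KL_{ik} = KL(\rho_{G_i} | \rho_{M_k(\hat\theta_k)})$ with the model
   density generated at $G_i$'s own size, and set responsibilities
   $t_k(G_i) \propto 1/KL_{ik}$, normalised over clusters so each
   graph's row sums to 1. (The algorithm's printed form could also be
   read as normalising over graphs; the package follows the
   conditional-probability reading — per graph over clusters — which is
   the only one that makes $t_k(G_i)$ a probability that graph $i$
   belongs to cluster $k$.)
2. **C-step.** Assign each graph to its maximum-responsibility cluster.
3. **M-step.** Re-estimate $\hat\theta_k$ as the average of the
   per-graph KL-minimising estimates within cluster $k$.

Because the per-graph estimates depend only on the graph and the model
family, they are computed once and memoised across iterations. The
averaged $\hat\theta_k$ can leave the feasible domain for integer-valued
parameters; it is projected back (k-regular degrees round to the nearest
even integer, which is feasible at every size; probabilities clamp to
[0, 1]). Convergence is declared when the objective
$\sum_i t_{k(i)}(G_i) \cdot KL_{i,k(i)}$ (the per-iteration quantity
aggregated by summing over assigned graphs) changes by less than
`tol = 1e-3` relatively, or when labels repeat, with a `max_iter = 50`
cap. Degenerate cases are handled explicitly: a graph with infinite KL
to every cluster gets a uniform responsibility row (with a warning); a
graph no model supports contributes nothing to the M-step average; an
emptied cluster is reseeded with the least-committed graph.

## Generators, rewiring, and what the benchmarks mean

The package ships five seeded generators (`gen_erdos_renyi_gnp`/`_gnm`,
`gen_geometric` on the unit square, `gen_k_regular`,
`gen_watts_strogatz`, `gen_pref_attachment` with attachment probability
$\propto \mathrm{degree}^{ps}$ from an $m$-clique start, targets drawn
without replacement as simplicity requires) and a degree-preserving
double-edge-swap rewiring (`markov_rewire`) that applies an exact number
of successful swaps, rejecting proposals that would create loops or
duplicates, with a proposal budget of $100 \times$ the requested swaps
before erroring (a complete graph admits no swap at all).

One generator design note: a naive "draw a uniform pairing of degree
stubs, reject the whole pairing if it has loops or multi-edges" sampler
for k-regular graphs has acceptance probability roughly
$e^{-(k^2-1)/4}$ — about $10^{-4}$ at $k = 6$ and effectively zero at
the $k = 20$ used in the benchmarks — so `gen_k_regular` delegates the
draw to igraph's k-regular sampler (deterministic under R's RNG) behind
the same interface.

The benchmark scenarios (`run_scenario`) reproduce three designs: (1)
three same-size clusters per model family, across sizes 30–120; (2) two
clusters of 10 graphs at $n = 100$ engineered to share size and edge
count (Watts–Strogatz vs $G(n, m{=}1000)$ as rewiring $p$ sweeps 0–1)
or additionally the whole degree sequence (ring lattice under 0–1000
swaps vs random 20-regular); (3) the design-1 scenarios with sizes drawn
uniformly from [30, 120], clustered by gCEM. Agreement with the ground
truth is scored by the pair-counting Jaccard index
$n_{11}/(n_{11}+n_{10}+n_{01})$ — the only common Jaccard variant whose
chance level for the 10 + 10 design is the quoted 0.32 (analytically,
$45/140 \approx 0.321$ under 50% per-item accuracy). Tests and the
acceptance script run 10–20 repetitions per condition rather than 100;
the Monte-Carlo standard error of a mean Jaccard at these sizes is below
the decision thresholds used, and the problem sizes are stated in each
test. The gCEM benchmarks evaluate densities on 256-point grids and 20
Monte-Carlo replicates per grid value; at these settings the recovered
parameters match the 512-point, 50-replicate configuration to the
resolution of the search grid.

## Signal-to-network pipeline

For multichannel recordings, `window_stream()` slices the signal,
`correlation_graph()` builds one graph per window (edge where Pearson
$r$ strictly exceeds `cutoff = 0.5`), `fbn_state_series()` clusters the
graph sequence with `kmeans_graphs` ($K = 2$) and orients labels so the
majority state of the leading windows is 1 (recordings are assumed to
start in that state), and `detect_transition()` reports the center of the
first 50-point centered moving-average window whose mean crosses 0.5
(downward for loss-of-consciousness-style transitions, upward for
recovery). Edge windows are not padded; no average is computed where the
window does not fit.

`synthetic_two_state_signals()` provides the test harness: channels are
a shared latent signal scaled by a coupling factor plus independent
Gaussian noise, with the coupling switching between a high and a low
value at specified samples. With the defaults (coupling 0.9 vs 0.1,
noise SD 0.5) the expected pairwise correlation is
$c^2/(c^2+\sigma^2) \approx 0.76$ in the coupled state and
$\approx 0.04$ in the uncoupled state — clearly on opposite sides of the
0.5 cutoff, by design. This emulates only the feature the pipeline needs
(a connectivity change), not amplitude dynamics, spectral content,
volume conduction, or artefacts of real electrophysiology; passing the
end-to-end test shows the pipeline machinery is correct, not that it
would segment any particular real recording.

## Known limitations

* Spectral density computation is $O(|V|^3)$ per graph; collections of
  graphs with thousands of vertices are the practical ceiling, and gCEM
  multiplies that by the grid size and `n_mc`.
* Small graphs ($|V| \lesssim 60$) give noisy densities; separation of
  close parameters degrades accordingly, and the size-sweep benchmark
  exists precisely to show that trend.
* gCEM requires naming candidate model families; a misspecified family
  can still win model selection as "least bad".
* Eigenvector information is deliberately unused; only eigenvalues enter
  the summary.
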
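---
title: "Methods: time-varying truncated-Gaussian graphical models for keyword panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying truncated-Gaussian graphical models for keyword panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A stream of documents (for instance news reports) is summarized, per
report, as a vector of non-negative adjusted keyword frequencies, and the
reports are grouped into ordered periods (calendar quarters by default).
Two questions are asked jointly:

1. Within a period, which pairs of keywords are *conditionally dependent*
   given all the others? These pairs are the edges of a keyword network.
2. Across periods, when does that network actually change? Runs of
   periods sharing one network form *phases*; their boundaries are change
   points that can be read against external events such as policy
   announcements.

`fusedtgm` answers both with a single penalized estimation problem, then
summarizes each phase network with standard network statistics, hubs,
modules, and topic-strength series.

# Model

Within period $m$, the $p$-vector of adjusted frequencies $Y^{(m)}$ is
modeled by the density proportional to

$$\exp\Big\{-\tfrac12 y^\top \Theta^{(m)} y + \eta^{(m)\top}(y - 1_p)\Big\}
  \, I(y \in \mathbb{R}_+^p),$$

a multivariate Gaussian with precision matrix $\Theta^{(m)}$ and mean
$(\Theta^{(m)})^{-1}\eta^{(m)}$, truncated to the non-negative orthant.
Keywords $i$ and $j$ are conditionally dependent given the rest exactly
when $\theta_{ij}^{(m)} \neq 0$, so the sparsity pattern of
$\Theta^{(m)}$ *is* the keyword network. The orthant truncation matters:
adjusted term frequencies are non-negative and strongly right-skewed, and
an untruncated Gaussian model would be misspecified at the boundary.

## Estimation loss

The truncation makes the normalizing constant intractable, so maximum
likelihood is unattractive. We instead use a generalized (h-weighted)
score-matching loss: with residuals $r_{ij} = (\Theta y_i)_j - \eta_j$
and weights $h_{ij} = h(y_{ij})$,

$$\hat J = \frac1n \sum_i \sum_j \Big[ \tfrac12 h_{ij} r_{ij}^2
  - h'_{ij} r_{ij} - h_{ij}\,\theta_{jj} \Big],$$

the integration-by-parts form of the h-weighted Hyvärinen objective. The
weight is $h(y) = \min(y, C)$ with derivative $1$ below the cap: since
$h(0)=0$, the boundary terms on the orthant vanish, and the cap bounds
the influence of heavy right tails. The default is $C = 3$ on the
standardized scale; `h_weight(Inf)` gives the uncapped variant. Columns
are standardized by their standard deviation pooled over all periods,
without centering (centering would destroy non-negativity); estimates are
reported on that scale. The loss is jointly quadratic, hence convex, in
$(\Theta, \eta)$, which the solver exploits heavily.

Positive definiteness is not enforced during estimation — score matching
does not require it — but `fit_joint()` warns if a final estimate is not
positive definite.

## Joint objective

All periods are fitted together by minimizing

$$\sum_{m=1}^M \hat J(\Theta^{(m)}, \eta^{(m)})
 + \lambda_1 \sum_m |\Theta^{(m)-}|
 + \lambda_2 \sum_{m<M} \|\Theta^{(m)-} - \Theta^{(m+1)-}\|_F,$$

where $\Theta^{-}$ is the off-diagonal part, $|\cdot|$ is the entrywise
$\ell_1$ norm, and $\|\cdot\|_F$ the Frobenius norm. The $\lambda_1$ term
gives sparse networks; the fused group-lasso term ties *whole*
off-diagonal matrices of adjacent periods, and because its proximal
operator produces exact zero difference blocks, adjacent periods can
share literally identical networks — maximal runs of such periods are the
phases and their boundaries the change points. Diagonal entries and
$\eta$ are never penalized.

# Solver

`fit_joint()` runs ADMM on a consensus splitting with lasso copies
$Z_m = \Theta^{(m)-}$ and fusion copies
$D_m = \Theta^{(m)-} - \Theta^{(m+1)-}$:

* **Smooth step.** Because each $\hat J_m$ is an explicit quadratic
  ($\hat J_m(x) = \tfrac12 x^\top Q_m x - c_m^\top x$ in stacked
  coordinates, built once per panel by exact Hessian–vector products),
  the augmented subproblem is one sparse-structured linear system, and it
  is Cholesky-factorized once per value of the ADMM parameter $\rho$.
  Iterations then cost only triangular solves.
* **Z step:** elementwise soft-thresholding at $2\lambda_1/\rho$ (the
  factor 2 because the matrix penalty counts both symmetric entries of
  each upper-triangle coordinate).
* **D step:** group soft-thresholding at $\sqrt{2}\lambda_2/\rho$ (the
  $\sqrt2$ converts the Frobenius norm to the upper-triangle vector
  norm). Exact zero blocks here are what fuse periods.
* **Duals and stopping:** scaled dual ascent; convergence when primal and
  dual residuals fall below a relative tolerance (default `1e-5`);
  $\rho$ starts at 1 and is rebalanced by factors of 2 whenever one
  residual exceeds 10 times the other (duals rescaled, system
  refactorized). Non-convergence within `max_iter` returns the fit with
  a warning and `converged = FALSE`.

On convergence the returned estimates are assembled so fused periods
share *identical* off-diagonals (the average of their exactly sparse
lasso copies) — `extract_phases()` then recovers phases by exact ties,
with a `1e-8` Frobenius tolerance as a safety net only.

# Tuning selection

`aic_select()` scores fits on a $\lambda_1 \times \lambda_2$ grid by an
information criterion
$\sum_m 2 n_m \hat J_m + w\,\mathrm{df}$, with df counting each phase's
distinct nonzero upper-triangle entries once plus $p$ linear parameters
per phase. Four design points deserve explanation, because each one was
forced by a measurable failure of the plainer alternative on synthetic
panels with known truth:

1. **Penalty weight.** The score-matching loss is not a log-likelihood:
   its curvature $A$ and gradient variance $B$ differ, and the expected
   optimism per fitted parameter is $\mathrm{tr}(A^{-1}B)/\mathrm{df}$
   times larger than the classical AIC calibration assumes. On
   standardized keyword panels this *sandwich ratio* (exposed as
   `sandwich_ratio()`) is around 3–4, so the classical $w = 2$
   under-penalizes drastically — on panels simulated with *empty* true
   graphs it selects models with most edges present. The default is
   therefore BIC-type, $w = \ln(\sum_m n_m)$, plus the extended-BIC edge
   term $4\gamma\ln p$ (standard for sparse graph selection, default
   $\gamma = 0.5$), both rescaled by the estimated sandwich ratio.
   `penalty = "aic"` restores the uncorrected classical formula.
2. **Refit scoring.** Scored at the penalized estimates, heavily fused
   candidates look artificially good: once everything is fused the
   fusion penalty is inactive and their loss is unshrunk, while
   candidates with active fusion terms pay shrinkage bias. Every
   candidate structure is therefore scored at its unpenalized refit
   (cheap: one restricted quadratic solve per phase).
3. **Candidate partitions, then edges.** Along the fused-lasso path,
   sparsity and fusion are coupled: the grid rarely contains "the right
   partition at the right sparsity". The path is therefore used as a
   *candidate generator* for partitions; each distinct partition is then
   refined per phase — dense unpenalized refit, sandwich standard
   errors, keep edges with $|z| > \sqrt{\ln N_{\text{phase}}}$ (the
   classical BIC cut, applied on the corrected scale), refit restricted.
   This matters: on synthetic panels the lasso path's edge ordering
   measurably interleaves false edges before true ones, while the Wald
   ordering is nearly clean.
4. **Edge-only df across partitions.** The per-period diagonal and
   $\eta$ parameters are free under every partition, so comparing
   partitions charges only the phase-level edge parameters. Charging $p$
   linear parameters per phase (as the within-grid df does) would
   penalize splits for parameters that splitting does not actually add,
   and measurably over-merges.

Ties prefer larger $\lambda_1$, then larger $\lambda_2$. Default grids:
8 log-spaced points in $[0.01, 1]\cdot\lambda_{1,\max}$ for $\lambda_1$,
and the same scaled by $\sqrt{p(p-1)/2}$ for $\lambda_2$ — the fusion
prox thresholds a whole $p(p-1)/2$-entry block, so its natural scale
carries a square-root-of-block-size factor.

# Network analysis conventions

`build_network()` places an edge where $|\hat\theta_{ij}|$ exceeds
`1e-8` (the lasso produces exact zeros; the threshold is numerical
guard only). For the indicator bundle:

* Average degree is $2q/n$ over **all** nodes, isolated included.
* ASPL averages shortest paths over pairs at finite distance only.
* The clustering coefficient averages the local coefficient over
  non-isolated nodes, with degree-1 nodes contributing 0.
* Erdős–Rényi baselines $ASPL_r = \ln n'/(\ln 2q - \ln n')$ and
  $CC_r = 2q/(n'(n'-1))$ use $n'$ = the number of non-isolated nodes.
  This combination of conventions is the one that is internally
  consistent with published summary tables of this analysis type, where
  sparse phases have a handful of active nodes among dozens of isolated
  keywords.
* The small-world coefficient is $(CC/CC_r)/(ASPL/ASPL_r)$, defined as 0
  when $CC = 0$.
* The degree exponent $\gamma$ is the discrete maximum-likelihood
  estimate with $x_{\min} = 1$ (zeros excluded), maximizing the
  zeta-normalized likelihood numerically; degenerate all-equal degree
  sequences are flagged. An optional parametric bootstrap
  Kolmogorov–Smirnov test (100 replicates, plausibility at
  $p \ge 0.1$) flags sequences the power law fits poorly, mirroring the
  practice of reporting no exponent for such networks.

Hubs are ranked by degree and by eigenvector centrality. The eigenvector
is computed by power iteration on $A + I$ (same eigenvectors as $A$, but
a strictly dominant eigenvalue even on bipartite graphs, where plain
power iteration oscillates), max-normalized; on disconnected graphs it
concentrates on the component with the largest eigenvalue, giving one
global ranking. Ties in hub lists break lexicographically.

Modules come from the Louvain algorithm (via igraph, seeded node order)
at a resolution parameter $\lambda$ entering the modularity
$Q = \frac{1}{2l}\sum_{ij}[A_{ij} - \lambda k_ik_j/2l]\,\delta_{ij}$;
the in-package `modularity_score()` implements this sum directly and is
cross-checked against igraph in the tests. Following the formula,
*higher* resolution penalizes within-module expected edges more and
yields more, smaller modules; descriptions that associate low resolution
with more modules use the reciprocal convention. Modules below
`min_size` (default 3) are flagged omitted for presentation but their
nodes are never reassigned. Modules map to named topics by maximal
Jaccard overlap with a user-supplied lexicon; per-period absolute topic
strength is the share of reports containing at least one topic keyword,
and relative strength renormalizes the absolute strengths within the
period (a report may count toward several topics; the normalization is
designed to absorb that).

# Synthetic data

`make_scenario()` + `sample_tn()` + `make_corpus()` generate fully
ground-truthed inputs: piecewise-constant sparse precision matrices over
phases (off-diagonals $\pm$`effect`, diagonal = absolute row sum + 1, so
diagonal dominance certifies positive definiteness), truncated-Gaussian
samples via single-chain Gibbs (each full conditional is a univariate
truncated normal; inverse-CDF draws with Robert's translated-exponential
rejection in the far tail; defaults burn = 500, thin = 2), and
optionally a token-level corpus (Poisson keyword counts around the
latent values plus filler tokens).

Defaults describe the study conditions the package is built around:
$p = 10$ keywords, $M = 12$ quarters, 3 phases of equal length,
$p$ edges per phase at effect 0.5, $n_m = 300$ reports per period —
sizes at which a quarterly news panel over three years is realistic, and
at which the partial correlations (about 0.2) make recovery demanding
but feasible. `count_scale = 10` in the corpus generator keeps the
latent values recoverable from token counts (correlation above 0.9).
The generator emulates the *statistical* structure the model assumes —
non-negativity, right skew, phase-structured conditional dependence —
and deliberately not natural language: no word order, no topical
drift within phases, no document-length heterogeneity beyond Poisson
noise. Passing tests on it validate the estimation machinery, not
linguistic preprocessing choices on real corpora.

# Numerical choices and degenerate inputs

* ADMM tolerances default to `1e-5` relative; oracle-comparison tests
  run at `1e-8`. Cholesky factorizations fall back to a jittered matrix
  (`1e-8` scale) if a quadratic is numerically singular; refits fall
  back to a ridge solve when a selected support is unidentified.
* Empty graphs: ASPL, clustering, centralities and module detection are
  errors (with explicit messages), and the indicator bundle reports
  them as `NA` rather than failing.
* A period with fewer than 2 reports is an error in `fit_joint()`; a
  quarter with zero reports is an error in `build_panel()`; a report
  whose tokens are all removed is kept as an all-zero row with a
  warning.
* `2q = n'` makes the ER path-length baseline undefined and is an
  error.
* Tests and examples use problem sizes of $p \le 10$, $M \le 12$,
  $n_m \le 300$ (the default scenario), chosen so the full suite
  documents the method at study-like scale while running in minutes.

# Limitations

* The selection pipeline is calibrated for $n_m$ in the hundreds and
  $p$ in the tens; for $p$ approaching $n_m$ the dense per-phase refit
  that drives the Wald screening becomes unstable.
* Only the chain fusion (adjacent periods) is implemented; tying
  non-adjacent periods would need a pairwise fusion penalty, which this
  package deliberately omits.
* Edge weights $|\hat\theta|$ are exported, but all indicators are
  computed on the 0/1 graph.
* The truncated-Gaussian family fixes the power parameters of the
  general non-negative exponential family at 1; heavier-tailed variants
  are out of scope.
* On real corpora the tokenizer is the user's responsibility (the
  default splits on whitespace); languages requiring segmentation must
  be tokenized upstream.
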
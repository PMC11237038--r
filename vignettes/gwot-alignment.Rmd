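---
title: "Unsupervised alignment of similarity structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised alignment of similarity structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwotalign)
```

## The problem

Two observers — two groups of people, a person and an artificial rater, a
brain area and a model layer — each judge the pairwise dissimilarity of the
same set of items. Each produces a symmetric, nonnegative matrix $D$ whose
entry $D_{ij}$ says how different items $i$ and $j$ are for that observer.
The conventional way to compare two such matrices is representational
similarity analysis (RSA): correlate the corresponding upper-triangular
entries, which presupposes that item $i$ in one structure *is* item $i$ in
the other. That presupposition hides a failure mode: when items fall into a
few coarse categories, two matrices can correlate strongly even though
within each category the items correspond to nothing in particular. A high
$\rho$ can certify no more than category-level agreement.

Unsupervised alignment drops the presupposition. Gromov–Wasserstein optimal
transport (GWOT) searches for a probabilistic correspondence
$\Gamma$ between the two item sets using only the internal geometry of each
matrix, by minimizing the distortion

$$
\mathrm{GWD}
 \;=\; \min_{\Gamma}\; \sum_{i,j,k,l}
 \bigl(D_{ij} - D'_{kl}\bigr)^2\, \Gamma_{ik}\, \Gamma_{jl},
$$

over couplings $\Gamma \ge 0$ with uniform marginals
($\sum_k \Gamma_{ik} = 1/n$, $\sum_i \Gamma_{ik} = 1/m$). Only after the
optimization do external labels enter, to *evaluate* the found plan: source
item $i$ counts as matched when the argmax of its coupling row lands on a
target item with the same label; the matching rate is the percentage of
matched items, with chance level $100/n$ for distinct shared labels. The
dissociation that motivates all of this is then visible directly: structure
pairs engineered to agree only at category level keep a high RSA $\rho$
while their matching rate stays at chance.

## The solver

The plain objective is a non-convex quadratic program. Following standard
practice for this family of problems, the package optimizes the
entropy-regularized objective

$$
\mathrm{GWD}_{\epsilon}
 \;=\; \min_{\Gamma}\; \sum_{i,j,k,l} (D_{ij}-D'_{kl})^2\,
 \Gamma_{ik}\Gamma_{jl} \;-\; \epsilon\, H(\Gamma),
\qquad
H(\Gamma) = -\sum_{ik} \Gamma_{ik}\,(\log \Gamma_{ik} - 1),
$$

by projected mirror descent: each outer step forms the partial-gradient
cost tensor of the quadratic term (for the squared-difference loss it
factors as $c_C - 2\,D\,\Gamma\,D'$, never requiring the four-index sum)
and solves the resulting entropic linear transport subproblem by Sinkhorn
scaling at temperature $\epsilon$. `gw_cost()` evaluates the plain
objective of any plan through the same factored contraction.

Numerical choices that matter, all tunable through `entropic_gw()`:

* **Log-domain Sinkhorn throughout.** The useful $\epsilon$ range extends
  to $10^{-4}$ on matrices normalized to $[0,1]$, far below the cost scale,
  where naive exponential scaling under/overflows. Potentials are updated
  with log-sum-exp; a genuinely non-finite potential raises an error naming
  $\epsilon$.
* **Annealed cold start.** The very first subproblem is solved through a
  short temperature ladder (from 5% of the cost-tensor range down to
  $\epsilon$, factor 3 per stage) because Sinkhorn's linear convergence
  rate degenerates when $\epsilon$ is orders of magnitude below the cost
  scale. The ladder starts from the supplied initialization's cost tensor,
  so distinct random initializations still explore distinct basins.
* **Stall detection.** An inner solve whose marginal error improves by less
  than 2% per check is cut short — the outer loop recomputes the cost
  tensor anyway, so crawling toward the inner optimum is wasted work.
* **Convergence and patience.** The outer loop stops when the plain GWD
  changes by less than `tol` ($10^{-9}$) between iterations, at 1000
  iterations, or after 100 consecutive iterations without improvement (an
  oscillating basin). `converged` records which exit was taken.
* **Feasibility by rounding.** The returned plan is projected onto the
  exact marginal polytope by capping row and column sums and repairing the
  deficit with a rank-1 nonnegative correction, so every reported plan
  satisfies the marginal constraints regardless of where the inner solver
  stopped; the perturbation is bounded by the pre-rounding violation.

## The sweep and model selection

$\mathrm{GWD}_\epsilon$ is non-convex, so any single run lands in a local
optimum that depends on $\epsilon$ and the initialization. `gw_sweep()`
therefore runs many trials: trial $t$ takes the $t$-th value of a
log-spaced grid on $[\epsilon_{\min}, \epsilon_{\max}]$ (defaults
$10^{-4}$ to $10^{-1}$, 500 values — one random initialization per value)
and a fresh strictly positive random coupling from `random_coupling()`,
seeded by a deterministic per-trial stream derived from the master seed, so
sweeps are reproducible and could be parallelized without seed collisions.

The reported optimum is the plan with the smallest *plain* GWD — the
entropy term is dropped for selection so trials at different $\epsilon$ are
comparable. Selection runs over every trial, converged or not: each
recorded plan is a feasible coupling, so its objective value is a valid
upper bound wherever the iteration stopped; `converged` stays available as
a diagnostic. Ties break toward the smaller $\epsilon$, then the smaller
trial index. After selection, the few leading candidates are *polished* —
re-run from their own plans with a larger iteration budget and no annealed
restart — because small-$\epsilon$ descents routinely hit the per-trial cap
mid-descent; polishing recovers the basin's stationary point without
jumping basins.

## Evaluation

`matching_rate()` implements top-1 label matching with smallest-index
tie-breaking (ties are also flagged; strictly positive entropic plans make
exact ties measure-zero, but degenerate inputs can produce them). Duplicate
labels are legal: matching is by label equality, not index equality. The
chance level $100/n$ is reported whenever both label sets are duplicate-free
and coincide. `rsa_spearman()` is the supervised contrast: Spearman's
$\rho$ (average ranks for ties) on strict upper triangles, refusing inputs
whose label order differs, since the statistic is meaningless without the
assumed correspondence.

## Aligned visualization

`mds_embed()` produces metric multidimensional-scaling coordinates by
SMACOF majorization (Guttman transform), run from the classical-scaling
solution plus seven seeded random restarts, keeping the lowest raw stress.
`procrustes_align()` then rotates one embedding onto the other through the
optimal plan by solving
$\min_Q \lVert X - Q\tilde{Y} \rVert_F^2$ over orthogonal $Q$, where
$\tilde{Y}$ is the barycentric projection of the target coordinates:
column $i$ of $\tilde{Y}$ is $\sum_k \Gamma_{ik} Y_{\cdot k} / p_i$. Two
conventions deserve explicit statement. First, the stored plan is $n\times
m$ with source items as rows, so the projection right-multiplies $Y$ by the
plan's transpose. Second, the division by the source marginal $p_i$ undoes
the plan's $1/n$ mass scaling; without it the projected cloud shrinks by
$n$ and the identity alignment would not have a near-zero residual (the
rotation itself is scale-invariant, the plotted coordinates are not). The
solution is $Q = UV^\top$ from the SVD of $X\tilde{Y}^\top$; reflections
are allowed since only orthogonality is required.

## Color-space baseline models

For color stimuli given as HEX codes, `rgb_dissimilarity()` is the
Euclidean distance in the RGB cube and `lab_dissimilarity()` the CIEDE2000
difference on CIELAB coordinates. The sRGB-to-Lab path is IEC 61966-2-1
inverse companding, the sRGB primaries matrix, and the D65 white point
(2° observer) — the dominant convention of colorimetry packages.
CIEDE2000 is implemented from its published definition with parametric
factors $k_L = k_C = k_H = 1$, including the hue-angle discontinuity rules
at zero chroma; the tests pin every branch against an independent
implementation.

## The synthetic generator

No experimental data ship with the package; every analysis runs on
generated structures whose ground truth is known. The generator emulates
three features of group-averaged similarity-judgment data:

* **Euclidean bases** (`sample_structure()`): i.i.d. normal point clouds,
  so the triangle inequality holds by construction. The alignment objective
  requires no metric axioms; this is a convenience, not an assumption.
* **Observers.** `simulate_rater_panel()` produces discrete 0–7 ratings
  (scaled base value plus Gaussian rater noise, clipped, rounded) in a
  long-format table that `dissim_from_ratings()` averages back — the
  group-average route. `simulate_llm_trials()` produces trial-averaged
  *continuous* ratings on the same scale (5 trials by default), emulating a
  stochastic artificial rater queried repeatedly.
* **Category structure** (`make_category_pair()`): category centers placed
  randomly (asymmetric coarse geometry, as real perceptual categories are)
  and rescaled so the mean between-center distance is `between_sep`; items
  jitter around centers with mean within-category distance `within_scale`.
  With `resample_fine = TRUE` the target's jitter is redrawn independently
  — coarse geometry preserved, fine structure unrelated.

Defaults are fixed at the study scale this package addresses: 93 items in
3 coarse categories of 31, `between_sep = 1`, `within_scale = 0.25`. The
31-per-category choice makes the two notions of "chance after coarse-only
alignment" — $100/n \approx 1.08\%$ globally and
$100/31 \approx 3.2\%$ within a correctly matched category — differ by
about two percentage points, so a coarse-only pair sits at chance on both
readings. Rater/trial noise magnitudes (0.5–0.8 rating units) are free
parameters chosen to span the regimes the property tests need; no
per-participant variance data exist to calibrate them against.

What passing tests on these generators show — and what they do not: they
show the solver recovers planted correspondences, degrades gracefully with
noise, and reproduces the correlation-versus-matching dissociation; they do
not show anything about rating-scale usage quirks, response biases,
culture- or language-dependent category boundaries, or perceptual
nonuniformities of real observers, none of which the generator models.

## Problem sizes used in the test and acceptance runs

Exhaustive-oracle comparisons use 20 instances at $n \in \{4,5,6\}$ with
120–200-trial sweeps (the oracle enumerates up to $6! = 720$ permutation
couplings); permutation recovery uses $n = 30$, 5% relative noise,
50-trial sweeps over 10 seeds; the dissociation suite uses the full
93-item category defaults, with 10-trial sweeps for the resampled branch
and 40-trial sweeps for the matched branch (whose fine-alignment basin
attracts only a minority of small-$\epsilon$ initializations); the
Monte-Carlo chance check uses 10,000 random couplings at $n = 93$. The
analysis scripts under `analysis/` run the 93-item panel with 30-trial
sweeps. These sizes keep each stage's cost proportionate to what it
demonstrates while preserving the study-scale geometry where it matters
(the 93-item dissociation).

## Known limitations

* The solver returns local optima; the sweep's trial count is the only
  defense. On hard instances the global basin attracts only a small
  fraction of random initializations, so small sweeps understate
  alignability.
* Runtime per outer iteration scales as $O(n^3)$ through the
  $D\,\Gamma\,D'$ products; structures beyond a few hundred items need a
  different engineering approach (low-rank couplings, subsampling) that
  this package does not provide.
* Only uniform marginals are supported — all items weigh equally, as in
  the rating-experiment setting. No unbalanced or partial transport, no
  fused variants with feature terms.
* `rsa_spearman()` and `matching_rate()` assume a shared item universe;
  comparing structures over genuinely different item sets is out of scope.
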
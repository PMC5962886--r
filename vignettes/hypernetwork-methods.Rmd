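---
title: "Hyper-network construction from regional fMRI time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyper-network construction from regional fMRI time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pairwise functional connectivity (one correlation per region pair) cannot
express joint interactions among three or more brain regions. A
hyper-network replaces the graph edge with a *hyper-edge*: a set of regions
selected together. `hypernet` builds such networks from regional BOLD time
series, extracts hyper-graph clustering coefficients as node features,
tests them between groups, and classifies subjects — the full chain of a
case/control resting-state hyper-network study.

## Sparse regression model

For a subject with standardized time-series matrix $X \in \mathbb{R}^{T
\times R}$, each region $m$ in turn is the *centroid*: its series $x_m$ is
regressed on the matrix $A_m$, which equals $X$ with column $m$ set to
zero,

$$x_m = A_m\,\alpha_m + \tau_m.$$

Regions with nonzero $\alpha_m$ form, with $m$ itself, one hyper-edge.
Three penalties are supported:

* **lasso** — $\tfrac12\lVert x_m - A_m\alpha\rVert_2^2 +
  \lambda\lVert\alpha\rVert_1$;
* **elastic net** — adds $\lambda_2\lVert\alpha\rVert_2^2$, restoring the
  *grouping effect*: exactly collinear regions receive equal coefficients
  and are selected together, where the lasso keeps at most one of them;
* **group lasso** — $\beta\sum_i \lVert\alpha_{G_i}\rVert_2$ over a
  partition $\{G_i\}$ of regions obtained by k-medoids clustering; a
  selected group enters as a whole.

Two conventions are worth making explicit, because the mathematical
notation in the field is often printed without them:

* The loss is the **squared** residual norm with factor $\tfrac12$. This is
  the convention of SLEP-style solvers and gives the standard closed forms
  (soft threshold, ridge-shrunk soft threshold, block soft threshold) on
  orthonormal designs.
* The group-lasso penalty is the plain sum of group $\ell_2$ norms
  (unweighted); `size_weighted = TRUE` switches on the
  $\sqrt{|G_i|}$ weights of the Yuan–Lin formulation.

### Penalty normalization

Raw penalty levels are not comparable across regions or subjects, so all
user-facing penalties are *fractions* of $\lambda_{\max}$, the smallest
penalty at which the all-zero solution is optimal:
$\lambda_{\max} = \max_j |a_j^\top x|$ for lasso/elastic net and
$\max_i \lVert A_{G_i}^\top x\rVert_2$ for the group lasso. A fraction of 1
always produces the empty model; $\lambda_{\min}$ is taken as 0. For the
elastic net the fraction is taken against the *lasso* $\lambda_{\max}$,
ignoring $\lambda_2$, so `lambda2 = 0` reduces exactly to the lasso. The
default grid is $0.1, 0.2, \ldots, 0.9$: nine hyper-edges per centroid, so
a 90-region subject yields a $90 \times 810$ incidence matrix.

### Solver

Lasso and elastic net are solved by cyclic coordinate descent on the Gram
matrix ($G = X^\top X$ is computed once per subject and shared by all 90
centroid problems, since zeroing column $m$ only zeroes a row/column of
$G$); the group lasso by FISTA with block soft-thresholding, with the
Lipschitz constant from the leading eigenvalue of $G$. Both are
deterministic (no random restarts), warm-started down the penalty grid, and
iterate until the KKT residual falls below $10^{-9}\lambda_{\max}$ (well
inside the $10^{-6}\lambda_{\max}$ contract the tests assert; the extra
accuracy makes structural identities such as duplicate-column coefficient
ties hold to $10^{-6}$ in the coefficients). Coefficients with magnitude
$\le 10^{-8}$ are declared zero — a numerical floor, since both algorithms
produce exact zeros at convergence. An empty support yields the retained,
flagged singleton hyper-edge $\{m\}$, keeping the incidence width fixed;
duplicate hyper-edges across grid levels are likewise retained.

## Region grouping for the group lasso

Similarity between regions is the Pearson correlation of their time
series; dissimilarity is $1 - r$ (optionally $1 - |r|$). By default the
series are pooled (averaged) across subjects so one partition is shared by
the whole cohort — Eq.-level group structure must be fixed per problem,
and a per-subject alternative is available by clustering a single
`roi_ts`. k-medoids uses k-means++-style seeding (first medoid uniform,
subsequent ones sampled proportionally to the dissimilarity to the nearest
chosen seed), alternates nearest-medoid assignment with within-cluster
medoid updates until the cost stops decreasing (at most 100 iterations),
and keeps the best of 10 seeded restarts. Everything is deterministic
given `seed`. The canonical group count is `k = 48`; the `sweep_k()`
helper reproduces the full $k = 6, 12, \ldots, 90$ sweep with repeated
seeds.

## Clustering-coefficient features

With incidence matrix $H$ ($H_{ve} = 1$ iff $v \in e$), node degree
$d(v)$, edge degree $\delta(e)$ and adjacency $A = HH^\top - D_v$, the
three node metrics are, for neighborhood $N(v)$ (co-members of $v$'s
edges, excluding $v$ itself) and star $S(v)$ (edges containing $v$):

* $HCC^1(v)$ — fraction of pairs $u, t \in N(v)$ co-occurring in an edge
  *without* $v$;
* $HCC^2(v)$ — fraction of pairs co-occurring in an edge *with* $v$;
* $HCC^3(v) = \dfrac{2\sum_{e \in S(v)}(|e| - 1) - |N(v)|}
  {|N(v)|\,(|S(v)| - 1)}$ — overlap among $v$'s edges.

Pair sums run over unordered pairs with the conventional leading factor 2
against the ordered-pair denominator $|N(v)|(|N(v)| - 1)$, which keeps
$HCC^1, HCC^2 \in [0, 1]$. $N(v)$ excludes $v$: a literal reading of the
set-builder definition would admit $u = v$, but that would count
self-pairs and contradict the notion of a neighborhood. Degenerate nodes
($|N(v)| \le 1$ for $HCC^{1,2}$; $|S(v)| \le 1$ or $N(v) = \emptyset$ for
$HCC^3$) return 0 and are flagged so the pipeline stays total — this
matters in practice because a single-level penalty grid leaves some nodes
in only one hyper-edge, zeroing the $HCC^3$ denominator. Per-subject
averages include flagged zeros by default; `drop_degenerate = TRUE` gives
the alternative policy. Whether the original analyses excluded degenerate
nodes is not documented anywhere we know of; including them as zeros is
the total, reproducible default.

Each subject contributes $3R$ features (270 at $R = 90$).

## Group statistics

Feature selection uses the two-sample Kolmogorov–Smirnov statistic with a
label-permutation null: $p = (1 + \#\{D^\pi \ge D\})/(1 + B)$, the +1
smoothing guaranteeing valid p-values. The default $B = 10^4$ resolves
below $q/m$ for 270 features; all features share one permutation set.
Rejections follow Benjamini–Hochberg step-up at $q = 0.05$ (via
`p.adjust`). Relief weights (classic binary Relief, every subject visited
once, Euclidean distances on standardized features) rank the selected
features. The *average hyper-edge* of a group summarizes one (centroid,
level) slot: $d$ = mean edge degree rounded up, then the $d$ most frequent
member regions, ties broken toward the lower region index (the tie rule is
ours; occurrence counting alone does not order ties).

## Classification

An RBF-kernel SVM (libsvm via `e1071`) is evaluated leave-one-subject-out.
Everything adaptive — feature standardization statistics and the
exhaustive $(c, g)$ grid search over $2^{-8} \ldots 2^{8}$ by stratified
inner 10-fold CV — happens inside each training fold; the held-out subject
is transformed with training statistics only. Grid-search ties break
toward smaller $c$, then smaller $g$. Patients are the positive class, so
sensitivity is the patient detection rate, and balanced accuracy is
$(\text{sens} + \text{spec})/2$. The inner fold count is capped at the
smaller class size. "Leave one out" is read as leave-one-*subject*-out
(leaving a feature out is not an evaluation scheme), and $(c, g)$ is
re-selected per fold — a leakage-free reading of an ambiguous protocol;
a global selection can be emulated by calling `grid_search_cv()` once.

## Synthetic cohorts

The generator makes every stage testable without clinical data. Region
$j$ of a subject is
$\sqrt{\rho}\,B_{b(j)}(t) + \sqrt{1-\rho}\,\varepsilon_j(t)$: one latent
signal per block plus private noise, all components unit-variance AR(1)
white noise (burn-in 100 samples), so the expected within-block
correlation is exactly $\rho$ and the full target correlation matrix is
available in closed form (`target_correlation()`). Patients additionally
receive a shared signal of scale `effect_size` on the affected regions
*and* a distant block, shifting their cross-block coupling and hence their
hyper-edge memberships — the mechanism behind group differences in
average hyper-edges. Columns are z-scored last. Per-subject seeds derive
deterministically from the master seed.

Defaults are the study conditions of a typical two-group resting-state
cohort: 28 controls + 38 patients, 90 regions, 238 retained volumes,
TR 2 s. Where no such condition exists we fixed, once, values a
practitioner would call realistic: 6 equal blocks (modular resting-state
organisation), within-block correlation 0.6, AR(1) coefficient 0.3
(moderate BOLD autocorrelation at TR 2 s), 3 affected regions,
effect size 1 (added coupling comparable to the block signal).

What the generator does *not* emulate: hemodynamic response convolution,
scanner noise spectra, motion artefacts, spatial smoothness, and
subject-level variability in block structure. Passing tests therefore
demonstrate the correctness and calibration of the machinery on data with
known ground truth, not clinical effect sizes; headline accuracies from
clinical cohorts are out of reach by construction, and the package makes
no attempt to reproduce them.

## Numerical choices and degenerate inputs

* Time-series columns are z-scored (sample sd, $n-1$) before every solve
  and the regressions carry no intercept; whether the original pipeline
  standardized is undocumented, and this convention makes the
  $\lambda_{\max}$ normalization well-behaved.
* Nuisance residualization is exact OLS via QR; rank-deficient designs
  are refused with the collinear columns named.
* A group consisting only of the centroid's zero column is forced to zero
  without error; a response orthogonal to all columns has
  $\lambda_{\max} = 0$ and every penalty yields the empty model.
* k-medoids seeding falls back to uniform sampling when all remaining
  dissimilarities are zero (duplicate regions).
* Constant features standardize to 0 (never NaN); LOOCV on minimal
  cohorts degrades gracefully (grid search returns the smallest pair when
  inner CV is impossible).

## Problem sizes used by the test-suite

The suite checks calibration and recovery at sizes chosen to keep the
whole run in a few minutes while leaving Monte-Carlo error well inside the
asserted margins: null calibration uses 200 replicates of 28+38-subject
cohorts at 6 regions, 40 timepoints and a 3-level grid (18 features,
$B = 200$); end-to-end recovery uses 20 regions, 20+20 subjects,
effect size 1.5, the 9-level grid and a reduced SVM grid
($2^{-4} \ldots 2^4$ step $2^2$, 5 inner folds). The acceptance script
mirrors the latter design.

## Known limitations

* Pure-R solvers: a 90-region, 9-level construction takes tens of seconds
  per subject; the Gram trick keeps this practical, but very large
  parcellations would warrant a compiled inner loop.
* Cohort-pooled clustering assumes equal series length across subjects.
* The group-lasso branch inherits k-medoids seeding variability across
  seeds; `sweep_k()` averages over seeds, mirroring the usual practice of
  reporting the mean of repeated runs.
* Hyper-edge weights (coefficient magnitudes) are discarded after support
  extraction; only membership enters the metrics.
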
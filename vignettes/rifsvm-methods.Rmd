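---
title: "Relative density-based intuitionistic fuzzy SVMs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative density-based intuitionistic fuzzy SVMs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifsvm)
library(dplyr)
```

## The problem

In imbalanced binary classification -- common across biomedical screening,
fault detection and fraud settings -- the minority (positive) class is the
one that matters, yet a standard soft-margin SVM drifts toward the majority
class because every instance pays the same slack penalty. Fuzzy SVMs
counteract this by weighting each instance's slack with a fuzzy value
$s_i \in [0, 1]$, so the optimization

$$
\min_{w, b, \xi} \ \tfrac12\|w\|^2 + C \sum_i s_i \xi_i
\quad \text{s.t.} \quad y_i(w^\top\phi(x_i) + b) \ge 1 - \xi_i,\ \xi_i \ge 0
$$

down-weights unreliable instances. Everything then hinges on how $s_i$ is
chosen. Centroid-based schemes (membership decaying with distance to the
class center) fail on exactly the data that motivate this package: classes
with small disjunct sub-clusters, and manifold-shaped classes such as
concentric rings, where the class center is unrepresentative -- or, for
rings, not even inside the class.

## The RIF weighting scheme

The package's core is a weighting scheme built from *relative density*
rather than centroid distance. For an instance $x_i$, let $d_{ik}$ be the
Euclidean distance to its $k$-th nearest neighbor within a reference class;
$1/d_{ik}$ is the KNN-based relative density. Sparse instances -- noise and
outliers -- have large $d_{ik}$ in their own class. The neighbor index
follows the square-root policy $k^\pm = \lceil m \sqrt{N^\pm} \rceil$ for
class sizes $N^\pm$ with multiplier $m = 1$ by default, clamped to
$[1, N^\pm - 1]$; too small a $k$ fails to flag noise, too large a $k$
flags ordinary instances.

Majority (negative) instances get an intuitionistic fuzzy number
$(\mu, \nu)$:

* membership from the within-class distance,
  $\mu^-(x_i) = 2 / (1 + \exp(d^w_i / \max_j d^w_j))$, so the densest
  instance scores near 1 and the sparsest scores $2/(1+e) \approx 0.538$;
* an opposite-class affinity
  $\rho(x_i) = 2 / (1 + \exp(d^b_i / \max_j d^b_j))$ from the distance to
  the $k^+$-th nearest *minority* neighbor -- large when the instance sits
  close to the minority class;
* non-membership $\nu^- = (1 - \mu^-)\,\rho$, which is large only when the
  instance is simultaneously sparse in its own class and close to the
  other class, i.e. behaves like noise between the classes.

The intuitionistic score
$H = 0$ if $\mu < \nu$, otherwise $(1 - \nu)/(2 - \mu - \nu)$, grades
reliability, and the final majority weight is $s_i = \mathrm{IR} \cdot H(x_i)$
with $\mathrm{IR} = N^+/N^-$ the minority-to-majority ratio. The IR factor
rebalances the two classes' aggregate slack penalty, which is what keeps the
separating surface from drifting toward the majority class.

Minority instances are deliberately exempt from the non-membership penalty:
with few positives, any positive looks "sparse" and a symmetric rule would
brand legitimate minority instances as noise. They take their within-class
membership directly, $s_i = \mu^+(x_i) = 2/(1+\exp(d^w_i / \max_j d^w_j))$
over the minority class.

Two readings of the affinity normalizer are possible, because the written
form of the denominator ($\max\{d_{1k^+}, \ldots\}$) is ambiguous about
which instance set the maximum ranges over. The default normalizes each
majority instance's minority-side distance by the maximum of those same
distances, which keeps the decay argument in $(0, 1]$, makes $\rho < 1$,
and -- together with $\mu^- \ge 2/(1+e) > 1/2$ -- guarantees
$\mu^- > \nu^-$, so the $H = 0$ noise branch is unreachable and every
majority weight stays positive. The literal alternative (reusing the
minority within-class maximum) is available via
`rif_weights(rho_normalizer = "minority_within")`. The $\mu < \nu$ branch
of the score is retained verbatim even though the default normalizer never
reaches it.

## The IFSVM baseline

The centroid-based intuitionistic baseline is implemented for comparison:
membership $\mu(x_i) = 1 - \|\phi(x_i) - c_\pm\| / (R_\pm + \delta)$ with
the class mean $c_\pm$ and radius $R_\pm$ computed in kernel space via the
Gram-matrix expansion, $\delta = 10^{-4}$; affinity $\rho$ as the fraction
of instances within kernel distance $\beta_1$ of $x_i$ (the instance itself
counted in the denominator) that carry the opposite label, with
$\beta_1 = \min(R^+, R^-)/5$ by default; $\nu = (1-\mu)\rho$; and the score
with its extra $\nu = 0 \mapsto \mu$ branch applied to *both* classes --
the baseline has no class-asymmetric rule. On data with sub-clusters or
ring geometry this scheme visibly mis-weights boundary minority instances,
which is the behavior the RIF scheme corrects.

## The weighted solver

The dual

$$
\max_\alpha \ \sum_i \alpha_i - \tfrac12 \sum_{i,j}
\alpha_i \alpha_j y_i y_j K(x_i, x_j)
\quad \text{s.t.} \quad \textstyle\sum_i y_i \alpha_i = 0,\quad
0 \le \alpha_i \le s_i C
$$

differs from the standard SVM dual only in its per-sample box bounds, and
no off-the-shelf R SVM exposes those, so the package ships its own solver:
sequential minimal optimization over maximal-violating pairs with
second-order (quadratic-gain) working-set selection, written in C++. The
contract is the KKT system at tolerance, not the algorithm: tests verify
the complementarity conditions, agreement of the dual objective with a
generic dense QP solver, and -- at unit weights -- agreement of decision
values with an independent SVM implementation.

Numerical choices:

* stopping when the KKT gap falls below `tol` ($10^{-6}$ for final fits);
  deterministic for a fixed input order, no randomized working sets;
* during cross-validated grid scoring the solver runs at a looser gap
  ($10^{-4}$) with a 20,000-iteration cap and warm-starts each fit from
  the previous solution along the ascending-$C$ path (feasible, since the
  box only widens); model selection only needs fold rankings, and the
  selected pair is refit at full tolerance;
* the bias is the mean of $y_i - \sum_j \alpha_j y_j K_{ij}$ over free
  support vectors (strictly inside their box), the robust generalization
  of reading it off a single support vector; with no free support vector
  it falls back to the midpoint of the feasible interval the KKT
  inequalities leave for $b$;
* support vectors are $\alpha_i > 10^{-8}\, C \max_i s_i$;
* a cost-sensitive variant with per-class costs $C^- / C^+ = \mathrm{IR}$
  is algebraically the same box ($s_i$ absorbed the IR factor), asserted
  by a unit test rather than implemented as a second code path.

## Synthetic data generators

Two generators reproduce the study geometries and are first-class,
tested code:

* `synth_data1()`: three isotropic Gaussian groups in 2-D -- 800 negative
  points at $(0.4, 0.4)$, and 50 + 150 positive points at $(0.15, 0.15)$
  and $(0.7, 0.7)$ -- all with per-axis spread $0.1$ read as a diagonal,
  correlation-free scale applied independently per axis. A 1:4 imbalance
  with a small disjunct positive cluster and genuine class overlap.
* `synth_data2()`: two concentric origin-centered annuli of radial width
  $0.2$, negative inner radius $0.6$, positive inner radius $0.3$; the
  classes are separated by a $0.1$ radial gap. Absolute counts are not
  part of the geometry specification, only the 1:5 ratio; the default
  100 positive / 500 negative keeps the size comparable to the cluster
  preset and is configurable. The sampling law inside an annulus --
  angle uniform on $[0, 2\pi)$, radius uniform on the band -- is the
  simplest law consistent with a fixed ring width.

What these emulate: class imbalance, sub-cluster structure, manifold
geometry, and (through overlap) label noise near boundaries. What they do
not: high dimensionality, heavy-tailed or discrete features, feature
correlation, and real measurement artifacts. Passing the synthetic studies
therefore demonstrates the weighting scheme's intended behavior on the
geometries it was designed for, not performance on real screening data --
for that, the benchmark comparison machinery consumes published scores
(below).

## Evaluation protocol

`repeated_holdout()` runs the full study: per repeat a stratified 80/20
split (repeat $r$ is seeded `seed + r`), hyperparameter selection by
5-fold cross-validation on the training part maximizing mean fold G-Mean
over $C \in \{10^{-5}, \ldots, 10^5\}$ and RBF spread
$h \in \{2^{-5}, \ldots, 2^5\}$ (ties to the smaller $C$, then smaller
$h$), a final fit, and test metrics. Min-max normalization is applied to
the whole dataset before splitting by default, matching the reproduction
convention of normalizing all attributes to $[0, 1]$ as a preprocessing
step; a leakage-free per-split mode (`normalize = "fold"`) and `"none"`
are available.

Metrics are percent-scale sensitivity, specificity, G-Mean
$= \sqrt{\mathrm{Se} \cdot \mathrm{Sp}}$, F-Measure, and AUC; per-repeat
values are averaged arithmetically (so the averaged G-Mean is *not* the
G-Mean of averaged Se/Sp -- the reference synthetic table itself exhibits
this distinction, which fixes the averaging convention).

The AUC estimator deserves a note. `auc_score()` is the general
tie-corrected Mann-Whitney rank statistic and accepts any scores. The
protocol, however, defaults to scoring the *hard predicted labels*
(`auc_on = "labels"`), which reduces the rank AUC to
$(\mathrm{Se} + \mathrm{Sp})/2$. The reason is internal consistency of the
reference synthetic results: all four reference rows satisfy
$\mathrm{AUC} = (\mathrm{Se} + \mathrm{Sp})/2$ exactly (e.g.
$(92.50 + 99.13)/2 = 95.81$), while decision-value AUC on the cluster data
runs 3--4 points higher, so the label-based estimator is the one the
reference numbers were computed with. `auc_on = "decision"` switches to
continuous decision values.

`k_sweep()` repeats the whole protocol across neighbor-policy multipliers
(default $\{1/3, 1/2, 1, 2, 3\}$) to examine sensitivity to $k$; on the
synthetic geometries performance is flat-to-unimodal across this range,
consistent with the square-root default being a reasonable operating
point.

Problem sizes: the shipped studies use the presets at full size (1,000 and
600 points, 10 repeats, the full $11 \times 11$ grid with 5 folds). One
full study is a few minutes of single-core compute; the warm-started CV
solver is what keeps the $11 \times 11 \times 5 \times 10$ solve count
tractable.

## Rank-based comparison machinery

`rank_table()`, `friedman_rank_test()`, `nemenyi_cd()` and
`compare_report()` implement the standard multi-classifier comparison:
within each dataset row algorithms are ranked best = 1 with tied values
receiving the mean of the ranks they span (this tie convention reproduces
the published average ranks exactly on the packaged tables), then

$$
\Gamma_{\chi^2} = \frac{12 n}{k(k+1)}
\Big(\sum_i r_i^2 - \frac{k(k+1)^2}{4}\Big), \qquad
\tau_F = \frac{(n-1)\,\Gamma_{\chi^2}}{n(k-1) - \Gamma_{\chi^2}},
$$

with $\tau_F \sim F(k-1, (k-1)(n-1))$ under the null of equal performance.
No tie-correction factor is applied to $\Gamma_{\chi^2}$ (the plain
statistic, as used by the reference analysis). The Nemenyi critical
difference is $CD = q_\alpha \sqrt{k(k+1)/(6n)}$ with $q_\alpha$ hard-coded
from the standard two-tailed studentized-range-based table for
$k = 2..10$, $\alpha \in \{0.05, 0.10\}$; $q_{0.05}(8) = 3.031$ gives
$CD = 2.3478$ at $k = 8, n = 20$.

The packaged `benchmark_*.csv` tables transcribe published scores of eight
algorithms on twenty KEEL/UCI datasets and are inputs, not outputs: the six
third-party comparison algorithms are out of scope and never reimplemented.
One transcription finding is worth recording: the G-Mean and F-Measure
tables reproduce their published average ranks (1.60, 1.70) and Friedman
statistics (7.50, 6.24) exactly, but the AUC table as printed yields an
RIFSVM average rank of 1.55 and $\tau_F = 7.99$ under every tie convention,
not the published 1.85 / 6.04 -- an internal inconsistency of the source
table that the package reports as computed.

## Worked example

```{r example, eval = FALSE}
d <- synth_data2(seed = 1)
w <- rif_weights(d)
summary(w$weight[w$label == -1])  # majority weights, bounded by IR = 0.2

fit <- rifsvm(d, scheme = "rif", C = 1, kernel = rbf_kernel(2))
glance(fit)
autoplot(fit, d)  # ring-shaped boundary between the annuli

report <- repeated_holdout(d, "rif", eval_protocol(seed = 1))
glance(report)    # mean G-Mean 100 on the separable rings
```

## Known limitations

* Binary problems only; multiclass decomposition is out of scope, as are
  twin/least-squares SVM formulations.
* The density profile is computed in (normalized) input space; a flagged
  kernel-space variant is not provided because the weighting scheme is
  defined without reference to a kernel. Distances are Euclidean.
* The dense Gram matrix bounds practical problem size at a few thousand
  instances; there is no approximate-neighbor index or solver shrinking.
* Grid-search scoring accepts slightly sub-converged solutions by design
  (looser gap + iteration cap); pathological grid corners (very large $C$
  with very narrow kernels) may be ranked from an approximate fit. The
  final model is always refit at full tolerance.
* The $q_\alpha$ table covers $k \le 10$ and $\alpha \in \{0.05, 0.10\}$.
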
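---
title: "Semi-supervised projective NMF: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised projective NMF: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semipnmf)
```

## The model

Expression-based classification with few labels is a label-propagation
problem: a handful of samples carry class annotations, the rest only their
expression profile. `semipnmf` couples both through a single non-negative
factorization. With `V = [V_L; V_U]` (samples × genes, non-negative),
one-hot indicator `Q` (d × r) for the labeled block and free coefficients
`H_U` (n_U × r) for the unlabeled block, the objective is

$$J(W, H_U) = \tfrac12 \big\lVert \begin{bmatrix} V_L \\ V_U \end{bmatrix}
 - \begin{bmatrix} Q \\ H_U \end{bmatrix} W \big\rVert_F^2
 + \tfrac{\alpha}{2}\,\lVert W - H_U^\top V_U \rVert_F^2
 + \tfrac{\beta}{2} \sum_{i=1}^{n_U}\sum_{j=1}^{r}
   |H_{U,ij}|\,\lVert V_U^i - W^j \rVert_2^2 .$$

Three assumptions are baked in. First, classes are representable by
non-negative centroids in gene space (rows of `W`), and a sample is
approximately a non-negative combination of them. Second, the labeled
coefficients are *pinned* to `Q` — they are never free variables — so label
information reaches the unlabeled samples only through the shared `W`.
Third, centroids should lie near the span of the (typically much more
numerous) unlabeled samples: that is the projective term with weight
$\alpha$. The local coordinate coding term with weight $\beta$ penalizes a
sample loading on a distant centroid, which drives each `H_U` row toward a
sparse, nearly one-hot profile — exactly the shape the argmax classification
rule needs. Classification is `predict_classes()`: the column index of the
row maximum, ties to the lowest index (deterministic, and invariant under
positive rescaling of `H_U`).

With `d = 0` the `Q` blocks vanish and the model degenerates gracefully to
an unsupervised projective NMF; the package allows this (`labels = NULL`
with explicit `classes`), mainly for diagnostics.

## Optimization

Both factors are updated by multiplicative rules, `W` first, then `H_U`,
once per sweep:

$$W \leftarrow W \otimes \frac{Q^\top V_L + (1+\alpha+\beta) H_U^\top V_U}
 {Q^\top Q W + H_U^\top H_U W + \alpha W + \beta F_U W}, \qquad
 F_U = \mathrm{diag}(\mathbf{1}^\top H_U)$$

$$H_U \leftarrow H_U \otimes \frac{(1+\alpha+\beta)\, V_U W^\top}
 {H_U W W^\top + \alpha V_U V_U^\top H_U + \tfrac{\beta}{2}(A+B)},
 \quad A_{ij} = \lVert V_U^i \rVert_2^2,\; B_{ij} = \lVert W^j \rVert_2^2 .$$

Each rule is the closed-form minimizer of a convex auxiliary function that
majorizes `J` in the respective block, so a sweep can never increase the
objective. The test suite checks this property directly on hundreds of
random instances (relative slack 1e-9 for floating point), and checks the
vectorized rules against naive scalar-loop transcriptions to 1e-12.

Two shape conventions deserve a note, because dimensional analysis forces
them: `F_U` must be r × r, hence it holds *column* sums of `H_U` (total
coefficient mass per class); and `A`/`B` broadcast the unlabeled-row norms
across classes and the centroid-row norms across samples respectively —
this matches the gradient of the local coordinate term,
$\partial/\partial H_{ij} = \lVert V_U^i\rVert^2 - 2 V_U^i \cdot W^j +
\lVert W^j\rVert^2$ (for $H \ge 0$).

Numerical choices:

* **Initialization.** `W` and `H_U` start i.i.d. uniform on (0, 1) from the
  user's seed. A strictly positive start matters: multiplicative rules
  preserve exact zeros forever ("zero locking"), so a zero entry at
  initialization could never activate.
* **Denominator guard.** Multiplicative ratios are undefined at exact zero
  denominators; a tiny additive guard (default 1e-12) keeps them defined
  while perturbing descent only at numerical precision. It is configurable
  (`denom_guard`) and the fixed-point tests use a near-zero guard to verify
  stationarity exactly.
* **Stopping.** The relative criterion $|J_{l+1}-J_l|/|J_l| < \varepsilon$
  with $\varepsilon = 10^{-7}$ by default, capped at 1500 sweeps. The full
  three-term objective is evaluated for the criterion. `J = 0` exactly stops
  immediately. Hitting the cap sets `converged = FALSE` but is not an error.
* **KKT check.** At a converged point every multiplicative factor should be
  1 on the support; the tests verify factors within 1 ± 1e-3 on entries
  above 1e-6.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.2 | weight of the centroid-consistency (projective) penalty; dimensionless, scales with squared expression units |
| `beta` | 0.01 | weight of the local coordinate coding penalty |
| `tol` | 1e-7 | relative objective change at which iteration stops |
| `max_iter` | 1500 | sweep cap |
| `denom_guard` | 1e-12 | additive guard in update denominators |
| `seed` | 1 | initialization seed; same seed ⇒ identical fit |

The defaults favour a mild projective pull: `alpha` of order 0.1–1 works
well when unlabeled samples outnumber labeled ones moderately; larger values
(≈ 2) emphasize the unlabeled-span constraint and suit problems with many
classes and very few labels per class, at the price of slower coefficient
contrast. `beta` mainly sharpens coefficient sparsity; 1e-4 to 1e-2 is a
sensible range. Neither parameter is tuned automatically — the package
deliberately has no model-order selection either: the rank `r` always equals
the number of declared classes.

## The synthetic benchmark

`generate_toy()` draws three classes in three dimensions: class means
(1, 0.8, 0.8), (0.8, 0.8, 0.8), (0.8, 1, 0.7), uniform noise `scale · U(0,1)³`
with scales 0.1, 0.1, 0.15, ten samples per class, the first three labeled —
30 samples, 9 labeled, 21 unlabeled. The classes occupy disjoint axis-aligned
boxes (class 1 is separated on coordinate 1, class 3 on coordinates 2 and 3),
so the benchmark probes label propagation, not class overlap. Labeling the
*first* three per class is an arbitrary but exchangeable choice, since
samples are i.i.d. within class.

What the toy does **not** emulate about real expression data: dimensionality
(3 coordinates vs 10⁴–10⁵ genes), heavy-tailed and heteroscedastic noise,
correlated genes, batch effects, and class imbalance. Passing the toy
recovery tests therefore demonstrates the mechanics of the method —
monotone optimization, label propagation, argmax readout — not clinical
performance.

A caution specific to this geometry: all toy samples have nearly the same
direction (entries ≈ 0.7–1.1), so cosine structure barely discriminates and
the reconstruction term does the classifying. A related effect shows up in
the centroids: the projective term matches `W` to coefficient-weighted
*sums* of samples, which inflates centroid norms by a common factor, so
learned centroids align with the generating means in direction rather than
raw Euclidean position (the tests normalize rows before matching).

## Preprocessing

* **Box bounding** clamps to [20, 16000] by default — the conventional
  conditioning for array intensities (noise floor and scanner saturation).
  Idempotent; `NA`s pass through.
* **Ratio/variation filter** keeps genes with max/min ≥ 5 **and**
  max − min ≥ 500 across samples. Thresholds are inclusive: a gene at ratio
  exactly 5 is kept. The full per-gene report (max, min, ratio, variation,
  kept) is returned so the surviving count is auditable. Bounding must
  precede filtering — the pipeline order is combine → bound → filter — and
  a zero gene minimum is an error pointing at the missing bounding step.
* **kNN imputation** fills each missing entry with the mean of the k = 5
  nearest *genes*' values at that sample. The neighbour axis (genes),
  distance (Euclidean over co-observed entries, normalized by the
  co-observed count so unequal missingness patterns compare fairly) and k
  are all package decisions — reasonable defaults in the imputation
  literature, and all configurable. Observed entries are never modified.

## Evaluation protocols

Two harnesses are provided, and neither is silently preferred, because they
answer different questions:

* `leave_one_unlabeled()` hides one sample's label per fold, fits on all
  samples with that one unlabeled, and predicts it (per-fold seed = base
  seed + fold index). **Known limitation:** with `n_U = 1` the projective
  term asks the rank-1 outer product $H_U^\top V_U$ to match all `r`
  centroid rows at once, which flattens the coefficient contrast; on highly
  collinear data (such as the toy) this costs real accuracy (~70% on the toy
  versus ~100% transductive). The protocol is faithful to its definition; it
  is simply a stress test of the model's degenerate corner.
* `labeled_count_curve()` draws `n = 1…6` labeled samples per class
  (uniformly, without replacement, seeded), fits once with everything else
  unlabeled, and averages accuracy over many trials (default 100). This
  transductive protocol matches the model's intended use and yields the
  rising accuracy-vs-labels curve; on the toy it is near-perfect already at
  one label per class.

Metrics follow the one-vs-rest definitions: sensitivity TP/(TP+FN),
specificity TN/(TN+FP) per class, total accuracy as diagonal percentage.
Zero-denominator ratios are reported as `NA`, never 0, and macro averages
drop them.

## Problem sizes in the test and acceptance runs

The automated checks run at desk scale by design: random instances up to
20 × 10 with 2–4 classes for the descent and oracle properties (hundreds of
instances, seconds), the default 30-sample toy for recovery (20 seeded
fits), 30 leave-one-unlabeled folds, and 20-trial label-count curves. These
sizes make every property cheap to verify exactly while exercising the same
code paths as a full-size analysis; nothing in the implementation is
specific to small matrices (the updates are plain dense linear algebra,
`O(r²n + mrn)` per sweep).

## Known limitations

* No automatic tuning of `alpha`/`beta`; no rank selection beyond the class
  count.
* The objective is jointly non-convex; different seeds can reach different
  local minima (the toy recovery rate is reported over 20 seeds for this
  reason).
* Multiplicative updates stall near zero entries rather than crossing them;
  exact zeros in the initialization would lock (hence the positive uniform
  start).
* The leave-one-unlabeled degeneracy discussed above.
* Dense algebra throughout: very wide matrices (10⁵ genes) are handled, but
  `V_U V_U^\top` in the `H_U` update is `n_U × n_U`, so extremely many
  unlabeled samples dominate memory.
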
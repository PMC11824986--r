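---
title: "Cost-sensitive multi-kernel ELMs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive multi-kernel ELMs: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costelm)
```

## The problem

In diagnostic classification the two kinds of error are rarely equally bad:
calling a diseased sample healthy usually costs far more than the reverse.
`costelm` implements a family of closed-form neural classifiers — extreme
learning machines (ELMs) — whose final decision explicitly minimizes the
expected misclassification cost under a user-supplied cost matrix, rather
than maximizing raw accuracy.

Everything in the package trains in closed form: hidden layers are drawn
randomly once and frozen, and only output weights are solved, by ridge
regression. There is no iterative optimization anywhere in the training
path, which is what makes the models fast and exactly reproducible from a
seed.

## Building blocks

### Ridge solve in two Gram forms

Every fit reduces to `min ||H B - T||_F^2 + (1/C)||B||_F^2`, solved either
as `B = H'(I/C + HH')^{-1} T` (inverting an `N x N` matrix) or as
`B = (I/C + H'H)^{-1} H' T` (inverting `p x p`). The two are algebraically
identical; `ridge_solve()` picks whichever inverts the smaller matrix
(`gram_n` iff `N < p`, ties to `gram_p`). The regularizer enters as `I/C`
added to the Gram matrix, so **larger `C` means weaker shrinkage**. The
sigmoid is evaluated in a sign-branched form so extreme scores cannot
overflow.

### Kernels as similarity features

Four similarity functions are fused (`kernel_spec()`): the RBF kernel
`exp(-||x-r||^2/2σ²)`, the squared Euclidean distance, the Manhattan
distance, and a cosine similarity. Two deliberate literalisms:

* The distance families are used *as is*, without conversion to a decaying
  similarity. The downstream ridge solve is indifferent to the monotone
  orientation of a feature, so nothing is gained by flipping them.
* The default cosine (`cosine_printed`) divides by the **squared** norms
  `(x·r)/(||x||²||r||²)`. This is not the textbook cosine; whether the
  squared norms are intended is genuinely unclear, so the package ships the
  printed form as the default and the standard form
  (`cosine_standard`) behind a flag.

The RBF bandwidth σ is nowhere prescribed; the package defaults to the
median pairwise Euclidean distance of the rows of the representation the
kernel is applied to (raw features for RKELM-AE, the random-mapped rows for
REKELM-AE), the standard median heuristic. It is overridable via
`kernel_spec("rbf", sigma = ...)`.

### Reduced kernel autoencoders

A kernel ELM autoencoder (`fit_kelm_ae()`) solves
`Γ = (I/C + Ω)^{-1} X` with `Ω` the full `N x N` kernel matrix — an
`O(N³)` solve. The reduced variant (`fit_rkelm_ae()`) instead measures
every sample's similarity to a random subset of `n_refs` training rows,
giving a rectangular `N x n_refs` matrix and an `n_refs x n_refs` solve.
The rationale: two nearby reference points produce nearly identical
similarity columns, so most of the full kernel matrix is redundant.
References are drawn **without replacement** for exactly this reason.

The reduced *expectation* kernel autoencoder (`fit_rekelm_ae()`, the
package's central encoder) composes a random map with a kernel map:

1. draw a random layer of `L1` sigmoid nodes, standard-Gaussian weights;
2. map: `H = h(V'X)`, an `N x L1` matrix;
3. draw `n_refs` rows of `H` as reference points;
4. form `Ω̂[i,j] = K(h(V'x_i), r_j)`;
5. solve the ridge system `Ω̂ Γ ≈ X`.

This is an empirical expectation-kernel construction: applying a standard
kernel to randomly mapped inputs. No separate integral estimator is
implemented — the random-map-then-kernel composition *is* the estimator.

Two sizing ratios control the encoder and are the primary tuning knobs:
`r1 = L1/d` (dimensional expansion; default 10, performance is quite flat
in it) and `r2 = n_refs/N` (compression; default 0.05, with `ablate_r2()`
sweeping the 0.01–0.2 range where the interesting behavior lives — too few
references under-span the similarity space, too many add redundant
features).

### Two open readings, decided

**Encoding at inference.** `Γ` is solved in kernel space, yet the abstract
feature used downstream is the linear projection `XΓ'` on *raw* features.
The package follows that formula literally (`encode(..., method =
"linear")`), applying the same projection to training and unseen rows; the
alternative — using a sample's kernel row `Ω̂(x)` as its feature — is
available as `method = "kernel"` but is not the default.

**Residual wiring.** The residual stack adds an encoder's "input and
output". The encoding `XΓ'` is `N x n_refs` and cannot be added to an
`N x d` input unless `n_refs = d`, so the package reads "output" as the
encoder's **reconstruction** (always `N x d`): `Y^(i) = Y^(i-1) +
reconstruct(enc_i, Y^(i-1))`. Encoder `i` is refitted on the running
representation `Y^(i-1)` (not on `X`), and the final classifier consumes
`Y^(k)` only. This is the simplest dimension-consistent reading of a
residual stack.

### The two multi-kernel architectures

* **MKP-ELM** (`fit_mkp_elm()`): one REKELM-AE per kernel fitted in
  parallel on `X`; encodings concatenated column-wise (width
  `k × n_refs`); one final ELM classifier on the concatenation.
* **MKR-ELM** (`fit_mkr_elm()`): the residual cascade above; the
  representation keeps width `d` at every stage.

All encoders share the same `L1`, `n_refs` and `C`; the final classifier
uses `L` uniform-(-1,1) hidden nodes (default `L = 1000`, `C = 100`).
Targets are coded +1/-1 (true class/other); this centers the scores at 0 so
that the sigmoid used for posterior conversion maps an uninformative score
to 0.5. The coding is configurable (`target_coding = "zero_one"`).

### Seeding

One master seed per model. Component seeds are derived by a fixed affine
counter, and each encoder's sub-seed is keyed to its **kernel family**, not
its position in the list — so permuting the kernel bank permutes the fitted
encoders instead of silently redrawing them, and the concatenated feature
matrix is a column permutation of the original. Fits never touch the
session RNG state.

## The decision layer

Raw scores `f(x)` become posteriors by `P(i|x) = sigmoid(f_i(x))` followed
by row normalization (the sigmoids need not sum to 1 across classes).
Probabilities are clamped to `[1e-12, 1 - 1e-12]` before normalizing so
expected risks stay finite. The decision is then

`j* = argmin_j Σ_i P(i|x) c[i,j]`,

the class with lowest expected cost under the `m x m` cost matrix `c[i,j]`
(true class `i`, predicted `j`, zero diagonal). Ties break to the lowest
class index, deterministically. With 0-1 costs this is exactly the argmax;
scaling the whole matrix changes nothing.

A practical caveat the tests make visible: the sigmoid of ±1-coded ridge
scores is a *squashed* posterior — confident samples rarely exceed ~0.75.
Under a strongly asymmetric cost matrix the minimum-risk rule therefore
shifts aggressively toward the expensive class, buying large cost
reductions at a real accuracy price. That trade is the intended behavior
of a minimum-risk decision layer, not a defect, but users should expect
accuracy to drop when costs are very skewed.

### Cost matrices and weighting baselines

`make_cost_matrix()` offers a uniform-integer family (off-diagonal costs
uniform on `[1, 20]`, the regime used for model comparison) and three
structured families — uniform `[1, 10]` (`type_a`), one severity per true
class (`type_b`), and imbalance-linked costs proportional to inverse class
frequency (`type_c`). **The three typed families are this package's own
synthetic constructions**, named after a conventional three-way severity
taxonomy; no canonical definition exists for them.

`compute_cost_weights()` implements four per-sample weighting schemes
(inverse class size; true-class row-sum cost; its mean-1 rescaling; and a
hierarchical-ELM class weighting). The row-sum scheme drives the weighted
baseline `fit_celm()`, whose weighted ridge is solved in whichever Gram
form inverts the smaller matrix via the push-through identity. One parsing
note: the hierarchical-ELM weight formula is implemented as
`w_i = 1/(p_i + (N_i - p_i)·N_i/max_c N_c)` with `p_i = N - N_i` — the
reading under which weights are strictly positive for every class mix,
which the other candidate parses are not.

## Evaluation

`evaluate_predictions()` reports the confusion table, accuracy
`1 - Σ err_i / N`, and total misclassification cost
`Tc = Σ_ij err_ij c[i,j]`; `relative_performance()` divides each method's
`Tc` by the worst method's, anchoring the comparison at 1.

## The synthetic benchmark

`generate_classification_data()` draws one Gaussian center per class
(coordinates `N(0, separation²)`) and scatters samples with isotropic noise
`N(0, noise_sd²)`; class sizes are one multinomial draw at the requested
proportions (with a guarantee that no class is empty), rows shuffled,
everything deterministic from the seed.

The benchmark conditions used by the test suite and `scripts/acceptance.R`
are fixed once: 6 features, `separation = 1.3`, `noise_sd = 1.8`. This
places single-model argmax accuracy in the high-70s/low-80s percent range —
the regime of the public tabular benchmarks this class of methods is
usually evaluated on, and the regime where both kernel fusion and
cost-sensitive decisions have room to act. Problem sizes are `n = 300`
(3-class model comparison, 5–10 replicate seeds) and `n = 600` (2-class
cost-ratio-10:1 decision comparison, 10–20 seeds), with 60/40 train/test
splits throughout.

What the generator does *not* emulate about real tabular biomedical data:
correlated or heavy-tailed features, label noise, non-Gaussian class
shapes, and batch structure. Passing the directional tests (fusion helps;
minimum-risk cuts cost) on these clusters shows the machinery behaves as
designed, not that it will win on any particular real dataset.

Min-max normalization to [0, 1] is available (`minmax_normalize()`) and is
fitted **on training data only**, with the stored bounds reapplied to test
rows (which may therefore leave [0, 1]). Normalizing each split jointly
would leak test information; this is a deliberate deviation from the
common whole-dataset practice. Constant columns map to 0.

## Numerical choices

* `n_refs = round(r2 · N)`, clamped to `[1, N]`; `L1 = round(r1 · d)`,
  at least 1.
* Regularization is written as `I/C` on the Gram matrix exactly; `C → 0`
  shrinks all output weights to zero (so an MKR stack with tiny `C` is the
  identity map — a property test), `C → ∞` approaches interpolation.
* Posterior clamp at `1e-12`; risk ties to the lowest class index.
* Serialization is JSON at full double precision with atomic
  write-temp-then-rename; a reloaded model predicts bit-identically.

## Known limitations

* Posterior calibration is crude (sigmoid of ridge scores); a calibrated
  downstream (e.g. isotonic or Platt on a validation split) would temper
  the aggressive shifts under skewed costs. Out of scope here.
* The cosine-with-squared-norms default is scale-variant in an unusual way
  (doubling all features quarters the similarity); users who want the
  geometric cosine should pass `cosine_standard`.
* Kernel weights are not learned; fusion is by concatenation or residual
  stacking only.
* No stacked deep variants beyond the residual cascade, and no
  iterative/online training — closed-form solves are the point.
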
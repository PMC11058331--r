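---
title: "Frequency-space amplitude mixing with meta-learning: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-space amplitude mixing with meta-learning: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

A segmentation network trained on slices from one hospital (one scanner,
one contrast agent, one patient population) often degrades sharply on
slices from another. Single-source domain generalization asks for a model
that transfers to the unseen site *without* any target data or retraining.
`mfnet` implements one mechanism for this, tailored to multi-modal MRI-like
data where each case carries several co-registered contrasts (e.g. T1-,
T2- and contrast-enhanced T1-weighted slices): the modalities share
anatomy but differ in low-level appearance, and that appearance diversity
can be harvested as augmentation.

## The model

**Spectral decomposition.** For a real 2D slice $x$, the unnormalized DFT
is written in polar form $F(x) = A \cdot e^{iP}$, with amplitude $A = |F(x)|$
and phase $P = \arg F(x)$. Empirically, $A$ carries low-level "style"
(contrast, intensity distribution) while $P$ carries spatial semantics
(edges, anatomy). The literature sometimes writes the decomposition loosely
as $F(x) = A + P$; only the polar reading is invertible, and it is the one
consistent with reconstructing via $F^{-1}(A, P)$, so it is what
`decompose_image()` / `compose()` implement. We fix the convention:
unnormalized forward transform, $1/(WH)$-normalized inverse. The mixing
result is invariant to this choice as long as the pair is consistent;
fixing one makes every worked example numerically checkable.

**Amplitude mixing.** Given a source modality $k$ and a donor modality
$h \ne k$ of the *same* case, `mix_images()` forms

$$A^m = (1-\lambda)A^k + \lambda A^h, \qquad
  x^m = \mathrm{Re}\,F^{-1}\!\big(A^m e^{iP^k}\big), \qquad
  \lambda \sim U[0,1],$$

and carries the source mask over unchanged — phase is untouched, so the
spatial semantics (and hence the label) are preserved. Because amplitudes
of real images are Hermitian-symmetric and convex combination preserves
that symmetry, the imaginary residual of the inverse is float noise; the
real part is taken and values are clipped to the valid range $[0,1]$.
The full spectrum is mixed: the mechanism is a *continuous* interpolation
in frequency space, and no band restriction is applied by default.

**Two-task meta-learning.** Training alternates two coupled tasks per
batch. On the original batch, the Dice loss

$$L_{\mathrm{init}} = 1 - \frac{2\sum_i p_i g_i + \varepsilon}
  {\sum_i p_i^2 + \sum_i g_i^2 + \varepsilon}$$

is computed at the current parameters $\theta$, and a single plain gradient
step gives the adapted parameters
$\hat\theta = \theta - \gamma \nabla_\theta L_{\mathrm{init}}$.
The mixed batch is then evaluated *at the adapted parameters*,
$L_{\mathrm{mix}} = L(f_{\hat\theta}(x^m))$, and the outer SGD step
minimizes $\alpha L_{\mathrm{init}} + \beta L_{\mathrm{mix}}$. The
inner step acts as a one-step rehearsal: parameters are pushed in a
direction that still works after adaptation when the style of the input
shifts, which is precisely the deployment condition at an unseen site.
$\beta = 0$ recovers plain empirical risk minimization exactly, step for
step — this reduction is asserted bit-for-bit in the test suite.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| $\alpha,\beta$ | 1, 1 | dimensionless | published sensitivity analysis reports stability over $[0.7, 1.3]$ but not the chosen values; equal weighting is the neutral choice |
| $\gamma$ (`inner_lr`) | 0.01 | LR units | not printed in the source experiment; set equal to the base LR so inner and outer steps share a scale |
| `base_lr` | 0.01 | — | standard for SGD + poly decay in segmentation |
| `poly_power` | 0.9 | — | the scheduler is named but its exponent is not; 0.9 is the dominant convention |
| `momentum`, `weight_decay` | 0.9, 5e-4 | — | stated training recipe; both apply to the outer step only — the printed inner update is plain gradient descent |
| `batch_size` | 4 | images | stated recipe |
| `epochs` | 30 | — | "30 iterations" is read as 30 epochs: it is described as sufficient for convergence, which 30 optimizer steps cannot be for a U-Net |
| `second_order` | `FALSE` | — | whether the original back-propagates through $\hat\theta$ is unstated; first-order is standard for this family and CPU-friendly. Both modes are validated against closed forms |
| $\lambda$ granularity | per sample, per iteration | — | unstated in the source; per-sample maximizes augmentation diversity |

The donor modality is drawn uniformly from the other modalities of the
same case — the mixing equation indexes both spectra by the same patient.
Whether the original work ever mixed across patients is unknown;
within-patient mixing is what is implemented.

## Numerical choices

* **Dice loss smoothing**: the printed formula has no $\varepsilon$ and is
  undefined for an empty mask with a zero prediction; $\varepsilon = 10^{-6}$
  is added to numerator and denominator. Set `eps = 0` to recover the exact
  formula (the tests do).
* **Metrics**: predictions are binarized at 0.5. Empty-vs-empty mask pairs
  score 1 (correct rejection); the published evaluation only uses
  lesion-containing slices, but the functions must be total. The primary
  MIoU is the per-image *foreground* IoU mean, which provably never exceeds
  Dice; since reported benchmark tables sometimes show MIoU above Dice
  (possible only if the background class is averaged in), a two-class mode
  (`two_class_iou()`) is provided as well. Neither mode is claimed to
  reproduce any published table.
* **Second-order mode**: the meta-gradient's Hessian-vector product
  $H_{\mathrm{init}}\,g_{\mathrm{mix}}$ is evaluated by central finite
  differences of the analytic gradient. This is exact for quadratics (the
  validation oracle) and $O(h^2)$ otherwise; no second-order autodiff
  machinery exists in this stack and the approximation is standard for
  first-order meta-learning implementations.
* **Batch norm**: classic 2-conv U-Net blocks with batch normalization and
  bilinear 2x upsampling (the most common form of the cited base
  architecture; the original variant is unstated). Running statistics
  advance only on original-batch forward passes, never on the mixed pass at
  $\hat\theta$, so the $\beta = 0$ reduction stays exact.
* **Schedules and RNG**: the polynomial LR is applied per optimizer step
  over the full horizon. Shuffling and mixing draw from independently
  derived seeds, so disabling the mixed stream does not perturb data order
  — this is what makes the ERM reduction bit-identical rather than merely
  statistically equivalent.
* **Degenerate inputs**: non-finite images are rejected naming the slice;
  single-modality cases contribute to the original stream only (warned
  once); `poly_lr` past the horizon clamps to 0 with a warning; non-finite
  losses abort with epoch/step context.

## What the phantom emulates — and what it does not

The real two-hospital dataset is private, so every pipeline stage is
exercised on a synthetic two-domain phantom. Each case is a layered 2D
anatomy (head ellipse, 2–4 internal structures, one irregular tumour blob
of 1–8% of the head area) rendered into three modalities through
modality-specific intensity transfer curves — qualitatively
structure-bright (m1), fluid-bright (m2) and rim-enhanced tumour (m3) —
then degraded with a smooth multiplicative bias field and Gaussian noise.
Domains A and B differ **only in appearance** (transfer curves, bias
amplitude, noise level, with a guaranteed minimum curve gap); geometry
statistics are identical by construction, because a geometric shift would
confound the domain-generalization readout with a shape-distribution
shift.

A green test on the phantom establishes that the mechanism behaves as
designed under a pure style shift with perfectly co-registered modalities.
It does *not* establish clinical performance: the phantom has no MR
physics, no misregistration between modalities, no slice-to-slice 3D
context, no annotation ambiguity, and a far larger inter-domain gap-to-
noise ratio than real hospitals exhibit.

## Scale profiles and the CPU budget

Two profiles ship: the full-scale recipe (512x512 inputs, base width 64,
depth 4, 5 seeds) mirroring the published implementation, and a desk-scale
profile (96x96, base 16, depth 3, 3 seeds) for CPU work. The training
engine here is pure R + RcppArmadillo; a meta-step at desk scale costs
~1.7 s on one CPU, so the in-suite generalization experiment runs a
further reduced instance — 64x64, base width 8, 24 training + 8 validation
(domain A) and 16 test (domain B) cases, 30 epochs, 3 seeds — chosen from
step-time benchmarks *before* any generalization outcome was measured,
and not revisited. The hyperparameter-stability sweep runs
$\alpha \in \{0.7, 1.0, 1.3\}$ at 12 cases / 10 epochs / 3 seeds; its
stability criterion compares the spread of per-$\alpha$ mean test Dice
against twice the mean per-$\alpha$ seed standard deviation.

## Known limitations

* First-order mode is the default; the second-order term is available but
  finite-difference based, and at network scale its extra cost buys little
  (consistent with wider experience in this model family).
* No 3D/volumetric mixing, no cross-patient mixing, no style-transfer
  baselines (Mixup/StyleMix/MI-SegNet/Dual-Norm are out of scope; only the
  ERM baseline is built in).
* The evaluation split is case-level 80/20; no early stopping or model
  selection on the validation split is performed.
* Checkpoints are R serializations of plain parameter arrays; no
  interchange format with other frameworks is attempted.

## Worked example

```{r}
library(mfnet)

train <- as_modality_images(generate_dataset(24, "A", master_seed = 1,
                                             size = 64)$cases)
test  <- as_modality_images(generate_dataset(16, "B", master_seed = 2,
                                             size = 64)$cases)

cfg <- train_config(epochs = 30, seeds = 1:3)
net <- unet_config(base_channels = 8, depth = 3)

mf  <- train_mfnet(train, cfg, net)
erm <- train_erm(train, train_config(beta = 0, epochs = 30, seeds = 1:3), net)

evaluate_runs(mf, test)$dice_mean
evaluate_runs(erm, test)$dice_mean
```

The same experiment, at exactly this scale, runs inside
`tests/testthat/test-acceptance.R` and prints both numbers.
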
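---
title: "Residual-shifting diffusion for MRI motion correction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-shifting diffusion for MRI motion correction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `rsmoco`, the assumptions
behind it, the tunable parameters and their defaults, what the synthetic
phantom world does and does not emulate, and the design decisions taken
where the published description of this model class leaves the design open.
It states no empirical number that the test suite or the acceptance script
does not itself compute.

## 1. The model and its assumptions

Retrospective motion correction is the inverse problem `y = A(x) + n`:
recover the motion-free magnitude slice `x` from the corrupted slice `y`,
where `A` is the (unknown) motion-corruption operator. A conventional
diffusion model would learn a prior on `x` anchored at pure Gaussian noise
and condition the reverse chain on `y`; that requires many reverse steps
because the chain must bridge the full distance from white noise to
anatomy.

The residual-shifting variant instead builds the forward chain *between*
`x` and `y`. With residual `r = y − x`, shifting sequence
`0 = β₀ < β₁ < … < β_N < 1` and increments `α_t = β_t − β_{t−1}`:

* transition kernel: `q(x_t | x_{t−1}, y) = N(x_{t−1} + α_t r, γ² α_t I)`;
* marginal (by telescoping): `q(x_t | x, y) = N(x + β_t r, γ² β_t I)`.

Because `β_N ≈ 1`, the terminal distribution is `N(y − r(1−β_N), γ²β_N I)
≈ N(y, γ² I)`: the chain ends *at the observation*, and the reverse chain
only has to undo the (comparatively small) artifact, which is why very few
reverse steps suffice. The reverse posterior is available in closed form
(the residual cancels):

```
q(x_{t−1} | x_t, x, y) = N( (β_{t−1}/β_t) x_t + (α_t/β_t) x ,
                            γ² (β_{t−1}/β_t) α_t I )
```

The model replaces `x` in the mean by the denoiser estimate
`x̂₀ = f_θ(x_t, y, t)` and fixes the variance to the posterior variance
(it is input-independent, so learning it buys nothing). At `t = 1`, β₀ = 0
collapses the posterior to a point mass at `x̂₀`: the final sampler update
is deterministic.

Assumptions inherited from this construction: magnitude images normalized
to `[0, 1]`; paired training data (the simulator provides them); rigid,
in-plane, piecewise-constant motion; and a residual whose scale the
schedule's `γ` is tuned to.

## 2. Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_steps` (N) | 4 | steps | The few-step reverse chain is the point of the construction; the same schedule is used for training and sampling (see §5). |
| `gamma` (γ) | 2 | — | Scales all injected noise; with β₁ = (0.04/γ)² it keeps γ√β₁ = 0.04 so the first forward state is almost exactly `x`. |
| `growth_p` (p) | 0.3 | — | Exponent of the geometric growth law; smaller p front-loads the shift (larger interior β_t). Property-tested: β_t is strictly decreasing in p at fixed interior t. |
| `beta1`, `betaN` | (0.04/γ)², 0.999 | — | Endpoints of the shifting sequence; β_N < 1 keeps the terminal variance finite. |
| preset `n_lines` | 15/10/7 | k-space lines | heavy/moderate/minor severity; line accounting is exact by construction. |
| slab widths | 3–7 | lines | Contiguous corrupted readout slabs. |
| rotation / translation bounds | ±7 / ±5 | degrees / mm | Rigid-motion amplitude; draws are uniform within the bounds (§5). |
| `lr_start → lr_min` | 2e-4 → 2e-5 | — | Warm-up then cosine annealing, the reference recipe; the desk-scale acceptance run raises this to 1e-3 → 1e-4 (§5). |
| `data_range` | 1 | — | All metrics assume `[0, 1]`-normalized slices. |

## 3. What the phantom world emulates — and what it does not

`make_phantom()` generates an elliptical "head" with (i) a bright closed
rim just inside the boundary, emulating subcutaneous fat, (ii) a
mid-intensity interior with random internal ellipses emulating soft-tissue
structure, and (iii) smooth Gaussian-filtered texture. The rim exists
specifically so that both artifact classes of interest are visible after
k-space corruption: ringing *inside* the head and ghost replicas of the
bright rim *outside* it, along the phase-encode direction.

What it does not emulate: real T1-weighted contrast and anatomy, partial
volume effects, bias fields, scanner noise statistics (Rician magnitude
noise), through-plane motion, or the long-range correlations of real
brains. Consequently a green learning test establishes that the
simulate→train→sample loop is implemented correctly and can learn to
invert the simulated corruption at desk scale — it does not establish
full-scale restoration quality on clinical data, which requires the real
datasets and GPU-scale training that are out of scope here.

## 4. Numerical choices

* **Schedule endpoints** are pinned exactly after the exp/log round trip,
  so `β₁` and `β_N` are reproduced to machine precision and the audit
  quantity γ√β₁ = 0.04 holds to ≤ 1e-12.
* **FFT convention**: centered spectra, unitary `1/√(HW)` normalization
  (Parseval holds exactly), phase-encode axis = array rows. Reconstruction
  takes the magnitude of the inverse transform, as for magnitude MRI.
* **Rigid resampling** is bilinear with zero fill; rotation about the image
  center precedes translation; mm are converted to pixels via the slice
  spacing (phantom default 1 mm/pixel).
* **Slab drawing** partitions the requested line budget into widths drawn
  uniformly in [3, 7]; when the remainder cannot fit the minimum width the
  final slab is clipped (logged, not raised) so the perturbed-line count is
  always exact. Slabs are disjoint; placement is uniform over the
  phase-encode extent.
* **Loss reduction** is the mean over pixels and batch (not the sum), so
  loss magnitudes are resolution-independent; ℓ₂ and ℓ₁ terms are equally
  weighted, with an ℓ₂-only ablation mode.
* **Sampler** initializes with variance γ²β_N (the operational algorithm)
  rather than the γ² approximation; with β_N = 0.999 the difference is
  negligible. ε = 0 at `t = 1`.
* **Degenerate inputs**: identical images report the documented 100 dB
  PSNR sentinel; NMSE raises on an all-zero reference; pooled Pearson
  returns `NA` when either side is constant; SSIM requires images at least
  as large as its 11×11 window.
* **SSIM** uses the standard Gaussian-weighted local moments (11×11,
  σ = 1.5, K₁ = 0.01, K₂ = 0.03, no sample-covariance correction) over
  valid window positions; it agrees with scikit-image's implementation to
  ≤ 1e-9 on frozen deterministic cases in the test suite.
* **Standard deviations** in reports use the population (n) convention.
* **RNG**: every entry point takes one master seed from which independent
  Mersenne-Twister streams are derived per purpose (data order, time-step
  draws, forward noise, sampler noise, phantom geometry), so runs are
  exactly reproducible and streams do not perturb the caller's RNG.

## 5. Design decisions where the design was open

* **Schedule formula endpoint consistency.** The published growth law is
  stated for interior steps with a prefactor that does not reproduce β₁ at
  t = 1; we use `√β_t = √β₁ exp(…)` for all t = 1..N, which is
  endpoint-consistent and matches the geometric construction this family
  of schedules derives from.
* **One schedule for training and sampling.** The reference description
  trains the forward process with more steps than it samples, without
  stating the mapping between the two. We use a single N = 4 schedule for
  both; N is configurable, and sampling from a model trained at a
  different N is refused rather than silently interpolated.
* **Denoiser topology.** The reference architecture is described only
  schematically (U-net, attention positions replaced by shifted-window
  transformer blocks, inputs `x_t`, `y`, `t`). We condition on `y` by
  channel concatenation, inject `t` as a sinusoidal embedding passed
  through a small MLP and added as a per-channel bias in every residual
  block, and place a regular+shifted window-attention pair at the
  configured levels (default: coarsest). Channel counts, depths and window
  sizes are desk-scale defaults, fully exposed in the configuration; the
  fidelity target is the topology, not a layer-exact replica.
* **Residual output head.** The final convolution is zero-initialized and
  its output added to `y`, so the untrained denoiser predicts `y` — a
  sensible prior that lets short desk-scale runs spend their budget on
  learning the correction instead of the identity.
* **Optimizer.** Rectified Adam with warm-up and cosine annealing, as in
  the reference recipe. The reference learning rate (2e-4, tuned for large
  batches on GPU) is kept as the package default; the desk-scale
  acceptance run uses 1e-3 → 1e-4, which converges far better for a
  ~45k-parameter model at batch 4 — this is the "scaled down by config"
  reading of the recipe.
* **Motion law.** The stated ±7° / ±5 mm bounds are read as uniform draws
  (the bounds are the only testable statement); each slab gets an
  independent motion state (piecewise-constant motion during acquisition),
  which produces richer artifacts than one shared transform. Central
  k-space lines are not excluded from slab placement by default; an
  exclusion radius is exposed as an option.
* **Transformed-copy spectra** are computed by transforming in image space
  and re-running the FFT, not by k-space phase ramps: rotations have no
  exact per-line k-space implementation, and this route keeps the operator
  exact for arbitrary rigid motions.
* **Metrics on whole slices.** No brain mask is applied (the evaluation
  library defaults the reference results are consistent with); Pearson
  correlation is pooled over all pixels of the slice set.
* **Per-volume min–max normalization** to `[0, 1]` at load time; the
  foreground filter drops slices whose fraction of pixels above 0.05 is
  below a configurable threshold (a stand-in for the unstated slice
  selection rule of the reference datasets).
* **NIfTI-1 I/O** is implemented minimally in-package (no R NIfTI reader
  is available in the dependency budget); it is validated against nibabel
  in the test suite and always writes little-endian float32.

## 6. Known limitations

* Pure-R training is desk-scale only: tens of thousands of parameters and
  a few thousand iterations, not the reference model's scale.
* 2-D, single-contrast, rigid in-plane motion only; no through-plane or
  non-rigid motion, no B0/susceptibility effects, no multi-shot
  trajectories.
* The learning acceptance run demonstrates improvement over the corrupted
  input on phantoms, not clinical-grade restoration; like all
  generative-restoration models, the approach can hallucinate structure
  when the input lacks contrast, and no uncertainty quantification is
  provided.
* The NIfTI layer ignores orientation (qform/sform rotations); volumes
  are treated as raw arrays with voxel spacing.
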
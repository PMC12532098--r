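# rsmoco — residual-shifting diffusion correction of MRI motion artifacts

Patient head movement during MRI acquisition corrupts phase-encode lines of
k-space, producing ghosting and ringing artifacts in the reconstructed
magnitude image. `rsmoco` implements retrospective, image-domain motion
artifact correction of 2-D brain MRI slices with a **residual-shifting
denoising diffusion model**, together with the k-space rigid-motion artifact
simulator and synthetic phantoms needed to exercise the complete
simulate → train → sample → evaluate loop at desk scale on one CPU.

It is aimed at researchers in medical image analysis who want a small,
fully testable, pure-R reference implementation of this class of model —
every component, including the trainable U-net denoiser with shifted-window
attention blocks, is implemented in R with hand-written gradients and
validated against independent oracles (finite differences, grid
integration, scikit-image, nibabel).

## The model

Let `x` be the motion-free slice, `y` the motion-corrupted slice and
`r = y − x` their residual. Instead of diffusing `x` to white noise, the
forward Markov chain *shifts* `x` toward `y` under a monotone sequence
`{β_t}` with increments `α_t = β_t − β_{t−1}` (β₀ = 0):

- transition kernel: `q(x_t | x_{t−1}, y) = N(x_{t−1} + α_t r, γ² α_t I)`
- marginal: `q(x_t | x, y) = N(x + β_t r, γ² β_t I)`

With `β_N → 1` the terminal state is centered on the corrupted image, so
the learned reverse chain starts from (a noisy version of) `y` and needs
only `N = 4` steps. The shifting sequence follows a non-uniform geometric
law `√β_t = √β₁ · exp(½ [(t−1)/(N−1)]^p · log(β_N/β₁))` with defaults
`γ = 2`, `β₁ = (0.04/γ)²` (so γ√β₁ = 0.04), `β_N = 0.999`, `p = 0.3`.

The exact reverse posterior is Gaussian with

```
μ_q = (β_{t−1}/β_t) x_t + (α_t/β_t) x,   Σ_q = γ² (β_{t−1}/β_t) α_t I
```

and the model replaces `x` by the denoiser estimate
`x̂₀ = f_θ(x_t, y, t)` (a U-net whose attention positions hold
shifted-window transformer blocks, conditioned on `y` by channel
concatenation and on `t` by a sinusoidal embedding). Training minimizes the
equally weighted `ℓ₂ + ℓ₁` loss between `x̂₀` and `x` (an `ℓ₂`-only
ablation mode is included). Sampling initializes `x_N = y + γ√β_N ε` and
iterates the posterior-mean update with `ε = 0` at the last step.

The motion simulator replaces random disjoint slabs (3–7 lines) of
phase-encode rows of centered k-space with rows from rigidly transformed
copies of the image (rotations within ±7°, translations within ±5 mm per
axis); the named severity presets `minor`/`moderate`/`heavy` perturb
7/10/15 lines.

## Worked example

```r
library(rsmoco)

sch <- build_schedule()
print(sch)
#> Residual-shifting noise schedule
#>   N = 4, gamma = 2, p = 0.3, gamma*sqrt(beta1) = 0.04
#>   beta: 0.000000 0.000400 0.111077 0.407794 0.999000
#>   alpha: 0.000400 0.110677 0.296717 0.591206

img  <- make_phantom(64, seed = 1)                     # brain-like phantom in [0,1]
pair <- corrupt_slice(img, severity_preset("heavy"), rng_seed = 2)
print(pair)
#> Paired sample (64x64), preset 'heavy', 4 slab(s), 15 perturbed line(s)
sprintf("PSNR %.2f dB, SSIM %.3f, NMSE %.2f%%",
        psnr(pair$x, pair$y), ssim(pair$x, pair$y), nmse(pair$x, pair$y))
#> "PSNR 23.04 dB, SSIM 0.723, NMSE 2.45%"
```

`beta` runs from β₀ = 0 through β₁ = 4·10⁻⁴ to β_N = 0.999: the first
forward step barely perturbs `x`, the last lands on `y` up to γ²β_N noise.
The corrupted phantom loses ~27 dB of PSNR relative to a perfect copy
(capped at 100 dB), with ghosting of the bright rim visible outside the
head — the artifact classes the simulator is designed to reproduce.

Training and correction (the configuration used by the acceptance suite;
~4 min on one CPU):

```r
ds  <- build_dataset(220, size = 32, preset = severity_preset("moderate"), seed = 11)
den <- build_denoiser(denoiser_config(base_channels = 12, channel_multipliers = c(1, 2),
                                      time_embed_dim = 16, image_size = 32), rng_seed = 11)
m   <- train_denoiser(ds$pairs[1:200], den, sch,
                      train_config(iterations = 1000, batch_size = 4,
                                   lr_start = 1e-3, lr_min = 1e-4, seed = 11))
xc  <- sample_reverse(ds$pairs[[201]]$y, m, sch, rng_seed = 101)   # 4 denoiser calls
```

On the 20 held-out pairs of that run the mean PSNR rises from 16.85 dB
(corrupted) to 20.40 dB (corrected) and the mean SSIM from 0.708 to 0.779 —
a scaled-down mirror of the full-scale behavior, recomputed by
`tests/testthat/test-acceptance.R` on every run.

The same loop is available from the command line via the `run_cli()`
entry point (or `exec/rsmoco`):

```sh
rsmoco fixtures --n 50 --size 64 --severity heavy --seed 0 --out data/
rsmoco train    --data data/ --out ckpt.rds --seed 0
rsmoco correct  --in data/corrupted.nii.gz --ckpt ckpt.rds --seed 0 --out corrected.nii.gz
rsmoco evaluate --pred corrected.nii.gz --ref data/clean.nii.gz --report metrics.json
```

## Package layout

- `R/schedule.R`, `R/diffusion.R` — noise schedule, forward/reverse
  processes, loss, few-step sampler
- `R/nn.R`, `R/denoiser.R`, `R/train.R` — network primitives with
  hand-written backpropagation, the U-net/Swin denoiser, RAdam training
- `R/kspace.R`, `R/motion.R` — centered FFT pair, rigid transforms,
  slab-replacement artifact simulator
- `R/phantom.R` — brain-like phantom generator and paired datasets
- `R/metrics.R` — PSNR / SSIM / NMSE / pooled Pearson, report aggregation
- `R/nifti.R`, `R/io.R`, `R/config.R`, `R/cli.R` — NIfTI-1 I/O, YAML
  configuration, command-line interface
- `vignettes/residual-shifting-moco.Rmd` — methods notes: model
  assumptions, parameter choices, generator realism, numerical decisions
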
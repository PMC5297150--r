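# mridenoise

Unsupervised denoising of 3D magnitude MRI stacks by maximum a posteriori
(MAP) estimation. The noise model is the low-SNR limit of the Rician
statistics of magnitude MR data — additive Rayleigh noise,
`a = b + n`, `n ~ Rayleigh(σ)` — and the spatial prior is a **local
Gaussian Markov random field** over the 26-voxel 3D neighborhood:

```
E(b, θ) = Σ_k Σ_{q ∈ N_k} (b_k − b_q)² / (2 θ²_{k,q} d²_{k,q})
```

where `d_{k,q}` is the physical distance between voxel centres (so thick
slices smooth less across slices) and the pairwise hyperparameters
`θ²_{k,q} = (θ²_k + θ²_q)/2` are **re-estimated from the running estimate at
every iteration** via `θ²_k = (1/26) Σ_q (b̂_k − b̂_q)²`. Small `θ²` (flat
region) means strong smoothing; large `θ²` (edge or small detail) decouples
the pair. The result is spatially adaptive regularization with **no
user-tuned smoothing parameter**: the only physical input is the noise scale
σ, which can itself be estimated from an air background region.

The MAP objective

```
Σ_k { −log((a_k − b_k)/σ²) + (a_k − b_k)²/(2σ²) } + Σ_{pairs} (b_k − b_q)²/(2 θ²_{k,q} d²_{k,q})
```

is minimized by exact coordinate descent (iterated conditional modes with an
exact convex 1D solve per voxel, vectorized over a checkerboard coloring),
alternating with hyperparameter updates until the mean per-voxel correction
falls below a threshold. Convergence on the reference phantom takes about 6
cycles.

The package is intended for researchers processing magnitude MR volumes
(NIfTI-1 in/out) and for methodological work on adaptive MRF denoising: it
ships a synthetic head phantom and acquisition simulator, masked MSE/SSIM
quality indexes, and a command-line interface.

## Worked example

```r
library(mridenoise)

b   <- generate_head_phantom(phantom_spec(dims = c(64, 64, 15)))  # ground truth
a   <- simulate_acquisition(b, sigma = 4, seed = 11)              # noisy acquisition
fit <- run_map_denoise(a, sigma = 4)
fit
#> <denoise_result> 64 x 64 x 15 voxels, sigma = 4
#>   7 outer iterations, converged: TRUE
#>   final mean correction 7.394e-04, final objective 2.451311e+05

m <- brain_mask(b)
round(c(mse_noisy = masked_mse(a, b, m), mse_denoised = masked_mse(fit$b_hat, b, m)), 3)
#>    mse_noisy mse_denoised
#>       32.241        9.434
L <- diff(range(unclass(b)))
round(c(ssim_noisy    = masked_ssim(b, a, m, data_range = L),
        ssim_denoised = masked_ssim(b, fit$b_hat, m, data_range = L)), 4)
#>    ssim_noisy ssim_denoised
#>        0.8513        0.9274
```

The masked MSE inside the head drops from 32.2 (the Rayleigh second moment
2σ² = 32 at σ = 4) to 9.4, and SSIM rises from 0.85 to 0.93; `fit$theta2`
holds the learned hyperparameter field, which is orders of magnitude larger
at edges than in flat tissue — that contrast is what preserves detail while
flat areas are smoothed hard. If σ is unknown, `run_map_denoise(a)` estimates
it from the volume's corner background patches, or pass
`estimate_sigma(a, mask)` with an explicit air mask.

## Command line

```sh
exec/mridenoise simulate --dims 128 128 27 --sigma 4 --seed 1 -o sim/
exec/mridenoise denoise  -i sim/noisy.nii.gz --sigma 4 -o denoised.nii.gz
exec/mridenoise evaluate --truth sim/truth.nii.gz --test denoised.nii.gz \
                         --mask sim/mask.nii.gz -o report.json
```

Each run writes a JSON provenance/diagnostics sidecar (config, seed, package
version, per-iteration traces). A YAML file mirroring the flags can be
passed with `--config`.

## Documentation

The methods vignette (`vignettes/map-lgmrf-denoising.Rmd`) describes the
model and its assumptions, the pair-counting convention of the prior, the
numerical guards (hyperparameter floor, initialization, boundary handling),
what the synthetic phantom does and does not emulate, and known limitations.
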
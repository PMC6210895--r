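# pssahcs

Prediction-based spatial-spectral adaptive compressive sensing for
hyperspectral image cubes.

Hyperspectral cameras used in plant phenotyping and remote sensing produce
cubes of hundreds of wavelength bands, each a full 2-D image — far more data
than most acquisition and telemetry budgets tolerate. The two redundancies
those cubes carry are spatial (neighbouring pixels are similar) and spectral
(neighbouring bands are near-affine copies of each other, except at noisy
atmospheric-absorption bands). `pssahcs` implements a codec that exploits
both at once, together with the standard evaluation metrics and a synthetic
cube generator so the whole pipeline can be exercised without proprietary
sensor data.

## The algorithm

For a cube *f(x, y, z)* of *a × b* pixels and *c* bands at bit depth *n*:

1. **Adaptive spatial blocking.** The per-band spatial autocorrelation
   η(Δx, Δy, z) = Σ(f − f̄)(f₊Δ − f̄) / Σ(f − f̄)² is averaged over rows,
   columns and a band sample; the block size *M* is the smallest lag whose
   mean correlation falls in [0.9, 0.95].
2. **Adaptive spectral grouping.** Bands are clustered by Lloyd k-means
   under the Euclidean interband distance D(z_i, z_c) = √Σ(f_{z_i} −
   f_{z_c})², with *k* chosen from drops in the adjacent-band spectral
   correlation ζ(z, z+1) below 0.9 (`k = "auto"`), and groups kept
   contiguous in wavelength.
3. **Key-band selection (LMLSD).** In each group, every band is scored by
   its sub-blocks' local means *M* and local standard deviations *D*:
   R = 20·log₁₀(M_mean / D_mean) over the modal interval of the *D*
   histogram. The band with the largest R — the least noisy — becomes the
   group's key band.
4. **Interband prediction.** Each non-key band *g* is modelled from its
   group's key band as f_g = m·f_R + n with the closed-form least-squares
   (m, n). Prediction is closed-loop: the encoder fits against the
   *reconstructed* key band, exactly what the decoder will have, and codes
   only the residual.
5. **Compressive sensing.** Key bands and residuals are sampled per block
   by a seeded Gaussian measurement matrix Φ (regenerated from its seed at
   decode time, never transmitted) against an orthonormal 2-D DCT basis Ψ,
   and recovered by stagewise orthogonal matching pursuit (StOMP) with
   threshold t = 2.5 on the normalized matched filter.
6. **Evaluation.** PSNR = 10·log₁₀((2ⁿ−1)²/MSE) over all voxels, per-band
   PSNR, row/column spatial-correlation curves, and the interspectral
   correlation curve ζ(z, z+1).

The rate knob `bpp` maps to `round(bpp × pixels × n / quant_bits)`
measurements per band, so at the default 12-bit quantizer the rate equals
the sampling fraction: `bpp = 0.25` means 25% of the pixel count in
measurements (3.00 stored bits per pixel).

## Worked example

```r
library(pssahcs)

gen  <- generate_cube(tea_like_spec(seed = 1))   # leaf-like synthetic cube
cube <- gen$cube
cube
#> <hyperspectral_cube> 128 x 256 pixels, 40 bands, 12-bit
#>   wavelengths: 380.0 - 1030.0 nm
#>   DN range: [108, 3841]

cfg <- pssahcs_config(bpp = 0.25, kmeans_seed = 1, matrix_seed = 1)
pkg <- compress(cube, cfg)
pkg
#> <compressed_package> 128x256x40, 12-bit, M = 8, 3 group(s)
#>   rate: 0.2500 (nominal 0.2500), 3.000 bits/pixel stored
pkg$grouping
#> <spectral_grouping> 3 group(s)
#>   group 1: bands 1..13 (13), key band 10
#>   group 2: bands 14..27 (14), key band 24
#>   group 3: bands 28..40 (13), key band 37

recon <- decompress(pkg)
evaluate(cube, recon)
#> <evaluation_report>
#>   PSNR: 28.9114 dB
#>   per-band PSNR: 27.70 - 30.24 dB over 40 bands
#>   showcase bands: 5, 15, 37

psnr(cube, baseline_blocked_cs(cube, cfg)$recon)
#> [1] 28.6617
```

The codec found an 8×8 block size from the cube's spatial autocorrelation,
recovered the three planted spectral groups, picked a clean mid-group band
as each key band (the noisy bands sit at the spectral ends), and at a 25%
sampling rate reconstructs the cube at 28.9 dB — 0.25 dB above a blocked-CS
baseline that codes every band independently at the same realized rate.
`save_package()` / `load_package()` round-trip the result through the
single-file `.pssahcs` container bit-exactly, and
`inst/cli/pssahcs.R` exposes `compress` / `decompress` / `baseline` /
`evaluate` / `simulate` subcommands for shell use.

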
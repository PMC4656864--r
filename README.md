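# elmfit

**Ellipsoid localization microscopy: subdiffraction sizing of fluorescent
shells in widefield micrographs.**

Bacterial spores are wrapped in concentric protein coat layers, many of them
thinner than 50 nm and separated by distances far below the ~250 nm
diffraction limit. `elmfit` determines the radius, axes, orientation and
polar-localization bias of such layers from ordinary widefield fluorescence
micrographs of spores carrying fluorescent fusion proteins — with roughly
10 nm precision — by fitting a physical model of the *whole shell image*
rather than locating intensity peaks. It is aimed at microbiologists and
biophysicists who want layer order and spore-coat geometry from standard
epifluorescence data, without superresolution hardware.

## The model

A thin spherical shell of radius *a*, uniformly fluorescent with emission
*I₀* per unit area, imaged through a spherically symmetric Gaussian PSF of
radius σ, has the closed-form radial image profile

```
f(r) = (a I₀ / r) · [ exp(−(r−a)²/2σ²) − exp(−(r+a)²/2σ²) ],
f(0) = (2 a² I₀ / σ²) · exp(−a²/2σ²)            (removable singularity)
```

where *r* is the distance from the shell centre in the object frame. Fitting
the five parameters (x₀, y₀, a, I₀, σ) to a 27 × 27-pixel region around each
spore pins down *a* far more precisely than the width of the blurred ring
itself. The ring of maximum brightness lies *inward* of *a* by a σ-dependent
offset — `peak_brightness_radius()` quantifies exactly the bias that makes
peak-to-peak diameter measurements disagree between fluorophore colours.

Elongated spores are handled by Monte Carlo image models of a prolate
ellipsoid (semiaxes *a* ≤ *b*, in-plane orientation φ): fluorophores are
placed on the surface either by stretching a uniform sphere sample (dense
poles), uniformly per unit area (rejection sampling with retention
probability p = a·(x²/b⁴ + y²/a⁴ + z²/a⁴)^1/2), or with an explicit polarity
bias q ∈ [−1, 1] (q > 0 enriches the poles). Images are sums of Gaussian
point-source images, and a common-random-numbers iterative random search
fits the parameters. A fitted aspect ratio feeds the thin-walled
pressure-vessel anisotropy γy/γx = 4(b/a)²/(3(b/a)²+1)
(`anisotropy_ratio()`).

The pipeline mirrors laboratory practice: circular-Hough segmentation of
full frames, an anticollision filter against double-counted elongated
spores, background zeroing at the median of below-mean pixels, and a single
quality-control rule — accept a fit only if 0 < σ\_fit ≤ 2 σ\_known — that
proves very effective at discarding overlaps and debris. Per-field averages
over independent fields of view give the method's random error.

## Worked example

Simulate one field of 500 nm spherical shells (10,000 fluorophores each,
1.3 NA oil objective, 74 nm pixels, shot noise, 12-bit camera), then run the
full pipeline:

```r
library(elmfit)

sim <- simulate_calibration_frame(
  simulation_spec(n_shells = 20, n_rows = 260, n_cols = 300, seed = 11))
cfg <- pipeline_config(sigma_known = defocus_psf_sigma(0), seed = 5)
out <- run_pipeline(cfg, list(sim$frame))
#> frame sim-seed11: 84 candidates, 20 after anticollision, 20 accepted
out$experiment
#> experiment summary over 1 fields (20 accepted spores)
#>   radius : 500.4 +/- NA nm (across-field sd)
head(out$table[, c("candidate", "a", "sigma_fit", "epsilon", "accepted")], 3)
#>   candidate        a sigma_fit     epsilon accepted
#> 1         1 499.8636  81.91086 0.007342261     TRUE
#> 2         2 500.4652  82.09813 0.008730714     TRUE
#> 3         3 500.5841  82.28029 0.003718933     TRUE
```

Every one of the twenty 500 nm shells is recovered to within ~1 nm, and the
fitted σ (~82 nm) sits just above the in-focus PSF radius (80.8 nm) because
shell curvature adds out-of-plane blur. The peak-offset analysis runs in
milliseconds:

```r
peak_brightness_radius(600, psf_model(160))  # 553.8 nm -> 550 (nearest 10)
peak_brightness_radius(600, psf_model(130))  # 570.4 nm -> 570
```

so the same 600 nm layer reads ~40 nm wider in diameter through a
sharper-PSF channel — the classic colour-dependent bias of peak-finding,
predicted quantitatively by the model.

A shell-by-shell superresolved visualisation of the fitted structure (not a
raw image) comes from `reconstruct(fits, psf_radius = 25)`.

A command-line front end is installed as `exec/elmfit` with `simulate`,
`run` and `reconstruct` subcommands over the same functions.

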
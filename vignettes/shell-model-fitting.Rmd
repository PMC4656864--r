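---
title: "Model-based sizing of fluorescent shells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based sizing of fluorescent shells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmfit)
```

## The inference problem

A fluorescent fusion protein incorporated into one layer of a bacterial
spore coat forms, to good approximation, a thin spheroidal fluorescent
shell a few hundred nanometres in radius. Its widefield image is a blurred
ring whose geometry encodes the layer radius far more precisely than the
diffraction limit suggests: although the ring is ~300 nm wide, its *shape*
is a one-parameter family in the radius once the PSF is modelled, so a
least-squares fit over a few hundred pixels localises the radius to a few
nanometres — the same statistical leverage that lets single-molecule
localization microscopy beat the diffraction limit, applied to a
parametric object instead of a point.

## Image models

**Spherical shell, closed form.** The PSF is modelled as a spherically
symmetric Gaussian of radius $\sigma$ (object-frame nm). For a thin shell
of radius $a$ and surface brightness $I_0$ centred at $(x_0, y_0)$, the
image intensity at in-plane distance $r$ from the centre is

$$f(r) = \frac{a I_0}{r}\left(e^{-(r-a)^2/2\sigma^2} -
          e^{-(r+a)^2/2\sigma^2}\right),$$

with the removable singularity at the centre filled in by its limit
$f(0) = (2a^2 I_0/\sigma^2)\,e^{-a^2/2\sigma^2}$. We switch to the limit
for $r < 10^{-6} a$; the two branches agree to better than one part in
$10^9$ at the crossover.

An important and easily missed consequence of the *spherically symmetric*
(3D) Gaussian PSF: fluorescence from parts of the shell a height $z$ out of
the focal plane is attenuated by $e^{-z^2/2\sigma^2}$. The plane integral
of $f$ is therefore $2\pi a I_0 \sqrt{2\pi}\sigma\,\mathrm{erf}(a/\sqrt2\sigma)$
— *not* the total shell emission $4\pi a^2 I_0$. `shell_image_flux()`
implements this closed form and the renderer is tested against it; the
Monte Carlo renderer applies the same $e^{-z^2/2\sigma^2}$ weight per
fluorophore, which is what makes the two model routes agree to Monte Carlo
error. A shell of finite thickness is handled by integrating $f$ over the
shell radius (error-function antiderivative, validated against quadrature),
but fitting a thickness is out of scope: thickness and $\sigma$ are nearly
interchangeable in the image unless $\sigma$ is much smaller than the
thickness.

**Ellipsoidal shells, Monte Carlo.** Elongated spores are modelled as
prolate ellipsoids of revolution lying flat in the object plane
($x^2/b^2 + y^2/a^2 + z^2/a^2 = 1$ before rotation by $\varphi$ about the
optical axis). Three fluorophore placements are provided:

* *stretched sphere* — uniform sphere points stretched onto the ellipsoid;
  the anisotropic stretch makes the poles denser per unit area, hence
  relatively bright poles;
* *uniform ellipsoid* — stretched points thinned by the local area scale
  factor $p = a(x^2/b^4 + y^2/a^4 + z^2/a^4)^{1/2}$ (rejection sampling),
  giving constant label density per unit surface;
* *polarized ellipsoid* — the uniform model with acceptance multiplied by
  $C(1 - q\sin t)$, where $\sin t$ rises from 0 at the poles to 1 at the
  equator and $C = 1$ for $q \ge 0$, $(1-q)^{-1}$ for $q < 0$. The polarity
  $q \in [-1, 1]$ interpolates from equatorial ($q<0$) to polar ($q>0$)
  enrichment; $q = 0$ reduces *exactly* (same random numbers, same points)
  to the uniform model.

Rejection sampling resamples until exactly `n_fluorophores` points are
retained, so the total image brightness parameterisation $n I$ does not
drift with $b/a$ or $q$. One open modelling choice was whether to thin a
fixed batch instead; resampling was chosen precisely to keep brightness
orthogonal to shape in the fit.

## Rendering and pixel geometry

All lengths are object-frame nanometres; pixel $(i, j)$ (row-major,
1-based) covers $[(j-1)w, jw] \times [(i-1)w, iw]$ with $w = 74$ nm by
default. Because the pixel width is comparable to $\sigma$, centre-point
evaluation biases fits, so pixel values are footprint means: the radial
closed form is averaged over $3\times3$ sub-pixel samples, while Gaussian
point sources are integrated *exactly* over each pixel (separable erf
differences, in compiled code). The exact separable integral replaces
sub-sampling wherever the kernel is a Gaussian — it is both faster and
unbiased, and matches a 100% fill-factor camera.

## Segmentation and quality control

Frames are segmented by a circular Hough transform on the
gradient-magnitude edge map after a 1-pixel Gaussian smooth, with voting
rings of radius 4–12 px (≈300–900 nm at 74 nm/px, spanning spore coat
radii with margin) and an accumulator threshold of half the frame maximum.
These thresholds favour recall; false positives are tolerated because
quality control removes them. Elongated spores often register as two
circles, so a greedy anticollision filter keeps the stronger response of
any pair closer than 13 px (half a fitting region). None of these values is
physically critical and all are config-exposed.

Each candidate yields a 27 × 27-pixel region. The dark background level is
the median of all pixels darker than the region mean (an exactly constant
region falls back to its minimum — it carries no signal and is rejected
downstream anyway); corrected values are clipped at zero, and the residual
$\varepsilon = \sum_j (I^{data}_j - I^{fit}_j)^2 / \sum_j (I^{data}_j)^2$
is computed on these background-subtracted values — the quantities actually
fitted. Candidates nearer than 13 px to a frame edge are dropped rather
than zero-padded, since padding would bias the fitted $\sigma$.

Quality control is a single rule: accept iff $0 < \sigma_{fit} \le
2\sigma_{known}$. Overlapping spores, fragments and noise all inflate or
destabilise the fitted blur radius, so this one cut is remarkably
effective; the decision boundary is exact at $2\sigma_{known}$.

## Fitting

The spherical closed form is fitted by bounded quasi-Newton least squares
(`nlminb`) over $(x_0, y_0, a, \sigma)$ with the linear parameter $I_0$
profiled out analytically; initialisation comes from the Hough centre and
radius. On noise-free self-rendered inputs the truth is recovered to well
under a nanometre.

The Monte Carlo models are fitted by an iterative random search: a fixed
fluorophore sample (common random numbers — the cloud seed is reused at
every objective evaluation, making the objective deterministic) is rendered
at the candidate parameters, brightness is profiled out, and every
parameter receives a Gaussian perturbation whose scale starts at (5 nm
centre, 20 nm axes, 0.1 rad, 0.1 in $q$, 5 nm in $\sigma$) and decays by
0.9925 per iteration over 600 iterations; moves are accepted only when
they lower the sum of squares. The search is warm-started from the
algebraic sphere fit, with orientation *and* a rough aspect ratio taken
from the intensity second moments — without the aspect warm start the
search can stall in a spherical local optimum on strongly polarized
elongated shells, which is how the 600/0.9925 schedule and the moment
start were arrived at (the shorter 300/0.985 schedule left the polarity
under-converged on some inputs). Axes are canonicalised to $b \ge a$
(swap plus $\varphi \to \varphi + \pi/2$), $q$ is clamped to $[-1, 1]$
(outside which the acceptance probability would leave $[0,1]$), and when
$b/a < 1.05$ the orientation is reported but flagged unreliable, since
$\varphi$ is unidentifiable for a near-sphere. Model choice between sphere
and ellipsoid fits is reported side by side via $\varepsilon$, not
automated: fewer free parameters are preferred when they fit equally well,
and that judgement is left to the analyst.

Summaries are unweighted means over accepted spores per field; the method's
random error is the standard deviation of those per-field means across
independent fields (never across individual spores, whose biological
scatter is an order of magnitude larger).

## The calibration simulator

`simulate_calibration_frame()` generates the validation conditions: frames
of well-separated spherical shells of radius exactly 500 nm, 10,000
fluorophores each, centres in the focal plane, imaged at 500 nm emission
through a 1.3 NA oil objective onto 74 nm pixels, with Poisson shot noise
(30 detected photons per in-focus fluorophore by default — a realistic
budget for a bright fusion protein that keeps 12-bit pixels well below
saturation), 2-count Gaussian read noise, and 12-bit quantisation.

Its PSF extends the analysis model with defocus: a fluorophore at height
$z$ is rendered as a 2D Gaussian of width
$\sigma(z) = \sigma_0\sqrt{1 + (z/z_R)^2}$ (with
$\sigma_0 = 0.21\lambda/\mathrm{NA} \approx 80.8$ nm and
$z_R = n_{imm}\lambda/\mathrm{NA}^2 \approx 448$ nm) whose detected flux
carries the analysis model's own axial envelope $e^{-z^2/2\sigma_0^2}$.
This choice has no free parameters and isolates what the calibration is
meant to test: everything the pipeline does *around* the PSF approximation
— segmentation, background zeroing, pixel integration, shot noise,
quantisation, the optimiser and quality control. It deliberately does
*not* test the Gaussian-PSF approximation against full wave optics: the
axial response of a real widefield objective is not Gaussian, defocused
light in a real instrument spreads into broad skirts whose handling
(partial loss below the background, partial survival as a central haze)
dominates the residual bias of the method, and a simulator faithful to
that physics requires the instrument's measured 3D PSF. This is the main
fidelity gap between the built-in simulator and validation against an
external imaging simulator or a real calibration specimen, and it is the
reason the package's recovered calibration bias (a fraction of a
nanometre; see the acceptance script) is smaller than what a fully
independent simulation would show. The across-field scatter, by contrast,
is faithfully reproduced.

Fixture frames for every placement model are produced by
`generate_test_fixtures()`; all fixtures are generated in code at run time
and written as plain 16-bit TIFFs with CSV manifests.

## Superresolved reconstruction

Fitted parameters can be fed back into the image model with an arbitrarily
small render PSF — by default 25 nm, half a typical fluorescent layer
thickness, on a 10 nm output grid that resolves it. The result visualises
the fitted geometry (layer order, aspect, polarity) and must be read as a
model-based inference under the single-thin-shell assumption, not as data:
fluorescent material away from the fitted layer appears only as a small
rise in $\varepsilon$, never in the reconstruction.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale: three
to five simulated fields of ~50 shells for the calibration experiment,
$10^5$-fluorophore clouds for Monte Carlo/closed-form agreement (relative
RMS below 2%, converging as $n^{-1/2}$), 10,000-fluorophore renders and
600-iteration searches for parameter recovery. Peak finding uses bounded
scalar maximisation on $(0, a)$ with $10^{-3}$ nm tolerance ($f$ is
unimodal there). The model-capacity ordering of residuals
(polarized ≤ uniform ≤ sphere when each search starts from the simpler
optimum) holds up to a small Monte Carlo allowance, because different
placement models cannot share the identical fluorophore sample.

## Known limitations

* Only prolate ellipsoids with the long axis in the object plane; tilted
  or oblate spores violate the model and typically fail quality control.
* A single fluorescent layer per image; two bright concentric layers in
  one colour channel bias the fit.
* Layer thickness is not fitted (thickness–$\sigma$ degeneracy).
* The calibration simulator shares the analysis model's axial response, as
  discussed above; absolute-bias claims transfer to real instruments only
  to the extent that the Gaussian-PSF approximation holds there.
* Hough thresholds and the collision radius are sensible defaults for
  sparse fields of spore-sized objects, not universal constants; dense
  fields need retuning through `pipeline_config()`.
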
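---
title: "Depth reconstruction from single hyperspectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth reconstruction from single hyperspectral images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsdepth)
```

## The problem

A hyperspectral camera records, for every pixel of a scene, a full
reflectance spectrum.  For turbid media — tissue, or the tissue
phantoms used here — those spectra also carry information about the
*third* dimension: an absorbing inclusion (an ink-filled channel, a
blood vessel) buried under a cover layer perturbs the surface
reflectance less the deeper it sits, because diffusely propagating
photons must cross the cover twice and are attenuated at the rate
$\mu_{eff}(\lambda) = \sqrt{3\mu_a(\mu_a+\mu_s')}$.

Two opposing effects shape that perturbation:

* **Absorption**: in bands where the inclusion's fill absorbs, the
  inclusion darkens the surface, and more so the closer it is to the
  surface.
* **Scattering**: where the fill does not absorb, the extra scattering
  contrast (and index mismatch at the channel walls) brightens the
  surface, again more so when the inclusion is shallow.

With a red-transparent absorber the first effect dominates the
blue/green bands and the second dominates the red bands.  In between
there can be a wavelength where the two effects cancel exactly: the
**iso-point**, a band whose reflectance is independent of the
inclusion's cover depth.  A band ratio anchored at the iso-point then
isolates the depth signal:

$$ d_i \;=\; 1 - \frac{I_{\lambda_{abs}}}{I_{\lambda_{iso}}} $$

where $I_\lambda$ is the white-reference-normalized reflectance,
$\lambda_{iso}$ the iso-point and $\lambda_{abs}$ a nearby
absorption-sensitive band (25 nm below the iso-point by default; the
exact choice is not critical).  $d_i$ is zero without an inclusion
(after baseline handling) and varies monotonically with cover depth
while the iso-point holds.

## The forward model (`simulate_cube`)

No public raw data exists for the measured phantom, so the package
ships a forward simulator that reproduces the cancellation mechanism
with *known* ground truth, making every analysis stage testable.  It
is a perturbation model, deliberately the simplest one that realizes
the mechanism with an analytic iso-point:

$$ R(\lambda, x, y) \;=\;
   R_0(\lambda)\,\bigl[\,1 + C(\lambda)\,W(\lambda, d)\,S(u, d)\,\bigr] $$

* $R_0(\lambda)$ — diffuse reflectance of the semi-infinite substrate
  in the diffusion approximation with an extrapolated boundary:
  $R_0 = a' / \bigl(1 + 2k(1-a') + (1+2k/3)\sqrt{3(1-a')}\bigr)$ with
  transport albedo $a' = \mu_s'/(\mu_s'+\mu_a)$ and internal-reflection
  parameter $k = (1+r_d)/(1-r_d)$,
  $r_d = -1.44 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n$ — a standard
  closed form with testable limits ($R_0 \to 1$ lossless, $R_0 \to 0$
  without scattering).
* $C(\lambda) = c_s - c_a\,\epsilon(\lambda)$ — the inclusion's
  spectral contrast: a flat scattering brightening $c_s$ against an
  absorption darkening proportional to the fill extinction.  The
  iso-point is the root of $C$.
* $W(\lambda, d) = e^{-2\mu_{eff}(\lambda) d}$ — the two-pass depth
  kernel; $W(\cdot, 0) = 1$, strictly decreasing in depth.
* $S(u, d)$ — the lateral footprint: a top-hat of the channel's 1 mm
  half-width convolved (in closed form, via error functions) with a
  Gaussian of $\sigma(d) = \sigma_0 + \sigma_1 d$.  This reproduces
  the observation that a buried channel appears much wider than its
  physical 2 mm because scattering blurs it, increasingly so with
  depth.  The exact blur law is a free modelling choice;
  $\sigma_0 = 0.3$ mm, $\sigma_1 = 0.5$ are defaults, not physics.

Raw intensities are $R$ times the illumination spectrum (flat by
default, as for the measured phantom's adjustable LED source),
convolved along the band axis with a Gaussian PSF of 10 nm FWHM (the
camera's effective spectral resolution), with multiplicative Gaussian
detector noise (1% by default — the measured system's noise is small
thanks to a strong source).  The white-reference frame applies the
same acquisition model to a flat 0.99-reflectance standard.

### Scene and default parameters

| Parameter | Default | Why |
|---|---|---|
| scene | 95 × 500 px, 260/43 µm pitch | native scanner geometry (24.7 × 21.5 mm) |
| bands | 407–670 nm, 950 bands (~0.28 nm) | native spectral axis |
| spectral PSF | 10 nm FWHM | effective resolution of the instrument |
| substrate $\mu_s'$ | $1.0\,(\lambda/500\,\mathrm{nm})^{-1.2}$ mm⁻¹ | power law; below-tissue scattering, as for the phantom |
| substrate $\mu_a$ | 0.002 + 0.01 · band(λ) mm⁻¹ | weak background absorption incl. a trace of the same dye |
| refractive index | 1.5 | polyurethane-like |
| absorber band | peak 480 nm, FWHM 100 nm | red-transparent dye ~100 nm wide (see below) |
| peak extinction | 10 mm⁻¹ per unit concentration | sets the 0 / ~1% / 10% fill ladder |
| channel | ⌀ 2 mm, cover depth 0 → 10 mm along the scan axis | diagonal drilling emulated as an affine depth ramp |
| contrast | $c_s = 0.082$, $c_a = 1$ | places the 10%-fill iso-point at 575 nm |
| noise | 1% multiplicative Gaussian | small-noise regime of the instrument |

Two defaults deserve explanation:

**Absorber peak at 480 nm.**  With a symmetric Gaussian extinction
band, a crossing of $C(\lambda)$ on the red side at $\lambda_{peak} +
\delta$ implies a mirror crossing at $\lambda_{peak} - \delta$.  For
the iso-point to be the *only* sign change on 407–670 nm — which is
what a red-transparent ink produces physically, since real ink
extinction stays high throughout the blue — the mirror crossing must
fall below 407 nm, i.e. $\lambda_{peak} < 491$ nm when the iso-point
sits at 575 nm.  The default peak of 480 nm puts the mirror crossing
at 385 nm, safely out of band, while $c_s = 0.082$ tunes the red-side
root to 574.98 nm.  A pleasant consequence: the concentration at which
the contrast just grazes zero (the "boundary" scene) comes out at
0.82%, so the simulator's 0% / ~1% / 10% concentration ladder mirrors
the phantom's fill series.

**Depth ramp along the scan (x) axis.**  Spectra are analysed against
the x position because the inclusion's cover depth ramps along x; the
95-pixel scan axis spans 24.7 mm, giving a 0 → 10 mm ramp at ~0.4
mm/mm.

The ground truth returned with every simulated scene carries the
per-pixel cover depth (sentinel −1 outside the channel; 0 is a
meaningful value for a surface-touching channel, so the boolean mask
is authoritative), the channel mask, the analytic iso-point
wavelength (root of $C$, or none), and the background spectrum.

### What the generator does *not* emulate

Monte-Carlo photon transport (the perturbation model is first-order:
no multiple interactions between inclusion and boundary), keystone and
smile distortions (the analysis assumes a corrected cube),
polarization, shot noise, and camera electronics.  Passing tests on
simulated scenes therefore demonstrate the *internal* consistency of
the pipeline — that each stage recovers what the forward model put in
— not performance on real tissue.

## Preprocessing (`median_filter`, `normalize_reflectance`, `band_average`)

The pipeline order is fixed: 5 × 5 spatial median filter on both the
scene and the white-reference frame, then per-band division by the
reference spectrum, then a 20-band running mean along the spectral
axis.  At the native ~0.28 nm sampling the 20-band window spans about
6 nm, below the 10 nm spectral resolution, so it suppresses noise
without losing spectral information.  Both filters reflect at borders
(edge-duplicating reflection); the phantom boundary is thereby not
biased toward zero, at the price of exact value ties possible in the
outermost two pixel rows/columns.  Bands where the reference falls
below 10⁻⁶ of its own maximum are masked rather than divided.

## Iso-point detection (`depth_sensitivity`, `detect_isopoint`)

The measured study picked 575 nm by inspecting spectra; the package
makes that step algorithmic.  From depth-labelled spectra (pixels
along the channel axis with their ground-truth depths) it fits, per
band, the OLS slope of reflectance versus depth with its standard
error.  The slope spectrum is positive in the absorption-dominated
bands, negative in the scattering-dominated bands, and crosses zero
at the iso-point; the crossing is located by linear interpolation
between the bracketing bands.

A sign change only counts if the slope is *significant* — at least
`tolerance` (default 2) standard errors — somewhere on each flank
with the matching sign.  Without a qualifying sign change the
spectrum is classified:

* **boundary** if the slope dips toward zero: either below the
  2-standard-error tolerance (the noisy grazing case) or below 5% of
  the spectrum's peak |slope| (the near-noise-free grazing case — the
  slope/SE ratio is invariant to rescaling all spectra, so an
  SE-based criterion alone can never fire on clean data);
* **absent** otherwise (e.g. a water-filled channel, whose slope is
  negative at every band).

Several sign changes farther than 20 nm apart raise an ambiguity
error carrying all candidates, rather than silently picking one.

## Depth mapping and calibration

`depth_parameter_map` evaluates $d_i$ per pixel at the bands nearest
the chosen wavelengths (ties toward the longer wavelength) and
subtracts the median over a background region.  With distinct bands
the raw ratio of an inclusion-free pixel is not exactly zero —
$R_0(\lambda_{abs}) \ne R_0(\lambda_{iso})$ — so the baseline
subtraction is what makes "zero without inclusion" hold
operationally; the median is robust to inclusion pixels leaking into
the region.

Against true depth, $d_i$ is approximately linear at shallow depths
(the first-order expansion of the exponential kernel) and decays
exponentially at larger depths, where the iso-point itself degrades.
`segment_regimes` fits this piecewise: a grid search over candidate
breakpoints at the profile's own depth resolution, an OLS line below
and a 3-parameter exponential $A e^{-kd} + c$ above each candidate,
keeping the breakpoint with minimal total SSE (ties to the smaller
breakpoint; degenerate candidates with one empty segment are included
so the piecewise SSE never exceeds either single-model fit).  The
exponential fit is deterministic: offset initialized at the minimum
minus a small margin, log-linear regression for amplitude and rate,
Levenberg–Marquardt refinement with the rate constrained nonnegative.
Exactly-linear profiles short-circuit to the maximal breakpoint with
the exponential segment flagged empty; constant profiles are reported
as degenerate (only amplitude + offset identifiable).

The channel boundaries are where the statistic is least reliable, so
calibration quality is also reported on the central 60% of the
profile (`inner_fraction`, trimming ⌊n(1−f)/2⌋ samples per end along
the channel axis).  `invert_depth` maps $d_i$ back to millimetres by
inverting the linear branch in closed form and the exponential branch
through a logarithm; like $y = x^2$ the mapping is only piecewise
injective, the shallow branch is preferred, and values reachable by
neither branch return `NA` with a warning rather than extrapolating.

## Numerical and design choices

* Wavelength → band mapping: nearest band centre, ties toward the
  longer wavelength.
* Degenerate $R^2$: constant response defines $R^2 = 0$ (SST = SSE);
  otherwise $R^2 = 1 - SSE/SST \in (-\infty, 1]$.
* $I_{iso} \le 0$ pixels are masked to `NA` with a warning, never
  silently dropped.
* The spatial median, spectral running mean and spectral PSF
  convolution are compiled (Rcpp) with long-double accumulation, so
  they match naive R loop implementations to the last bit — the
  equivalence is part of the test suite.  The 20-band window is even;
  the convention is ⌊(w−1)/2⌋ bands below and the remainder above the
  centre band.
* All randomness flows from a single seed per scene; identical
  (specification, seed) pairs give byte-identical cubes and fixture
  files.
* Problem sizes: unit and property tests run on desk-scale scenes
  (48 × 96 px, 2 nm bands — the same physical scene extent and
  mechanism at ~1/350 the voxel count); the acceptance path also runs
  one full-size 95 × 500 × 950 scene through the entire pipeline.

## Known limitations

* The calibration is phantom-specific: slope, breakpoint and rate
  depend on the optical properties; with tissue-like (roughly 3×
  higher) coefficients, usable depths shrink accordingly.
* The method needs a sparse inclusion: overlapping blurred footprints
  of multiple channels would mix depth signals.
* The depth-parameter → depth mapping is surjective across the two
  regimes; without prior knowledge of the regime a single $d_i$ value
  can be ambiguous.
* The detection stage requires depth-labelled spectra (simulator
  ground truth or an external depth measurement along one line); on
  unlabelled data the iso-point must be supplied (`lambda_iso`).
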
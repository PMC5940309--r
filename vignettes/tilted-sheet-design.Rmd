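---
title: "Designing and validating tilted interference light sheets"
author: "tiltsheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating tilted interference light sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltsheet)
```

## The problem

Conventional light-sheet (selective-plane) illumination mounts the
excitation objective orthogonally to the detection objective. That
geometry needs millimetres of clearance around the sample, which rules out
high-NA oil-immersion detection lenses with working distances of a few
hundred micrometres. The alternative implemented here tilts a
cylindrical-lens light sheet by a small angle so that the lower edge of the
converging wedge runs parallel to the coverslip: the sheet forms at the
detection focal plane inside the working distance of any objective, and 3D
acquisition moves the sample through the static sheet. The cost of the
tilt is a coupled design problem — width, usable length and tilt angle
cannot be chosen independently — and this package is the calculator,
simulator and measurement suite for that design problem.

## The design chain

Five quantities describe a design. For a sheet of focal full-width at half
maximum $w$ produced at excitation wavelength $\lambda_{ex}$ by an
effective cylindrical-lens aperture $NA_{\mathrm{eff}}$:

$$w = \frac{\sqrt{2\ln 2}\,\lambda_{ex}}{\pi\, NA_{\mathrm{eff}}},
\qquad L = \frac{\pi w^2}{2\lambda_{ex}},$$

where $L$ is the distance the unmasked Gaussian sheet stays near its focal
width. A quadruple-slit pupil mask elongates this length by making two
cosine waves interfere along the axis; in terms of the inner slit-pair
radius $R_1$ on a lens of focal length $f$, or of the width itself,

$$L' = \frac{\lambda_{ex} f^2}{R_1^2}
     = \frac{\lambda_{ex}}{\tan^2\!\big[\sin^{-1}\!\big(
       \tfrac{\sqrt{2\ln2}\,\lambda_{ex}}{\pi w}\big)\big]},$$

and the tilt half-angle is
$\theta = \sin^{-1}\!\big(\sqrt{2\ln2}\,\lambda_{ex}/(\pi w)\big)$. On the
detection side, $FOV = FN/M$ and $DOF = 1.61\, n_{im}\lambda_{em}/NA^2$.

**Index convention.** The width equation is sometimes written with a
leading medium index $n$. The published design values for this family of
instruments (a 4.3-µm sheet with a 2.4° tilt and 270-µm length; a 2.1-µm
sheet with 5.0° and 63.8 µm) are mutually consistent only when the vacuum
wavelength is paired with the *in-air* convergence angle of the dry
cylindrical lens: refraction into the aqueous chamber compresses the angle
by the same factor by which the in-medium wavelength shrinks, and the two
cancel across a flat interface for paraxial angles. The package therefore
omits $n$ from the width/length/angle chain; $n_{im}$ appears only in the
depth of field. All angles are degrees at interfaces and radians
internally; lengths are µm except lens/mask geometry in mm.

```{r chain}
c(theta43 = tiltAngle(4.3, 0.488),
  lprime43 = elongatedLengthFromWidth(4.3, 0.488),
  lprime21 = elongatedLengthFromWidth(2.1, 0.488),
  theta21 = tiltAngle(2.1, 0.488))
```

## The optimal-width relation

The thinnest sheet is not the best sheet: a thin sheet diverges before it
crosses the field of view, and a tilted sheet additionally sweeps through
depth as it crosses the field. `optimalSheetWidth()` takes the covering
condition — a slab of width $w$, inclined at the angle $\theta(w)$ that the
width itself dictates, must contain the $FOV \times DOF$ field
rectangle —

$$w = F\sin\theta + DOF\cos\theta,\qquad
  F = \frac{FOV^2}{\sqrt{DOF^2 + FOV^2}}$$

($F$ is the chord projection of the field diameter; it differs from $FOV$
by well under 0.1 % for any real lens) and solves it in closed form as a
quadratic in $w^2$ after substituting $\sin\theta$ from the tilt relation.
The closed form was reconstructed from the covering geometry because no
legible printed statement of it was available; it is therefore *gated by
self-checks* rather than trusted: the implementation verifies $w > DOF$ on
every call (the tilt geometry makes the optimal sheet always wider than
the depth of field) and the test suite verifies monotonicity in $FOV$ and
$\lambda_{ex}$ and the short-wavelength limit $w \to DOF$. A violation
raises an error naming a probable transcription fault instead of returning
a number.

```{r optw}
w <- optimalSheetWidth(fov = 150, dof = depthOfField(1.49, 0.515, 1.52),
                       lambdaEx = 0.488)
c(w = w, theta = tiltAngle(w, 0.488))
```

## The diffraction simulator

The cylindrical lens focuses one axis only, so a scalar **1D** paraxial
model suffices (the unfocused breadth axis is carried as metadata, never
computed; at $NA_{\mathrm{eff}} \approx 0.04$ vectorial corrections are
irrelevant). The focal-region field of a plane-wave pupil through the
binary mask $T(y)$ is the quadrature

$$E(x, z) = \int T(y)\,
  e^{-i k x y / f}\, e^{\,i k y^2 z / (2 f^2)}\, dy,$$

a Fraunhofer focus term plus quadratic defocus phase. `propagate()`
evaluates it FFT-free by midpoint rule on per-slit subgrids (the pupil
support is four narrow slits, so direct quadrature is cheap and exact to
quadrature order); grids default to a transverse step at least 16 samples
per finest fringe (bound $\lambda/(8 s_{\max})$ enforced with an error) and
a window of five beat-envelope lobes. Two independent numerical routes
check it: the closed-form two-cosine pattern
$|\cos(k s_1 x) + \cos(k s_2 x)|^2$ for narrow slits, and an FFT-based
`energyAudit()` on a conjugate-matched grid where discrete Parseval holds
exactly, verifying that pupil energy equals the focal-plane transverse
integral (to 1e-6) and is conserved along $z$ (to 1e-4).

**Metric conventions** (the published material names the quantities but
not the estimators, so these are the package's own explicit choices):

* *FWHM at focus* — linear interpolation of the half-maximum crossings of
  $I(x, 0)$ around the central peak.
* *Sheet length* — the contiguous $|z|$ range where on-axis intensity
  stays ≥ 50 % of the focal maximum: the standard depth-of-field
  convention, monotone and easy to assert, chosen because "remains at its
  diffraction-limited width" has no printed threshold.
* *Center sheet* — the region between the first minima of the slow beat
  envelope flanking $x = 0$ (narrow-slit closed form
  $x_0 = \lambda f / (2 (R_2 - R_1))$, refined to the nearest actual
  profile minimum); the coplanar side sheets are everything beyond. The
  central energy fraction divides the focal-plane integral over the center
  sheet by the integral over the full simulated window.

## Mask calibration

The physical slit radii and widths of the reference instrument are not
tabulated anywhere, so the default mask is *calibrated, not hard-coded*:
`calibrateMask()` minimises the squared relative error of the simulated
(FWHM, sheet length) against the targets subject to a central energy
fraction ≥ 0.80, by Nelder–Mead polishing of a fixed list of starting
geometries (the narrow-slit seed $R_1 = f\sqrt{\lambda/L'}$ with mean slit
sine $\lambda/(4w)$, plus scaled variants of a wide-inner-slit regime).
There is no randomness: identical calls return identical masks. The FWHM
term is weighted 10× the length term because the feasible set is narrow in
width — with two interfering pairs the attainable (FWHM, length)
combinations at 80 % center energy form a one-parameter trade-off, and the
width is the tighter published constraint (5 % vs 10 %).

```{r mask}
mask <- defaultMask()   # (4.3 um, 270 um) on the 40-mm lens at 488 nm
mask
measureSheet(propagate(mask, 0.488))
```

The calibrated optimum puts the *wide* slit pair inside and the narrow
pair outside; the wide inner slits supply the smooth envelope that confines
energy to the center sheet while the narrow outer pair sets the fast
fringe that fixes the width.

## Image quantification

* **Bead PSFs** (`fitBead`) — per-axis 1D Gaussian fits (not a joint 3D
  fit), mirroring the per-dimension trace-fitting procedure used for bead
  stacks, with profiles taken through the intensity-weighted centroid over
  a 3-pixel averaging band. The model is the *pixel-integrated* Gaussian
  (error-function difference over each pixel): a point-sampled model
  inflates $\sigma^2$ by $\Delta^2/12$, which at 0.1-µm pixels on a
  0.09-µm-σ bead is a 5 % bias — larger than the 2 % recovery tolerance the
  tests enforce. FWHM $= 2\sqrt{2\ln2}\,\sigma$ everywhere. Depth is
  measured from the lowest acquired plane, declared as the coverslip proxy.
* **SBR** (`sbr`) — mean(signal)/mean(background) over explicit disjoint
  masks; a uniform image scores exactly 1.0, the floor. Since the
  reference procedure leaves ROI geometry unstated, `defaultRoiMasks()`
  ships a reproducible default (Otsu nucleus mask on the first frame,
  3-px dilated annulus background).
* **Bleaching** (`bleachTrace`) — per time point: z-maximum projection,
  raw integrated density = ROI sum − area × background mean. Camera offset
  and local background are two separate, logged steps. Cumulative frame
  counts include *every z-plane exposure* (41 per time point for the
  0.5-µm/20-µm reference protocol), not time points.
  `framesToFraction()` applies a first-crossing rule with no smoothing (an
  unstated filter would be an invented parameter); never-crossing traces
  return the total with a censoring flag.
* **Kymographs** (`kymograph`) — unit-pixel samples along a polyline,
  maximum over a perpendicular band, rows = time.

## Synthetic data: what it emulates and what it does not

Generators are pure functions of (spec, seed). Beads are 3D Gaussians
analytically integrated over voxels; nuclei are uniform ellipsoids.
Detection applies Poisson shot noise, Gaussian read noise and a recorded
constant offset. Bleaching is first-order in local excitation dose
(single species, no dark-state recovery), emulating an ATP-arrested
sample; a linear fluorophore-production term exists to explore turnover
compensation and is off by default (it is speculative, not a fitted
model). Epi illumination deposits uniform dose over the whole z-extent
each exposure; sheet illumination deposits a Gaussian z-profile of the
sheet's FWHM centred on the acquired plane, optionally sheared by the tilt
angle, and both modes are scaled to equal initial in-focus integrated
density so bleaching comparisons start from matched images. The
epi-to-sheet dose ratio is then approximately (z-extent)/(1.0645 · w) —
about 4.5 for the default 4.3-µm sheet over 20 µm — and the measured rate
ratio tracks it within 10 %.

Deliberately **not** modelled: detection-PSF blur during movie synthesis
(beyond per-plane slab selection), refraction through the tilted chamber
wall, Gaussian incident beam profiles (the pupil is a plane wave),
scattering and autofluorescence structure, nuclear motion, and any
phototoxicity biology. Passing recovery tests therefore demonstrates that
the *estimators* are calibrated on data satisfying their assumptions, not
that real samples satisfy them — notably, real sheets behave thinner in
cells than their measured FWHM suggests, an effect with no quantitative
model and hence no implementation here.

## Problem sizes and numerical choices

The test and acceptance workloads run at desk scale by design: 12-bead
stacks (96×96×41 voxels) at peak SNR 20 matching the n = 12 reference
measurement, 25–40-time-point 48×48×41 movies, 1 000–2 000-point
transverse profiles for simulator checks, and a 1 000-point random sweep
for the optimal-width property. Mask calibration evaluates a few hundred
fast profile metrics (~10 s). Fit non-convergence raises errors with the
residual report rather than returning garbage; degenerate inputs (uniform
profiles, empty masks, zero-length lines, missing sidecars) raise errors
naming the failed precondition. Reported design numbers follow the
2-significant-figure convention of the reference values; returned objects
keep full precision.

## Known limitations

* The optimal-width closed form is a geometric reconstruction gated by
  self-checks; an authoritative tabulated form could differ in the chord
  projection factor (the numerical difference is far below measurement
  relevance, but the provenance is the covering geometry, not a
  transcription).
* The simulator is scalar, 1D and paraxial; it is not meant for
  $NA_{\mathrm{eff}} > 0.2$ and refuses slit geometries beyond $f/4$.
* Experimentally measured sheet lengths can exceed the theoretical value
  (296 µm has been observed against a 270-µm design); the package makes no
  attempt to model that discrepancy.
* The unfocused breadth $b$ of the sheet is carried as metadata only.
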
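---
title: "Models and methods behind sheetloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sheetloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sheetloc)
```

sheetloc implements the analysis chain of a Bessel-beam light-sheet
localization microscope: a thin, tilted illumination sheet excites
spontaneously blinking fluorophores, an astigmatic detection path encodes
each emitter's distance from the sheet in the ellipticity of its image, and
the pipeline turns camera stacks into drift-corrected, deskewed 3D
localization tables, density renderings, resolution estimates and averaged
nuclear-pore reconstructions. This vignette explains the models, the
parameters that matter, and the design decisions taken where the underlying
methods admit more than one reasonable choice.

## Optical sectioning by an annular pupil

The excitation beam is shaped by an annulus between numerical apertures
`na_inner` and `na_outer` (defaults 0.42 and 0.50 at 637 nm). sheetloc uses
the scalar diffraction integral for a uniformly filled annulus,

$$E(r) = \int_{NA_{in}}^{NA_{out}} J_0\!\left(\tfrac{2\pi}{\lambda} \, NA \, r\right) NA \, dNA,
\qquad I(r) = |E(r)|^2 / |E(0)|^2,$$

evaluated by the trapezoid rule with 401 pupil samples (the computed FWHM is
stable to well under 1 nm on refinement). For the default annulus the
central-lobe full width at half maximum is 494.8 nm, i.e. 0.5 µm — this is
the optical-sectioning thickness of the virtual sheet. A scalar
(non-vectorial) model is adequate at NA 0.5 for a width calculator; it
deliberately does not model the annulus mask's power throughput or the
actual pupil apodization of a real system, where the back aperture is
underfilled in ways no published formula captures. The sheet (propagation)
length is a configuration input, not computed, for the same reason.

## The synthetic acquisition

Because no public raw data accompany this instrument class, the package
ships a first-class simulator whose defaults are the instrument's operating
point: 102 nm camera pixels, a 32.5° sheet–coverslip angle, 20 ms exposure,
a 500 nm sheet FWHM, and an sCMOS noise model
`round(gain * Poisson(qe*photons + background) + Normal(0, read_noise) + offset)`.
Photon budgets are quoted as *detected* photons, so the camera's quantum
efficiency defaults to 1; this keeps photon bookkeeping exact (with noise
off, `sum(image - offset)/gain` equals the emitted photons) while `qe`
remains available for users who prefer incident-photon units.

Blinking is a two-state chain (plus an absorbing bleached state)
discretized at frame resolution with per-frame switching probabilities
$1 - e^{-k\,\Delta t}$. Sub-frame partial on-times are ignored, which is
faithful only when on-times span several frames; the defaults therefore
describe a slow spontaneous blinker (mean on-time 400 ms against 20 ms
frames, duty cycle $5\times10^{-3}$, 1000 photons per on-frame). Under
these defaults a labeling density of 340 fluorophores/µm² registers
≈ 1.7 events µm⁻² frame⁻¹, the densely-labeled operating point of the
instrument. Excitation weight follows a Gaussian sheet profile of the
optical FWHM; optional side-lobe replicas at ±850 nm (the first side-lobe
position of the default annulus) with a configurable relative intensity
let tests exercise the width-gate rejection rationale. The full Bessel
radial profile is available from the optics module but is not the default,
for speed.

The simulator does not model dipole orientation, depth-dependent
aberrations, structured autofluorescence, or non-rigid sample motion.
Passing tests on these simulations therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
artifact of real specimens.

## Astigmatic axial encoding

A cylindrical lens displaces the x and y focal planes, so PSF widths follow
per-axis defocus curves. sheetloc fits the standard quartic-corrected
hyperbola

$$\sigma_i(z) = \sigma_{0,i}\sqrt{1 + u^2 + A_i u^3 + B_i u^4},
\qquad u = (z - c_i)/d_i,$$

to bead z-stacks (40 nm steps are the usual convention) by
Levenberg–Marquardt. The exact functional form used by any given
instrument's own software is rarely published; this one is the common
choice in astigmatic localization tools and is explicitly substitutable.
Inversion minimizes the width-space distance
$D(z) = (\sqrt{\sigma_x}-\sqrt{\sigma_x^{cal}(z)})^2 +
(\sqrt{\sigma_y}-\sqrt{\sigma_y^{cal}(z)})^2$ on a 1 nm grid with parabolic
refinement; ties break toward smaller $|z|$. Events whose best $D$ exceeds
a threshold (default 2) are flagged invalid — this is the mechanism that
rejects out-of-focus and side-lobe-excited events, whose widths match no
in-range calibration value.

The reference calibration used throughout the test-suite simulations has
$\sigma_0$ = 130 nm, focal offsets ±200 nm and depth scales of 250 nm — a
fairly strong cylindrical lens, chosen so axial errors stay within about
2.5× the lateral error over a ±300 nm working range, which is the level of
axial performance this instrument class is designed for.

## Detection, fitting and uncertainties

Per-frame detection is a difference-of-Gaussians band-pass followed by
8-neighborhood maxima above `threshold_k` × a robust noise scale
(1.4826 × MAD of the band-passed frame); candidates closer than the ROI
half-width keep only the brighter one. Fitting is an axis-aligned,
pixel-integrated elliptical Gaussian plus constant background (the
cylindrical-lens axes coincide with the camera axes, so no rotation term),
solved by Levenberg–Marquardt and then refined by iteratively reweighted
least squares with weights from the model's shot-plus-read-noise variance —
for Poisson-dominated data this approaches maximum-likelihood efficiency
without a dedicated MLE solver. Degenerate fits are flagged, never raised.

The per-event lateral uncertainty uses the Thompson–Larson–Webb form

$$\sigma_{loc}^2 = \frac{\sigma^2}{N} + \frac{a^2}{12N}
 + \frac{8\pi\sigma^4 b^2}{a^2 N^2}$$

with $\sigma$ the fitted width (geometric mean of the axes), $a$ the pixel
size, $N$ the photon count and $b$ the fitted background; Mortensen's
formula is available behind a switch. The axial uncertainty propagates a
width error of $\sigma_i/\sqrt{N}$ through the calibration slopes
$d\sigma_i/dz$ at the assigned z.

## Drift correction and deskew

Fiducial tracking links each always-on bead through time by
nearest-neighbor association, averages per-bead displacements (relative to
each bead's own mean) across beads, interpolates gaps and smooths with a
50-frame centered moving average. Automatic bead proposal pools a
`link_radius` histogram over 3×3 neighborhoods and keeps positions carrying
events in ≥ 80% of frames; explicit seed positions override it, and are
recommended when the field contains dense structure. The per-axis standard
deviation of the corrected bead tracks is reported as the achieved
localization precision — the same statistic an instrument reports when it
quotes its "actual" precision from a fiducial. The cross-correlation
alternative renders block-wise 2D histograms and phase-correlates each
block against the first with 3-point parabolic sub-pixel refinement.
Between nodes, both traces are linearly interpolated (per-volume constant
correction was the other defensible reading; interpolation was chosen
because it degrades gracefully as block length grows).

Deskew maps in-sheet coordinates $(u, v)$, the astigmatic sheet-normal
offset $w$ and the plane index $p$ into coverslip coordinates:

$$X = p s + u\cos\theta - w\sin\theta,\quad Y = v,\quad
  Z = u\sin\theta + w\cos\theta,$$

an isometry within each plane (tested to $10^{-9}$ relative). All
coordinates are nm; plane and frame indices are 0-based; the origin is the
plane-0 sheet intersection with the scan axis. The scan step that yields a
0.17 µm reconstructed z-interval is not uniquely determined by the printed
numbers; 0.17 µm / sin 32.5° ≈ 316 nm is used as the default and is an
ordinary configuration value, not a constraint.

## Rendering

2D density maps draw each event as a unit-integral symmetric Gaussian whose
σ is the event's own theoretical uncertainty (or a fixed value); kernels
are truncated at 5.5σ so interior events conserve their unit weight to
better than $10^{-6}$, and border-clipped kernels are deliberately not
renormalized. 3D volumes are voxel histograms smoothed with a separable
Gaussian kernel of unit sum. Temporal color coding assigns events to bins
of `frames_per_bin` frames (2000 frames = 40 s at 20 ms exposure is the
live-imaging segmentation the instrument uses) and composes per-bin maps
with one color per bin; the per-bin maps sum exactly to the full map.

## Fourier ring correlation

Resolution is estimated by randomly halving the events (not odd/even
frames: frame-based splits put consecutive re-blinks of one molecule in
opposite halves less often, biasing FRC pessimistic, while any split of
same-molecule re-blinks across halves biases it optimistic — the random
split plus this documented caveat is the standard compromise), rendering
both halves as 10 nm histograms (no smoothing — smoothing inflates FRC),
and correlating Fourier rings:

$$FRC(q) = \frac{\mathrm{Re}\sum_{|f|\in q} F_1 \bar F_2}
 {\sqrt{\sum_{|f|\in q} |F_1|^2 \sum_{|f|\in q} |F_2|^2}}.$$

Curves average over 5 splits. The resolution is $1/q^\*$ at the first
downward crossing of the fixed 1/7 threshold (config-overridable; the
instrument's own criterion is unpublished), linearly interpolated between
rings; a curve that never crosses reports the Nyquist bound
2 × render pixel with a flag. The accumulation analysis pools the first k
volumes for growing k; on synthetic filament data the median resolution is
non-increasing and saturating in k, which is the qualitative behavior the
instrument reports (its printed 107 nm → 75 nm values are bound to its own
raw data and are not reproduction targets). FRC here operates on the 2D
projection of the pooled table; per-slab 3D analysis is out of scope.

## Nuclear-pore particle averaging

The candidate recipe is deliberately literal: bin events at 10 nm, mask
pixels carrying events, fill holes morphologically, dilate by a 3×3 square,
label 8-connected components (connectivity is unstated in the field's
descriptions; 8 is chosen and config-exposed), keep components whose
*dilated* area lies in [250, 300] px² inclusive (dilation-then-filter is
the literal reading of the published operation order), compute centroids,
and crop 32×32 px windows `[c-16, c+16)`; edge-clipped candidates are
dropped. Each candidate's center is the probability-weighted centroid of a
bivariate Gaussian KDE of its raw events on a 2 nm lattice with per-axis
Silverman bandwidths (the KDE-versus-mixture ambiguity in published
descriptions is resolved as plain KDE). Candidates are ranked by donut-fit
RSS normalized by crop energy — so bright and dim pores compete fairly —
and the top 50 are shifted (bilinear interpolation) to align their KDE
centers and summed.

The ring ("donut") model fitted to crops and to the overlay is

$$I(x,y) = A\,S(r;\,r_0,\sigma_r) + c,\qquad r = \|(x,y)-\text{center}\|,$$

multi-started over $r_0 \in \{30, 50, 70\}$ nm. For $S$, the default is the
**blurred ring**: an ideal circle of radius $r_0$ convolved with an
isotropic Gaussian of width $\sigma_r$,

$$S(r) = \exp\!\left(-\frac{r^2+r_0^2}{2\sigma_r^2}\right)
 I_0\!\left(\frac{r\,r_0}{\sigma_r^2}\right),$$

evaluated through an exponentially scaled $I_0$ (rational polynomial
approximation, absolute error ~ $10^{-7}$, an order of magnitude faster
than the library Bessel call inside iterative fits). This form is the exact
expected event density for ring-arranged binding sites observed at
localization precision $\sigma_r$, and that exactness matters: when the
localization spread is comparable to the ring radius (40 nm precision on a
50 nm radius), the blur fills the ring in, the image shows a central
maximum, and the naive Gaussian-in-radius ring (available as
`profile = "gaussian_ring"`) underestimates a 100 nm pore as ~37 nm. The
blurred-ring fit recovers both 100 nm and 120 nm generator truths to
within a few nm at 20 and 40 nm precision, and the diameter estimate is
`2 * r0` of the overlay fit. The averaging pipeline carries no anchor at
100 nm — a 120 nm generator truth comes back as 120 nm.

Eight-fold symmetry analysis, template-free 3D averaging and pore
classification are out of scope.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the caller's
RNG state; identical seeds give bit-identical stacks, tables and renders.
The test suite runs its statistical checks at deliberately desk-sized
problems — 50–100 Monte-Carlo localization draws per photon level, 20
accumulation volumes, 100-pore fields over 5 seeds — chosen so the full
suite completes in minutes while leaving comfortable statistical margin at
the asserted tolerances. The 1/√N precision-scaling check runs with the
PSF symmetric at the sheet plane and near-zero background, the standard
condition for benchmarking photon-limited precision; the 1.3×-of-theory
bound is checked separately under realistic background.

## Known limitations

- Single-emitter fitting only: overlapping emitters are merged or rejected,
  so performance degrades above roughly 1–2 registered events µm⁻²
  frame⁻¹ — consistent with the densely-labeled regime the instrument
  targets, but not beyond it.
- The defocus model form and the width-space inversion metric are
  conventions, not measurements; both are config-exposed.
- Drift is rigid per frame; non-rigid sample deformation is not modeled or
  corrected.
- FRC on random event halves can be optimistic when single molecules
  re-blink across halves.
- The simulator's camera is spatially uniform; per-pixel sCMOS gain/noise
  maps are not modeled.
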
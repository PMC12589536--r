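---
title: "From scattered-light stacks to fiber orientations, muFODs, and an artificial diffusion dataset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scattered-light stacks to fiber orientations, muFODs, and an artificial diffusion dataset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comsli)
```

## The measurement model

Computational scattered light imaging (ComSLI) illuminates an unstained or
stained histological section obliquely while rotating the light source in
azimuth, recording one image per azimuth. Light scatters predominantly
perpendicular to fiber axes, so a pixel containing an in-plane fiber
population at orientation $\theta$ shows a *pair* of intensity peaks in
its azimuthal profile $I(\phi)$, centered near $\theta + 90°$ and
$\theta - 90°$. The circular midpoint of a peak pair, reduced modulo
$180°$, is the fiber orientation; a profile with one peak pair carries one
fiber population, two pairs (4 peaks) two populations, and three pairs
(6 peaks) three — the most that can be resolved robustly in a
micrometer-scale pixel. Orientations are axial (fibers have no
direction), so every orientation lives in $[0°, 180°)$ and all circular
statistics in the package use the doubled-angle embedding or the
half-circle metric $d(a,b) = \min(|a-b|,\, 180 - |a-b|)$.

The package covers the full computational chain:

1. **Calibration** (`normalize_diffuser`, `flat_field_correct`): a
   ground-glass diffuser stack, blurred with a wide Gaussian (default
   $\sigma = 100$ px, reflect padding) and normalized by the mean of its
   per-angle maxima, becomes the per-angle flat-field divisor.
2. **Profile analysis** (`analyze_stack`): per pixel — Fourier low-pass
   filter, circular peak detection with prominences, $180°$ pairing,
   midline orientations.
3. **Products** (`render_fom`, `vector_overlay`, `crossing_fraction`,
   `apparent_crossing_map`): color-wheel maps, vector overlays,
   multi-resolution crossing statistics.
4. **muFODs** (`compute_mufod`, `spline_mufod`,
   `orientation_difference`): polar histograms of orientations over
   kernels or ROIs, their spline representation, and difference maps
   between co-registered fields.
5. **Diffusion bridge** (`build_gradient_table`, `synthesize_dwi`,
   `export_dwi`): an artificial 63-volume diffusion-MRI dataset that
   standard spherical-deconvolution tractography tools can consume.
6. **Phantom** (`generate_phantom`, `generate_diffuser`): synthetic
   stacks with known fiber fields for end-to-end validation.

## Flat-field correction

The diffuser captures the illumination unevenness of each azimuth. The
"homogenizing" blur is parameterized by its Gaussian standard deviation
(`blur_sigma_px`, default 100 px): a defect a few pixels wide must be
spread over a region much larger than itself, and the standard deviation
is the conventional way to size such a kernel. Boundaries are handled by
mirror reflection, which keeps the illumination estimate unbiased for any
illumination field that is locally linear — exactly in the interior
(beyond $3\sigma$ from the edge), approximately at the edge. Division
uses the blurred pages normalized by the *mean of the per-angle maxima*,
so the brightest spot has divisor $\approx 1$ on average and correction
preserves the global intensity scale. Divisors below $10^{-6}$ of the
field maximum are masked rather than divided: dividing by sensor-black
values would amplify noise without limit.

Because peak detection is invariant under any positive scaling of a
profile, correction by a smooth multiplicative illumination gradient
restores the *peak positions* of the gradient-free measurement exactly
(to numerical precision) wherever the blurred illumination estimate is
exact — the package's tests assert this at $10^{-6}$ degrees on interior
pixels of a gradient-lit phantom.

## Per-pixel profile analysis

**Filtering.** Profiles sampled at $10°$ steps are low-pass filtered
(cutoff $0.4$ of the Nyquist index, raised-cosine roll-off of relative
width $0.225$); $15°$-step measurements are analyzed unfiltered. The
`filter_mode = "auto"` default applies the filter only to samplings finer
than $15°$. The DC bin is never attenuated, so profile means are
preserved exactly.

**Peak detection.** Local maxima are found on the circular domain and
kept when their circular topographic prominence reaches
`prominence_fraction` (default 8%) of the profile range — a threshold the
measurement itself does not dictate, so it is exposed in the
configuration; 8% rejects noise ripple at SNR $\gtrsim 10$ while keeping minority
populations with amplitude fractions down to $\sim 0.1$. Positions are
refined to sub-sample precision as the midpoint of the two linearly
interpolated crossings of the half-prominence level — exact for
symmetric lobes and model-free. The crossing search never leaves the
peak's own lobe: it stops at the bounding local minima, since otherwise a
tall neighboring peak can hold the profile above the half level and drag
the estimate far sideways.

**Pairing.** Admissible pairs have circular separations within
$180° \pm 35°$; the tolerance accommodates the peak shifts of inclined
fibers while rejecting spurious matches. Pairs are selected greedily —
ranked by summed prominence, then by closeness of the separation to
$180°$, then by position — with each peak used once and at most three
pairs kept. The antipodality key matters: with equal-amplitude crossing
fibers, all peaks tie in prominence and peaks from *different*
populations can sit $150°$ apart (inside the tolerance); preferring the
most antipodal candidate resolves the tie toward the true pairs. The
greedy result is verified against an exhaustive enumeration over all
conflict-free pairings in the test suite.

**Resolvability.** Two scattering lobes of width $\sigma$ merge into one
peak when their separation falls below $\approx 2\sigma$, and their
positions bias each other noticeably below $\approx 4\sigma$ — compounded
by the $15°$ sampling. Population counts are therefore exact only for
orientation separations $\gtrsim 4\sigma$: with the default phantom lobe
width of $15°$ that means separations above $\sim 55°$; the package's
recovery tests of the $30°$-separation regime use $\sigma = 10°$
phantoms, for which $4\sigma = 40°$ marginally and counts are correct in
$> 99\%$ of random configurations with orientation errors below one
half-step ($7.5°$).

**Masking.** Pixels with zero mean signal are always masked;
`background_quantile` optionally masks the dimmest quantile of the
average-scattering map. Whether background masking should precede
orientation extraction depends on the acquisition, so quantile masking
defaults to off.

**Conventions.** $\theta$ is measured counterclockwise from the image
$+x$ (column) axis with the origin top-left, reported in $[0°, 180°)$;
reversing the azimuth direction of the stack maps $\theta \mapsto
(180° - \theta) \bmod 180°$, and rotating the scene by a sampling step
shifts every orientation by that step — both are asserted as properties.

## Crossing statistics at multiple resolutions

`crossing_fraction` tiles the field with non-overlapping kernels anchored
at pixel (1,1); a trailing partial kernel is kept when at least half its
extent lies inside the image. A kernel's value is the *maximum*
population count over its unmasked pixels — a $7\times7$ kernel of
$7\,\mu m$ pixels ($\approx 50 \times 50\,\mu m^2$) counts as a crossing
kernel if any microscopic pixel inside it crosses. Since a maximum over
a union cannot fall below the maxima of its parts, the crossing fraction
is non-decreasing over nested tilings, mirroring the growth of crossing
fractions from microscopic to millimeter resolutions.

`apparent_crossing_map` emulates a coarser detector: it block-averages
the *raw intensities* (not orientations) and reruns the analysis.
Averaged profiles of adjacent single-fiber domains superpose their peak
pairs, so merged pixels can report crossings that no microscopic pixel
contains — the apparent-crossing phenomenon. On phantoms whose domain
seams contain genuine two-population pixels, apparent crossings after
downsampling never exceed the kernel-based count at matched resolution
(information is only lost); on crossing-free interleaved domains the
apparent count exceeds the kernel-based count by construction, which is
precisely why the two statistics are kept distinct.

## muFODs

All orientations of all unmasked pixels in a kernel or ROI are pooled
into a polar histogram of 20 bins of $9°$ covering $[0°, 180°)$
(half-open bins; the axial domain is mirrored to $[180°, 360°)$ for
display). Counts are conserved: the muFODs of a partition's cells sum to
the whole-region muFOD, at every kernel size. For a continuous
representation, an interpolating periodic cubic spline is fitted through
the 20 bin mid-points ($4.5° + 9°k$) duplicated over the full circle;
because the knot data repeat with period $180°$ and the periodic cubic
interpolant is unique, the spline inherits the mirror symmetry
$f(\phi) = f(\phi + 180°)$ automatically. An interpolating (rather than
smoothing) spline is the documented default since the histogram counts
are exact data, not noisy estimates.

Orientation-difference maps between co-registered fields compare dominant
(most prominent) populations with the half-circle metric by default; a
`"matched"` mode instead averages, over the first field's populations,
the distance to the nearest population of the second — both are exposed
because multi-population comparison is not otherwise pinned down. The
difference histogram uses $0.3°$ bins; its spread is summarized by the
median and by the full width at half the modal height, interpolated
linearly between bin centers, without assuming any parametric peak shape.

## The artificial diffusion-MRI dataset

To hand the orientations to mature tractography stacks, the muFODs are
recoded as a 63-volume diffusion experiment: 3 unweighted volumes
($b = 0\ \mathrm{ms}/\mu m^2$, signal 1) and 60 volumes at
$b = 1\ \mathrm{ms}/\mu m^2$ in three 20-direction sets sharing the muFOD
bin azimuths:

* **in-plane** — for bin $k$ with count $n_k$, $S = e^{-n_k/10}$: more
  fibers along a direction, more attenuation along it;
* **perpendicular** — $S = 1$: no axons leave the section plane, forcing
  reconstructed orientations in-plane;
* **tilted** ($20°$ toward the normal) — $S = 1 - (1 - S_0)/5$, so the
  signal loss $20°$ off the in-plane axis is exactly 20% of the loss
  along it, emulating a sharp fiber response with fast off-axis falloff.

All signals lie in $(0, 1]$, in-plane signals decrease strictly with
$n_k$, and rotating every orientation by one bin permutes the in-plane
set cyclically. The attenuation scale (10) and the muFOD kernel feeding
$n$ (default 1 px, i.e., the pixel's own populations) are exposed, since
the normalization of the bin "frequency" is a free choice. The
perpendicular set's 20 directions are spread $9°$ apart in the plane
spanned by the section normal and the in-plane $x$-axis — only the
plane's orthogonality is constrained, the spread is this package's
(configurable) choice.

`export_dwi` writes a 1-voxel-thick 4D NIfTI (double precision; voxel
size = pixel pitch in mm, slice thickness = pixel size) with FSL-dialect
`bval`/`bvec` files ($b = 1\ \mathrm{ms}/\mu m^2$ written as
$1000\ \mathrm{s/mm^2}$, the downstream convention) and a JSON sidecar.
Spherical deconvolution and tracking remain deliberately external, e.g.
MRtrix3 `dwi2response` (`fa`, $l_{max} = 6$), `dwi2fod` (`csd`,
$l_{max} = 6$), `tckgen` (minimum tract length 2 mm).

## The phantom generator

The phantom emulates the signal structure the analysis rests on, not the
optics: per pixel,

$$I(\phi) = \Big[b + \sum_k A_k\, \big(g(\phi - \theta_k - 90°) +
g(\phi - \theta_k + 90°)\big)\Big]\; L(x, y, \phi) + \varepsilon,$$

with $g$ a wrapped Gaussian (closed-form peak positions, unlike a
von-Mises mixture), $L$ an optional smooth multiplicative illumination
gradient shared bit-exactly with `generate_diffuser`, and seeded Gaussian
noise clipped at the sensor floor 0 *after* illumination scaling.
Defaults: $24$ azimuths of $15°$ (the acquisition scheme of the target
measurements), lobe width $\sigma = 15°$, baseline 0.1, amplitude 1,
noise off; "SNR 10" in the tests means noise $\sigma = 0.1$ against unit
peak amplitude. What the phantom does *not* model — diffraction,
inclination-dependent peak displacement and broadening, structured sensor
noise, stain variability — bounds what passing tests show about real
sections: they validate the computational chain, not the physics.

## Numerical choices and degenerate inputs

* Flat profiles (range 0) yield zero peaks; all-zero stacks come back
  fully masked with zero populations.
* A kernel larger than the image is one kernel; trailing partial tiles
  are kept iff at least half-covered.
* Plateau maxima contribute one candidate (the trailing edge).
* An empty ROI gives the zero-count muFOD; an all-zero muFOD maps to the
  zero spline.
* Disjoint masks in `orientation_difference` return an `empty`-flagged
  result with a warning rather than an error, so batch comparisons can
  continue.
* TIFF float pages are stored in $[0,1]$ with the scale factor in the
  JSON sidecar (the format's portable float range); NIfTI volumes are
  written in double precision so exports round-trip bit-exactly.
* All randomness (phantom noise, pipeline runs) flows from a single
  integer seed; the caller's RNG state is left untouched.

## Problem sizes

The validation suite runs phantoms up to $256 \times 256 \times 24$
(noise-free and SNR 10) for recovery statistics, $142 \times 142$ fields
for multi-resolution crossing statistics, $10^5$ orientations for
histogram uniformity, and 1000 random profiles for the pairing oracle —
sizes at which every property is measured in minutes on a single core
while leaving the statistics stable.

## Known limitations

* No out-of-plane inclination: orientations are strictly in-plane, and
  inclined fibers appear only through shifted peak pairs absorbed by the
  pairing tolerance.
* Crossing separations below $\approx 4\sigma_{\mathrm{lobe}}$ merge;
  with wide scattering lobes, closely crossing populations are reported
  as one.
* No registration: difference maps assume co-registered inputs.
* The dMRI bridge synthesizes signals only; it does not reimplement
  spherical deconvolution or tracking, and its output is only as good as
  the muFODs feeding it.
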
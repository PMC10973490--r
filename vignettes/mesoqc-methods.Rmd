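---
title: "Methods behind the mesoqc quality-control suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the mesoqc quality-control suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoqc)
```

mesoqc quantifies three properties of a microscope that matter for
large-sample light-sheet imaging and are awkward to read off by eye:
the contrast and flatness of the detection path, the size of the point
spread function across the field, and whether a rare bright structure in a
volumetric scan is real or a noise artifact. This vignette explains each
model, the parameters that control it, and the design decisions taken where
more than one reasonable definition exists.

## Conventions

All image arrays are `[row, col, plane]`, i.e. `(y, x, z)`, 1-based, with
`x` increasing along columns in camera readout order. Focus and voxel
coordinates are in micrometres. The sign of the focus axis is a metadata
convention: every reported metric (sag, depth of field, chromatic offset)
is a difference of z values, so the convention cancels. Subregion pixel
intervals are half-open; boundary *i* of an *n*-way split of *w* pixels
sits at `floor(i*w/n)`, so subregion sizes differ by at most one pixel.

Integer TIFF data (8/16-bit) are read and written losslessly as raw camera
counts. Floating-point TIFFs follow the normalized-intensity convention of
R image packages (samples in [0, 1]); quantitative camera data should be
stored as integer counts, which is what the simulators emit (16-bit, with
quantization error far below every tolerance used here).

## Contrast and field flatness

A back-illuminated square-wave grating (Ronchi ruling) imaged through a
focus sweep probes the detection optics at a single spatial frequency,
independent of the light-sheet. Each plane is split into an
`nx_sub` × `ny_sub` grid (default 32 × 20) and each subregion's contrast is

$$C = \frac{P_{99} - P_{1}}{P_{99} + P_{1}},$$

with $P_q$ the *q*-th intensity percentile. Percentiles replace min/max so
that read noise and defective pixels do not dominate; the convention is
sorted-order linear interpolation (rank $1 + q/100\,(n-1)$, the default
type-7 rule of `stats::quantile()`), fixed so results are bit-reproducible.
$C(x,y,z)$ is an estimate of the MTF at the grating frequency. Contrast is
invariant under intensity gain and strictly decreased by stray-light
offsets, which the test suite checks as properties.

**Saturation.** A subregion is flagged `NaN` in a plane when more than 1 %
of its pixels sit at the container maximum (`2^bits − 1`): the 99th
percentile is meaningless under clipping. Flagged planes are skipped in the
z-profile.

**Best-focus surface.** Per subregion, the peak of contrast vs z is
located. The default refines the discrete argmax with a parabola through
the peak and its two neighbours — exact for a locally quadratic peak and
unbiased for any symmetric profile sampled symmetrically; `argmax` (no
refinement) and a full Gaussian profile fit are available, because the
measured surface can shift slightly with the chosen contrast criterion.
Peaks at the sweep boundary are masked invalid rather than reported, since
the true peak may lie outside the sweep. Monotone profiles therefore never
produce a surface value.

**Tilt compensation and sag.** The mounted test target always has residual
tip/tilt, which is a property of the mount, not the objective. An ordinary
least-squares plane $a_0 + a_x x + a_y y$ (in normalized field coordinates,
[−1, 1] across the frame) is fitted over valid subregions and subtracted.
The **sag** is the peak-to-valley of the detrended surface. "Sag" could
also be read as the amplitude of a curve fitted per field section; the
peak-to-valley over the full valid grid is adopted as the default because
it needs no model of the surface shape, and a robust variant (2nd–98th
percentile span of the detrended surface) is reported alongside to resist
outlier subregions.

**Maximum-contrast map and uniformity.** $C_{\max}(x,y) = \max_z C$ is
invariant to target tip/tilt and suited to cross-comparing objectives.
Uniformity statistics use the population standard deviation, because the
map is a census of the field, not a sample from it.

**Depth of field.** Per subregion, the z-extent over which contrast stays
at or above half the local peak (threshold adjustable), with crossings
linearly interpolated between the 10-µm samples. For a Gaussian contrast
profile of half-width $w$ this equals $2w\sqrt{2\ln 2}$. Profiles that do
not fall below the threshold on both sides within the sweep are flagged.
Note that additive noise raises the off-focus contrast floor, so under
heavy noise the 50 % width reads high; the depth-of-field map is intended
for comparisons at matched noise levels.

**Chromatic offsets.** The best-focus surface shifts bodily along z
between emission channels. The per-channel offset is summarized as the
median of $z_0^{ch} - z_0^{ref}$ over the valid overlap — a scalar, because
the practical use is a per-channel refocus value; the median resists
residual field-curvature differences between channels. Full per-pair offset
maps are retained in the report, and the pairwise matrix is antisymmetric
by construction.

## PSF measurement from beads

Sub-resolution beads (0.2 µm diameter) approximate point sources; their
images are the PSF. The 0.2 µm physical size is *not* deconvolved — at the
2–4 µm FWHM scale of mesoscale instruments it contributes well under 1 %
and ignoring it is a documented limitation, not an approximation error that
matters here.

*Detection*: local maxima over the 26-neighborhood above
`median + min_snr × (1.4826·MAD)` (default `min_snr = 8`; at that threshold
the expected number of false maxima in a 10⁶-voxel Gaussian-noise volume is
far below one). Global robust statistics suffice because calibration
volumes have flat background.

*Cluster exclusion*: any candidate with a neighbour closer than
`min_separation_um` (default 5 µm) is removed, **both** members of a close
pair, since either fit would be contaminated. The implementation is checked
against a brute-force O(n²) oracle.

*Fitting*: within a window (default half-widths 6 × 5 × 5 voxels in z, y,
x; widen for broad PSFs so the window spans ≳3σ), the bead's best plane is
the one maximizing the 3-point-smoothed windowed intensity; a 2D elliptical
Gaussian plus constant background is fitted there
(`minpack.lm::nlsLM`), then a 1D Gaussian along z through the refined
lateral center. Beads whose window clips the volume are excluded
(`status = "edge"`) rather than partially fitted; fits with
$R^2 < 0.8$ or widths at the optimizer bounds become `"poor_fit"`. Widths
convert as FWHM $= 2\sqrt{2\ln 2}\,\sigma$; the single lateral number is
the geometric mean of the x and y FWHM, a symmetric combination that equals
either one when they agree. Fitting is invariant under intensity gain and
offset (tested to 1e−6 relative).

*Summary*: mean, SD and fixed-bin histograms (0.25 µm) over `"ok"` fits
only, plus per-bead field maps for spotting spatial structure.

## Repeated-scan validation of sparse structures

Rare bright structures — e.g. fluorescence from radiation-induced color
centers, appearing as few-voxel tracks spanning ~5 consecutive planes —
cannot be separated from noise excursions within a single scan at modest
SNR. The validation principle is a repeat scan: real structures recur at
the same location, noise does not.

Raw sensor data are never literally zero, so "signal" voxels are defined
as exceeding `background mean + k_sigma × sd` (default k = 5), with the
background model taken from dark frames, blank controls, or robustly
(median/MAD) from the scan itself when structures are sparse. Clusters are
26-connected components with at least `min_voxels` (default 4) members.

Each cluster's neighborhood (bounding box + 2 voxels padding) is cut from
scan A and correlated over the corresponding region of scan B extended by a
search halo (default 10 voxels), which absorbs small rigid misregistration
between consecutive scans without a volumetric registration step. The
normalized cross-correlation is computed by direct summation (values in
[−1, 1], invariant to affine intensity transforms of either scan; checked
against a triple-loop oracle to 1e−10). The NCC values away from the peak's
immediate 3³ neighbourhood — excluded so a genuine match does not inflate
the spread — form the null sample; a Gaussian null (moment fit; median/MAD
option) gives the peak a z-score. The default flag threshold of 5σ is
deliberately conservative relative to the ~10σ scores that planted
structures produce at SNR 10, while keeping the per-map false-flag
probability negligible after accounting for the thousands of correlated
placements in a map. A candidate is **confirmed** only when flagged in both
directions (A→B and B→A, clusters paired by centroid proximity within the
halo), operationalizing "found repeatedly in more than one scan". Whether
the null should pool NCC values across candidates is ambiguous;
per-candidate nulls are the default since they adapt to local texture.

## The simulators: what they emulate, and what they do not

The simulators generate the three acquisition types with known ground
truth, and their defaults encode the standard study conditions:

* **Ronchi stacks** — 61 planes from −300 to +300 µm in 10 µm steps;
  40 lp/mm grating (period 10 px at the default 2.5 µm pixel);
  horizontal lines with the phase edge fixed at row 1 (determinism of the
  percentile statistics; optional jitter is deliberately absent); local
  contrast $C_{peak}(x,y)\exp(-(z-z_0(x,y))^2/2w^2)$ with
  $z_0 = a_0 + a_x x + a_y y + c_2 r^2 + c_4 r^4$ ($r$ normalized to 1 at
  the field corner) and $w$ = 30 µm by default (a ~70 µm depth of field,
  several focus steps wide); mean level 10 000 counts with Gaussian read
  noise 200 counts (2 %). The true MTF-vs-defocus shape of a real objective
  is not Gaussian, but only the peak location and amplitude are consumed
  downstream, so a symmetric unimodal model with analytically known peaks
  is the right fixture. Frames are 320 × 200 px rather than full sensor
  size: each 10 × 10 px subregion then holds one full grating period, the
  smallest frame at which the 32 × 20 analysis grid is still exercised
  faithfully.
* **Bead volumes** — 3D anisotropic Gaussian spots with sub-voxel centers
  (default σ chosen so the true FWHM is 1.51 µm lateral / 3.30 µm axial,
  representative mesoscale values), amplitude 2000 counts over a
  100-count background with noise 100 (SNR 20), 50 beads with ≥8 µm
  spacing in a 80 × 80 × 48 µm volume at (0.5, 0.5, 1) µm voxels. An
  optional `cluster_fraction` plants near-coincident pairs (1.5 µm apart)
  to exercise the cluster filter.
* **Scan pairs** — tracks as anti-diagonal runs of single bright voxels,
  one voxel per plane across 5 planes, at SNR 10 over a Gaussian
  background (mean 100, sd 5), planted identically in both volumes up to a
  ≤3-voxel rigid offset, with independent noise; 64 × 64 × 48 voxel
  volumes keep 20-seed power studies fast while leaving room for the
  search halo.

Not emulated: diffraction and aberration structure of a real PSF (spots
are ideal Gaussians), vignetting beyond a radial peak-contrast falloff,
Poisson photon noise (the analyses are percentile/correlation based and
distribution-insensitive at these SNRs; read noise dominates the regime of
interest), sample-induced scattering, and stage drift beyond a rigid
offset. Passing the end-to-end tests therefore demonstrates that the
*analysis* recovers known ground truth under realistic geometry and noise —
not that a physical instrument meets any particular specification.

## Numerical choices and degenerate inputs

* Percentile convention: `stats::quantile` type 7, stated above.
* Parabolic refinement clamps the vertex to the bracketing samples and
  falls back to the sampled maximum when the three points are not concave.
* `subregion_contrast` returns `NaN` (not an error) when $P_{99}+P_1 = 0$,
  so dark subregions propagate as flagged values, while empty or negative
  input is an error.
* Zero-variance NCC windows yield 0 and are flagged; a zero-variance
  template is an error (no meaningful correlation exists).
* Ties in bead detection are broken by requiring a strict unique maximum
  over the neighborhood; with sub-voxel centers and noise, exact plateaus
  occur with probability ~0.
* All simulators restore the caller's RNG state; a fixed `(config, seed)`
  pair is bit-reproducible.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script geometries are the defaults above:
full 61-plane sweeps on 320 × 200 px frames for sag recovery at planted
sags of 0/50/120 µm (tolerance: half a focus step, ±5 µm, with and without
target tilt); 10 seeds × 50 beads per case for FWHM recovery within 5 %;
20 seeds of 3-track SNR-10 pairs for ≥95 % confirmation power and 20
noise-only pairs for false-confirmation control. These sizes were chosen as
the smallest at which each estimate's sampling error is comfortably below
the tolerance being checked.

## Known limitations

* The sag depends on the valid-subregion mask: heavily vignetted corners
  that never peak inside the sweep are excluded, which can understate the
  curvature of extreme objectives; widen the sweep in that case.
* Depth of field reads high under strong noise (contrast floor), see above.
* The bead fitter assumes a locally constant background; structured
  fluorescent background (real tissue) violates this — bead volumes should
  be dedicated calibration samples.
* No volumetric registration: scan pairs with misregistration beyond the
  search halo will score genuine structures as unconfirmed.
* The 0.2 µm bead diameter is ignored in the reported FWHM.
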
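---
title: "Analytic k-space phantoms and automated MR image-quality metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic k-space phantoms and automated MR image-quality metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droiq)
```

## Why analytic phantoms

An MR scanner samples the Fourier transform of a *continuous* object; the image
is a band-limited, discretized rendering of it. A phantom defined as a pixel
image cannot reproduce the partial-volume and Gibbs-ringing behaviour of that
process. `droiq` therefore defines its test objects in continuous k-space: a
uniform disk of radius $R$, intensity $I$, center $(x_c, y_c)$ has transform

$$F(k_x, k_y) = \mathrm{Jinc}(k_r \mid R)\, I\, e^{-2\pi i (x_c k_x + y_c k_y)},
\qquad
\mathrm{Jinc}(k_r \mid R) = \frac{2\pi R^2 J_1(2\pi R k_r)}{2\pi R k_r},$$

with $J_1$ the first-order Bessel function and $k_r = \sqrt{k_x^2+k_y^2}$; the
$k_r = 0$ limit is the disk area $\pi R^2$. Compound phantoms are sums of disk
transforms (linearity). The transform is sampled on a DC-centered $N \times N$
grid with spacing $\delta k = 1/\mathrm{FOV}$ and reconstructed by inverse FFT.

### Amplitude convention

The continuous inverse transform is approximated by the Riemann sum
$f(\mathbf r) \approx \delta k^2 \sum F(\mathbf k_n) e^{2\pi i \mathbf k_n \cdot \mathbf r}$,
i.e. the unnormalized inverse DFT scaled by $1/\mathrm{FOV}^2$. Under this
convention a noiseless disk of intensity $I$ reconstructs with interior
intensity $I$ (verified to 0.005 % at the defaults). Image coordinates are
pixel centers $x = (m - N/2)\,\mathrm{FOV}/N$ with the origin at the FOV
center; $N$ must be even so the DC sample and the ROI geometry (which uses
$N/16$ divisions) are well defined.

### Noise convention

Acquisition noise is zero-mean complex Gaussian, added per k-space sample and
calibrated so that each *channel* (real and imaginary) of the reconstructed
complex image has per-pixel standard deviation $\sigma$; the required k-space
per-channel standard deviation is $\sigma\,\mathrm{FOV}^2/N$. With disk
intensity $I$ this makes the designed SNR $I/\sigma$ equal to what the NEMA
difference method measures ($\sqrt2\,\bar I / \mathrm{sd}(\Delta I)$): with
$I = 0.5$, $\sigma = 0.04$ and $0.02$ give SNR 12.5 and 25. Noise is *not*
Hermitian-symmetrized, so magnitude backgrounds are Rician — exactly as in a
single-coil magnitude reconstruction.

Seeding: each phantom spec carries a master seed; realization $k$ uses a
deterministically derived substream seed, so any realization is reproducible
in isolation and whole batch runs are bit-reproducible.

## Phantom layouts

**Disk phantom.** One centered disk, default $R = 95$ mm, $I = 0.5$, FOV
240 mm, $N = 128$ (pixel 1.875 mm).

**Resolution phantom.** For each radius $r \in \{0.8, 0.9, 1.0, 1.1\}$ mm
(resolutions $2r = 1.6$–$2.2$ mm, spanning the 1.875 mm pixel) and each
direction, a block of 4 rows × 4 identical disks. In-row center spacing is
$4r$ — two diameters, so the edge-to-edge gap equals the resolution under
test — and row $j$ is shifted laterally by $j\,r/2$. The sub-pixel row shifts
are essential: at resolutions near the pixel size, whether four separate peaks
survive sampling depends on the phase of the disk centers relative to the
pixel grid, and the staggered rows guarantee at least one favourable phase
(the partial-volume effect the shifts are designed to probe). Vertical blocks
are the 90°-rotated layout. Blocks are tiled on two FOV rows with > 10 mm
margins and validated disjoint.

**Low-contrast phantom.** A background disk ($R_{bg} = 65$ mm, $I = 0.5$) plus
10 spokes × 3 disks; per-spoke radii evenly spaced 0.75–3.5 mm; small disks
superimposed with added intensity $0.2 \times 0.5 = 0.1$ (20 % brighter than
background, the hyper-intense choice). Spokes sit at $36°s$; disks at ring
distances 21, 34, 47 mm. These distances are chosen so that **no neighbouring
disk and no part of the background edge falls inside any disk's 10 × 10-pixel
(18.75 mm) detection patch**: in-spoke separation 13 mm and adjacent-spoke
chord $2 d \sin 18°$ both clear the patch half-extent plus the largest disk
radius, and the outermost patch corner stays ≥ 4 mm inside the background
edge. With tighter ACR-like spacings (e.g. rings at 12/22/32 mm on a 40 mm
background) the patches overlap neighbouring structure and template
correlation collapses even without noise; the spacing is a requirement of the
patch-based detection method at this pixel size, not a cosmetic choice.

## Metrics

**Geometric accuracy.** Region growing from the center pixel with threshold
half the median of an 11 × 11 central patch (the half-maximum edge criterion;
relative, so the metric is invariant to intensity scaling); the connected
component containing the seed is the disk. Semi-axes come from the second
central moments of the region (equivalent-ellipse, $2\sqrt{\lambda}$), a
deterministic sub-pixel estimator that is exact for a continuous disk. The
metric is $100 \max(|R_{maj}-R_{gt}|, |R_{min}-R_{gt}|)/R_{gt}$.

**Percent intensity uniformity.** The detected mask is eroded with a
disk-shaped structuring element of radius 5 pixels (the isotropic reading of
"eroded by 5 pixels"), the image low-pass filtered with the uniform 3 × 3
kernel, and $\mathrm{PIU} = 100\,(1 - (I_{max}-I_{min})/(I_{max}+I_{min}))$
taken over the eroded ROI. Always in $[0, 100]$.

**Ghosting ratio.** Four rectangles, long edge $N/2$, short edge $N/16$,
centered $7N/16$ pixels from the *designed* disk center (using the designed
rather than detected center keeps the ROIs in the phantom's frame and
decouples this metric from the geometry estimate). The ratio is
$|(\bar I_{top}+\bar I_{bot}) - (\bar I_{left}+\bar I_{right})| / (2 \bar I_{disk})$
with the absolute value of the ACR formulation; Cartesian aliasing along the
horizontal (phase-encode) axis raises the left/right ROIs and the ratio.

**Sharpness.** Every pixel's exact distance to the designed center is
computed; intensities within $R \pm 15$ mm (8 pixels) are binned onto a
uniform grid of 1/10 pixel — the incommensurate pixel distances sample the
continuous edge far more finely than the pixel pitch. Rare empty bins are
filled by linear interpolation so the grid stays uniform. For noisy images the
binned ESF is replaced by a 4-parameter logistic fit
$L + (U-L)/(1+e^{(x-x_0)/s})$ (tails initialize $L, U$; $x_0 = R$; $s$ half a
pixel) for robustness; the noiseless path skips it. The ESF is differentiated
by central differences, negated (the edge falls outward), and fitted with the
Lorentzian $A\,\frac{1}{\pi}\frac{\Gamma/2}{(x-x_0)^2+(\Gamma/2)^2}+B$,
initialized from the derivative's extremum, its half-maximum span and its
integral, with $\Gamma > 0$ bounded. $\Gamma$ (mm) is the sharpness; it is
invariant to affine intensity transforms and grows under blurring.

**Difference SNR.** $\sqrt2\,\mathrm{mean}(I_1)/\mathrm{sd}(I_1 - I_2)$ over
the eroded disk ROI of two same-spec realizations; consecutive realizations
$(2k-1, 2k)$ form pair $k$.

**High-contrast resolution.** Along each designed row line (nearest pixel row
through the disk centers, with a 6 mm margin), local maxima strictly above
both neighbours are kept if they exceed the Otsu threshold of the profile's
own intensity distribution (scale-invariant) and are pruned greedily to a
minimum separation of two radii. A resolution $2r$ is achieved in a direction
when any of the four rows yields 4 peaks; the smallest achieved $2r$ is
reported per direction, with "not resolved" as `NA`. The 1-D Otsu threshold
takes the middle of the maximizing plateau of the between-class variance —
with well-separated classes the criterion is flat across the empty gap and
the plateau midpoint is the canonical split.

**Low-contrast detectability.** The template for a disk size is the noiseless
rendering, through the same k-space pipeline, of that disk centered on the
background disk, cropped to 7 × 7 pixels. Each phantom disk is tested by
cropping the 10 × 10 patch at its rounded designed center and sliding the
template over all 4 × 4 fully-contained positions (the correlation map),
scoring the maximum Pearson correlation. A 7-pixel template inside a 10-pixel
patch gives a true correlation map while covering the ±0.5-pixel placement
error of rounded centers; with a full-size 10 × 10 template the only possible
"map" comes from partial-overlap windows, which we found discards too many
edge pixels to separate small disks from background at the higher noise
level. Thresholds are calibrated per (disk size, σ, contrast) from 100
disk-present and 100 disk-absent simulated patches; disk-present patches get
a uniform sub-pixel center offset so the calibration shares the alignment
statistics of the phantom patches (without it the calibrated thresholds are
biased high and detection collapses). The threshold sweep uses midpoints of
consecutive sorted scores, ties broken toward the higher threshold (fewer
false positives). If the best accuracy is below 0.70 the disk size is deemed
undetectable and its spoke auto-fails. A spoke is visible when all three of
its disks are detected. Thresholds are calibrated once per batch and reused
across realizations.

## Batch evaluation and undersampling

`run_evaluation()` routes metrics by phantom kind (disk → geometry /
uniformity / ghosting / sharpness / SNR; resolution → resolution; low-contrast
→ detectability), records per-realization failures as error rows without
aborting, and aggregates mean ± sd per (kind, σ, metric). Reconstructions are
pluggable through `recon_interface()`; the reference is the inverse FFT.

`make_undersampling_mask()` builds variable-density Cartesian masks: the
central 30 % of phase-encode lines always sampled, the remaining budget (total
$N/\mathrm{acceleration}$) drawn without replacement with Gaussian
center-weighted probability (scale $N/4$ — a conventional choice; the exact
density law is a utility, not a measured quantity). The phase-encode axis is
horizontal. Zero-filled 2× undersampling raises the ghosting ratio by roughly
an order of magnitude and degrades the achieved horizontal resolution on
average; single realizations can buck the resolution trend because an
aliasing replica can masquerade as a fourth peak in the finest block — a known
limitation of peak counting.

## Problem sizes used in the tests

The packaged test-suite runs scaled-down versions of the full study: 100
realizations per phantom per noise level for the summary checks (the full 600
is the `scripts/acceptance.R` default, ~2 min on one CPU), 50 realizations per
cell for the 3 × 3 contrast × σ detectability-monotonicity grid, and 100
realizations for the noise-calibration check on a 64 × 64 grid. These sizes
keep Monte-Carlo standard errors a few times smaller than the tolerances they
are tested against.

## What the synthetic phantoms do and do not emulate

The generator reproduces band-limited acquisition of continuous objects,
partial-volume effects, Gibbs ringing, Rician magnitude noise, and Cartesian
undersampling aliasing. It does **not** model multi-coil acquisition or coil
sensitivities, field inhomogeneity, relaxation contrast, slice profiles, 3-D
geometry, or anthropomorphic structure. Passing metrics here demonstrates
that a reconstruction preserves the geometry, uniformity, sharpness, noise
and detectability characteristics of simple objects under ideal single-coil
conditions — a necessary, not sufficient, condition for clinical image
quality.

## Known limitations and numerical notes

* The equivalent-ellipse radius of the rasterized, thresholded disk carries a
  small (< 0.1 %) discretization bias relative to the continuous disk; it is
  stable across noise levels.
* The Lorentzian is fitted to a derivative that is not exactly Lorentzian
  (the true kernel is a Dirichlet/periodic-sinc edge response, sigmoid-smoothed
  on the noisy path), so $\Gamma$ is a model-based summary, not a literal
  PSF width; comparisons are meaningful between reconstructions evaluated with
  the same procedure.
* Low-contrast detectability depends on calibration draws near the 0.70
  accuracy floor: spokes whose calibration accuracy straddles the floor can
  flip between runs with different master seeds, which dominates the
  between-run variance of the visible-spoke count.
* Peak counting for resolution cannot distinguish genuine disk peaks from
  aliasing replicas, so undersampling comparisons should be made on averages
  over matched seeds.

## Round-trip and export formats

Phantom specs serialize to JSON (`phantom_spec_to_json()` /
`phantom_spec_from_json()`; identical specs re-simulate bit-identically).
Magnitude images export to NIfTI (pixel spacing in the header) and PNG;
reports to CSV/JSON. A thin CLI (`inst/cli/droiq`) wraps generation,
evaluation, reporting and mask construction.
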
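# droiq — digital reference object phantoms and automated MR image-quality metrics

Machine-learning MRI reconstruction is usually benchmarked with similarity scores
(SSIM, PSNR) against a ground-truth image. Those scores say little about the
scanner-style quality characteristics radiologists and physicists actually test
for: geometric distortion, intensity uniformity, ghosting, edge sharpness, SNR,
and high- and low-contrast object visibility. `droiq` brings the ACR/NEMA
physical-phantom methodology to the digital domain so that *any* reconstruction
algorithm can be scored on those terms against an inverse-FFT reference.

The key idea is that the test objects are defined **analytically in continuous
k-space**, not as rasterized images. A uniform disk of radius R, intensity I and
center (x_c, y_c) has the closed-form 2-D Fourier transform

```
F_disk(kx, ky) = Jinc(k_r | R) · I · exp(−2πi (x_c kx + y_c ky)),
Jinc(k_r | R)  = 2πR² J₁(2πR k_r) / (2πR k_r),     k_r = √(kx² + ky²),
```

with J₁ the first-order Bessel function. Compound phantoms are sums of disk
transforms. Sampling this continuous function on a DC-centered grid with spacing
δk = 1/FOV, adding complex Gaussian noise, and applying an inverse FFT mimics the
actual MR acquisition of a continuous object — including the partial-volume and
Gibbs-ringing behaviour a rasterized phantom would miss.

## Phantoms

* **Disk phantom** — one 95 mm disk (intensity 0.5 on a 240 mm FOV, 128×128
  grid). Used for geometric accuracy (max % radius error of the region-grown
  equivalent ellipse), percent intensity uniformity (NEMA 3×3 low-pass,
  5-pixel-eroded ROI), ghosting ratio (four N/2 × N/16 background ROIs at
  7N/16 from center), sharpness (Lorentzian FWHM fitted to the derivative of the
  radially-binned edge spread function), and difference-image SNR
  (√2·mean/sd of two-acquisition difference).
* **Resolution phantom** — per radius r ∈ {0.8, 0.9, 1.0, 1.1} mm and direction,
  4×4 arrays of disks spaced two diameters apart with half-radius row shifts;
  a resolution 2r is achieved when four Otsu-thresholded peaks appear in a row.
* **Low-contrast phantom** — ACR-style: 10 spokes × 3 disks on a background
  disk, per-spoke radii 0.75–3.5 mm, 20 % contrast. Detection is sliding-window
  template matching with thresholds calibrated per disk size from 100
  disk-present / 100 disk-absent simulated patches (0.70 accuracy floor);
  the score is the number of spokes with all disks detected.

Noise sigma 0.04 / 0.02 with intensity 0.5 gives designed SNR 12.5 / 25.

## Worked example

```r
library(droiq)

spec <- build_disk_phantom(fov_mm = 240, matrix_size = 128, radius_mm = 95,
                           intensity = 0.5, sigma = 0.04, seed = 1)
img <- simulate_phantom(spec, realization = 1)

ell <- detect_disk(img)
ell
#> <detected_ellipse> center (0.05, -0.03) mm, semi-axes 95.03 / 95.01 mm, 8069 px
geometric_accuracy(ell, 95)          # max % radius error
#> [1] 0.03667901
intensity_uniformity(img, ell)       # percent intensity uniformity
#> [1] 91.34893
ghosting_ratio(img, ellipse = ell)   # ghosting ratio
#> [1] 0.0005809857
sharpness(img)                       # Lorentzian FWHM of the ESF derivative, mm
#> [1] 0.8364405
snr_difference(img, simulate_phantom(spec, realization = 2))
#> [1] 12.59664
```

The detected disk is within 0.04 % of its designed 95 mm radius, the image is
~91 % uniform at this noise level, ghosting is negligible (no aliasing), the
edge transition has a fitted width of ~0.84 mm, and the measured SNR matches the
designed I/σ = 12.5.

A scaled-down batch over all three phantom kinds:

```r
report <- run_evaluation(default_config(n_realizations = 20, sigmas = 0.04, seed = 1))
report
#> <metric_report> 150 rows, ifft recon, seed 1
#>          kind sigma               metric  units      mean       sd  n n_missing
#>          disk  0.04   geometric_accuracy      %  0.058493 0.031777 20         0
#>          disk  0.04       ghosting_ratio         0.001758 0.001379 20         0
#>          disk  0.04 intensity_uniformity      % 90.185597 0.545347 20         0
#>          disk  0.04       sharpness_fwhm     mm  0.876690 0.025208 20         0
#>          disk  0.04       snr_difference        12.608000 0.116294 10         0
#>  low_contrast  0.04       visible_spokes spokes  6.400000 0.940325 20         0
#>    resolution  0.04      resolution_x_mm     mm  1.710000 0.102084 20         0
#>    resolution  0.04      resolution_y_mm     mm  1.670000 0.097872 20         0
```

To benchmark your own reconstruction, wrap it in a `recon_interface()` (any
function mapping DC-centered complex k-space to an image) and pass it to
`default_config(recon = ...)`. `make_undersampling_mask()` +
`apply_sampling_mask()` provide variable-density Cartesian undersampling with
zero-filling for accelerated-acquisition experiments.

A thin command-line wrapper ships in `inst/cli/droiq`
(`droiq generate | evaluate | report | mask`).

## Vignette

`vignettes/droiq-methods.Rmd` documents the model and its conventions
(amplitude and noise calibration, grid layout), every tunable parameter with
its default and rationale, the phantom layout geometry, numerical choices in
the estimators, and known limitations of the digital phantoms relative to
physical-phantom acquisitions.
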
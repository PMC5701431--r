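---
title: "Measuring tear-film lipid layer thickness from interference colors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tear-film lipid layer thickness from interference colors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tearfilm)
```

## The measurement problem

The outermost layer of the precorneal tear film is a lipid film, tens of
nanometers thick, secreted by the meibomian glands. Too little meibum
(hyposecretory meibomian gland dysfunction) thins the film and lets the
aqueous layer evaporate — the dominant mechanism of evaporative dry eye —
while hypersecretion thickens it. Under broadband white illumination the
film behaves as a classical thin film: light reflected at the air–lipid
interface interferes with light reflected at the lipid–aqueous interface,
and the reflected color encodes the film thickness. `tearfilm` turns eye
videos recorded under a diffuse white LED (color temperature about 6500 K,
nominally 30 frames/s) into per-pixel lipid layer thickness (LLT) maps and
their statistics.

## Forward model: thickness to color

For a film of thickness $d$ and refractive index $n_m$ at refraction angle
$\beta$, successive reflected rays are separated by the optical path
difference $\mathrm{OPD} = 2 n_m d \cos\beta$, i.e. a phase lag
$\Delta = 2\pi\,\mathrm{OPD}/\lambda$ per round trip. Interface power
coefficients come from the Fresnel equations per polarization
($\mathbb{R} = |r|^2$, $\mathbb{T} = \frac{n_j\cos\theta_j}{n_i\cos\theta_i}|t|^2$,
with $\mathbb{R} + \mathbb{T} = 1$ at every lossless interface). The ray
reflected $m$ times inside the film carries intensity

$$I_0 = \mathbb{R}_{12} I_i,\qquad
  I_1 = \mathbb{T}_{12}\mathbb{R}_{23}\mathbb{T}_{21} I_i,\qquad
  I_m = \mathbb{R}_{21}\mathbb{R}_{23}\, I_{m-1}\ (m > 1),$$

(layers: 1 air, 2 lipid, 3 aqueous) and phase $m\Delta$; the reflected
field is the coherent sum $\sum_m s_m \sqrt{I_m}\, e^{i m \Delta}$ and the
observed spectrum its squared magnitude, averaged over s- and
p-polarization because the LED light is unpolarized.

Two modeling choices deserve comment:

* **Reflection phases.** A magnitude-only sum ($s_m = +1$ for all $m$)
  makes a vanishing film the *in-phase maximum* — a bright color at
  $d = 0$ — which contradicts the defining phenomenology of lipid-layer
  interferometry (thin films look dark). The air-to-lipid reflection
  carries a half-wave phase jump; keeping the signs of the Fresnel
  amplitude products (`phase_convention = "fresnel"`, the default) makes
  $d = 0$ destructive and the $d = 0$ lookup-table entry the darkest, as
  observed clinically. The magnitude-only reading is retained as
  `phase_convention = "literal"` and is covered by tests.
* **Truncation.** Orders are added until $I_m / I_i < 10^{-9}$ or 50
  orders, whichever comes first. For tear-film indices the series
  effectively ends at $m = 3$; the residual enters the intensity through
  amplitude cross terms of order $10^{-6}$, far below 8-bit color
  resolution.

The spectrum over 360–830 nm (1-nm grid) is weighted by the illuminant and
the CIE 1964 10-degree standard observer and summed per channel. The
color-matching functions are evaluated from the published multi-lobe
Gaussian analytic approximations (Wyman, Sloan & Shirley, 2013, *Journal of
Computer Graphics Techniques*), whose error is a few percent of peak —
negligible against camera noise — and mapped to linear sRGB primaries with
the standard XYZ-to-sRGB matrix. Negative CMF lobes can make individual
channels slightly negative; they are clamped at zero during table
construction. The default illuminant is a 6500 K Planck spectrum; an
equal-energy illuminant and user-supplied spectra are accepted.

`build_lut()` evaluates the model on a 0–240 nm grid in 1-nm steps (241
entries, the physiological range of interest), scales the curve by a single
global gain so the maximum channel equals 255, and applies the sRGB
transfer curve by default so the table lives on the same gamma-encoded
8-bit scale as camera output. Colors are kept at double precision in
memory — rounding to integers can make neighboring entries collide, which
would break exact nearest-color inversion — and are rounded only on export
(`write_lut()`).

Default optical constants: $n_{\text{air}} = 1.000$,
$n_{\text{lipid}} = 1.48$ (meibum), $n_{\text{tear}} = 1.337$, normal
incidence. All are configurable through `optical_stack()`; none are
wavelength-dependent (no dispersion, no absorption — a known limitation).

```{r lut, fig.width = 6, fig.height = 1.6}
lut <- build_lut()
plot(lut)
```

## Inverse problem: video to thickness

The pipeline (`analyze_video()`) runs six phases per 2.5-s analysis window
(75 frames at 30 frames/s):

1. **Blink filtering.** A blink reflects the LED off the eyelid and
   brightens the whole frame. With $B_{\text{opened}}$ the mode of the
   per-frame mean brightness series (256 integer-centered bins) and
   $B_{\text{closed}}$ its maximum, frames brighter than
   $B_{\text{opened}} + c\,(B_{\text{closed}} - B_{\text{opened}})$ with
   $c = 0.33$ are discarded. If the maximum lies within one bin of the
   mode the series carries no blink evidence and every frame is kept —
   without this guard, rounding jitter in a blink-free sequence would put
   the mode's bin center below most frames. Brightness of a pixel is the
   plain channel mean $(R+G+B)/3$ throughout.
2. **Pupil and eye center.** The darkest 21×21-pixel window (by mean
   brightness; ties to the top-left) seeds an 8-connected flood fill with
   threshold 5/256 — a pixel joins if its brightness differs from the
   *seed's* by strictly less than the threshold. The coarse region is
   hole-filled (camera noise punches pinholes that would otherwise
   fragment the next step), painted white, the image Gaussian-blurred, and
   the fill repeated with threshold 3, yielding a smooth pupil whose
   centroid approximates the eye center. If that centroid strays more than
   half an expected iris radius from the darkest window, the window center
   is used instead. (A quarter radius proved too strict: the darkest
   window legitimately sits up to a pupil radius away from the centroid
   whenever the pupil is wider than a quarter of the iris.)
3. **Iris radius and ROI.** A second fill seeded up-left of the center at
   about 0.7 expected radii (mid-iris, clear of the pupil, of the
   interference band below the pupil, and of the lids; seeding at the
   center row risks landing in the band whenever the center estimate sits
   a pixel low) extracts the iris region. Canny edges of that region are
   kept where the edge tangent is within 15° of vertical — eyelid
   boundaries are nearly horizontal and drop out — and within
   0.8–1.2 expected radii of the center; the radius is the mean distance
   of surviving edge pixels. The ROI is the set of pixels within 80% of
   the iris radius, strictly below the center row, laterally within 80% of
   that inner radius, outside the pupil, and at least as bright as the
   mean of the region just defined. Frames whose geometry fails any of
   these steps are dropped as occluded.
4. **Iris color subtraction.** The interference colors ride on the iris
   color. Its estimate is the mean over the iris annulus between 0.8 and
   0.95 of the radius, excluding ROI and pupil; the outer trim matters
   because a 2-px center error otherwise lets the roughly six-times
   brighter sclera bleed into the sample. The estimate is subtracted
   per channel, clamped at zero.
5. **Illumination correction.** The sclera acts as an in-scene white
   reference: the brightest 1% of non-saturated pixels outside the iris
   circle (selected on a lightly smoothed brightness field so single-pixel
   noise does not bias the selection upward) give per-channel gains
   $g_c = 255 / \text{sclera}_c$ — von-Kries white balancing, applied
   after the subtraction (illumination acts multiplicatively, so the two
   corrections commute for the ROI term but the order is fixed and
   tested). Gains are estimated once per video on the first valid frame by
   default (`gains_mode = "per_frame"` is available).
6. **Thickness assignment.** Each corrected ROI pixel receives the
   lookup-table thickness with the nearest color in Euclidean RGB
   distance; exact ties go to the smaller thickness (the conservative,
   deterministic choice). Pixels darker than 10/255 after correction are
   excluded as eyelash shadow before any statistics.

Outputs per frame: mean and *population* SD of assigned thickness, a
relative-frequency histogram in 10-nm bins over 0–240 nm. Video level: the
pooled-pixel mean and SD (pooled over pixels, not the SD of frame means —
recorded in the output metadata), a 50×50 nearest-sampled surface grid of
the middle frame's ROI bounding box, and an RGB scatter of
(color, thickness) pairs pooled over three consecutive frames and
downsampled to every third pixel in scan order (column-major).

## The synthetic scene generator

No clinical videos ship with the package; validation runs on
ground-truth-labeled synthetic scenes (`scene_spec()`, `render_frame()`,
`render_video()`) that composite — independently of the analysis code
paths — a white sclera, a Gaussian-textured iris annulus, a dark pupil, an
interference band on the inferior iris colored through the supplied lookup
table with an additive iris tint, optional eyelid occluders and eyelash
streaks, per-channel illumination gains, blink brightening, Gaussian
camera noise and 8-bit quantization. The iris texture and the thickness
field are functions of the offset from the eye center, so they translate
rigidly with the eye.

Scale and default choices (all configurable):

* Frames are 240×320 with a 90-px iris radius and a 36-px pupil — an eye
  filling the frame as in slit-lamp close-ups, rendered at reduced
  resolution. Spatial analysis parameters quoted for the full 480-px-iris
  zoom (blur σ = 5 px, expected radius 240) scale accordingly
  (σ = 2 px, radius 90) when analyzing these scenes; the 21-px darkest
  window still fits comfortably inside the pupil and is left unchanged.
* The interference band spans the inferior iris out to 0.72 of the iris
  radius: the LED reflection zone is the inferior cornea, and keeping the
  band strictly inside the 0.8 analysis circle also keeps its boundary out
  of the edge-distance band used for radius fitting.
* Illumination gains default to (0.78, 0.75, 0.80): an exposure at which
  nothing in the scene saturates, as in a correctly exposed recording.
  The intrinsic sclera is white (255, 255, 255), so the pipeline's gains
  should invert the scene tint exactly.
* Camera noise defaults to σ = 3 counts per channel; the `patient1/2/3`
  presets carry uniform 45, 70 and 95 nm films (thin, normal, thick —
  mirroring hyposecretory, unaffected and hypersecretory gland states at
  the level a synthetic test can represent), `blinky` inserts five blink
  bursts, `moving` translates the eye at up to 10 px/frame under eyelid
  occluders, `gradient` thickens toward the lower lid, `lashes` draws
  shadow streaks.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about clinical data: real iris crypt structure (only
Gaussian texture), specular highlights, tear-film break-up dynamics,
defocus, interlacing, light-colored irises (known limitation of the
method: the flood-fill contrast between pupil and a pale iris may be
insufficient), motion blur and non-white scleras. The end-to-end recovery
numbers certify the pipeline's internal consistency under the stated noise
model, not clinical accuracy.

## Numerical choices and degenerate inputs

* Nearest-color search is exact (full 241-entry scan per pixel,
  vectorized); ties break to the smaller thickness; the search is the
  identity on the table's own entries, which the suite checks exactly.
* Noise tolerance of the inversion depends on the local speed of the color
  curve, about 1.3–1.5 counts/nm in the 45–95 nm range: with σ = 2
  per-channel noise about 90% of pixels land within ±2 nm of truth at
  70–95 nm (99.9% at 45 nm), with mean absolute error well under 1.5 nm.
* Flood fill compares every candidate against the *seed* brightness
  (not its local neighbor), so region brightness cannot drift; the fill is
  frontier-vectorized and exactly equals a scalar stack-based reference on
  random noise images.
* Canny thresholds are automatic (0.66 and 1.33 times the median nonzero
  gradient magnitude) with 8-connected hysteresis.
* Degenerate inputs fail loudly with classed conditions: frames smaller
  than the search window, empty ROIs (e.g. an eye center on the bottom
  image edge), an all-shadow ROI, a missing iris boundary, a saturated or
  empty sclera sample, a non-convergent stack
  ($\mathbb{R}_{21}\mathbb{R}_{23} \ge 1$). `analyze_video()` catches the
  per-frame conditions and drops the frame with the reason recorded in the
  selection report; a video with no surviving frames is an error.
* All randomness is seeded; rendering and analysis are bit-reproducible,
  and the renderer restores the caller's RNG state.

## Problem sizes used in the validation suite

The suite analyzes 75-frame videos (the 2.5-s window) for the end-to-end
recovery, geometry-tracking and blink-filtering checks, and shorter 3–6
frame sequences for I/O and determinism checks; `scripts/acceptance.R`
reruns the full set — three patient presets, the moving-eye video, the
blink video, a noise-free round trip and the gradient surface — from a
single seed in a few minutes on one core.

## Known limitations

* The absolute brightness link between the theoretical table and camera
  counts is fixed by normalizing the table's maximum channel to 255 and
  white-balancing the scene to the sclera; a radiometric calibration
  (e.g. a white fiducial target) would be better grounded.
* Mean iris color is subtracted uniformly; per-pixel iris background under
  the ROI is not modeled.
* No dispersion or absorption in the film; thickness outside 0–240 nm is
  reported as the nearest grid endpoint color match.
* Video containers are not decoded; extract numbered frames first.
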
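# tearfilm

Quantitative measurement of the tear-film **lipid layer thickness (LLT)**
from eye videos recorded under diffuse white-LED illumination.

The lipid film secreted by the meibomian glands (tens of nanometers thick)
guards the aqueous tear layer against evaporation; its thinning by
hyposecretory meibomian gland dysfunction is the leading cause of
evaporative dry eye. Under broadband illumination the film produces
thin-film interference colors on the inferior iris, and the color of each
pixel encodes the local film thickness. `tearfilm` is for vision
researchers and instrument developers who want an open, fully testable
implementation of that color-to-thickness inversion.

## The model

Successive reflections inside a film of thickness $d$ (index $n_m$,
refraction angle $\beta$) are separated by the optical path difference
$\mathrm{OPD} = 2 n_m d \cos\beta$ and phase lag
$\Delta = 2\pi\,\mathrm{OPD}/\lambda$. With Fresnel power coefficients
$\mathbb{R}_{ij}, \mathbb{T}_{ij}$ at the air(1)–lipid(2)–aqueous(3)
interfaces, the ray reflected $m$ times inside the film carries intensity

$$I_0 = \mathbb{R}_{12} I_i,\quad
  I_1 = \mathbb{T}_{12}\mathbb{R}_{23}\mathbb{T}_{21} I_i,\quad
  I_m = \mathbb{R}_{21}\mathbb{R}_{23} I_{m-1}\ (m>1),$$

and the reflected spectrum is the squared magnitude of the coherent sum
$\sum_m s_m \sqrt{I_m}\,e^{im\Delta}$ (signs $s_m$ from the Fresnel
amplitudes, so a vanishing film is destructive and dark), averaged over
polarization. Weighting by a 6500 K illuminant and the CIE 1964
10° standard observer over 360–830 nm gives one RGB color per thickness —
a lookup table over 0–240 nm in 1-nm steps. The video pipeline then:

1. drops blink frames (global brightness above
   `mode + 0.33 (max − mode)`),
2. finds the pupil by seeded flood fill from the darkest 21×21 window,
   refines it by blur + re-fill, and estimates the iris radius from
   orientation-filtered Canny edges,
3. extracts the region of interest on the inferior iris (within 80% of
   the iris radius, below the eye center),
4. subtracts the mean iris color sampled outside the ROI,
5. white-balances against the sclera,
6. assigns every ROI pixel the nearest LUT color's thickness (Euclidean
   RGB distance, ties toward thinner films),

and reports per-frame and pooled statistics, a 50×50 surface grid and an
RGB scatter. See `vignette("tearfilm-methods")` for assumptions,
parameters and limitations.

## Worked example

No clinical recordings are distributed; the package ships a labeled
synthetic scene generator used for all validation. A 75-frame video of an
eye carrying a uniform 70-nm film, analyzed end to end:

```r
library(tearfilm)
lut  <- build_lut()                                   # thickness -> RGB table
spec <- scene_preset("patient2", seed = 42)           # uniform 70 nm film
vid  <- render_video(spec, 75, lut)
an   <- analyze_video(vid$frames, lut,
                      expected_radius = 90,           # iris radius at this zoom
                      blur_sigma = 2)
print(an)
#> tear-film LLT analysis: 75/75 frames used
#> pooled LLT: 68.2 +/- 2.9 nm over 317788 pixels
head(round(an$summary$per_frame, 2), 3)
#>   frame_index time_s mean_nm sd_nm n_pixels
#> 0           0   0.00   68.08  2.93     4231
#> 1           1   0.03   68.20  2.82     4274
#> 2           2   0.07   68.19  2.86     4231
```

The pooled estimate of 68.2 nm recovers the true 70-nm film to within the
noise-induced bias of the correction chain (camera noise σ = 3 counts per
channel); per-frame means are stable to a few tenths of a nanometer. With
`out_dir =` set, `analyze_video()` writes `stats.csv`, per-frame
histograms, the surface grid, the RGB scatter, 16-bit thickness rasters
and the resolved configuration.

Real recordings enter as a directory of numbered PNG/TIFF frames
(`read_frames()`); at the native zoom of a 480-pixel-diameter iris the
geometry defaults (`expected_radius = 240`, `blur_sigma = 5`) apply. A
thin command-line wrapper ships in `inst/cli/tearfilm.R`
(`build-lut`, `simulate`, `analyze`).

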
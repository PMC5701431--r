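# Shared fixtures: one default lookup table for the whole suite (cheap to
# build, ~0.1 s) and the geometry parameters matched to the synthetic zoom
# (iris radius 90 px instead of the full-resolution 240 px default).

test_lut <- build_lut()

# analysis parameters for the synthetic scene scale
syn_geo <- list(expected_radius = 90, blur_sigma = 2)

syn_geometry <- function(img, ...) {
  eye_geometry(img, expected_radius = syn_geo$expected_radius,
               blur_sigma = syn_geo$blur_sigma, ...)
}

syn_analyze <- function(frames, lut = test_lut, ...) {
  analyze_video(frames, lut, expected_radius = syn_geo$expected_radius,
                blur_sigma = syn_geo$blur_sigma, ...)
}
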
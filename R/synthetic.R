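# Ground-truth-labeled synthetic eye videos.
#
# The renderer composites, independently of the analysis code paths, the
# elements the pipeline must cope with: a bright sclera, a textured iris
# annulus, a dark pupil, an interference-colored band on the inferior iris
# rendered through a supplied lookup table, optional eyelid occluders and
# eyelash streaks, an additive iris tint on the band, per-channel
# illumination gains, blink frames (global brightening), camera noise and
# 8-bit quantization. Every frame comes with its true geometry and
# per-pixel thickness labels.

#' Specify a synthetic eye scene
#'
#' @param height,width frame size in pixels (default 240 x 320).
#' @param center eye center `c(row, col)`; default the image center.
#' @param center_path optional `function(frame_index)` returning the
#'   per-frame eye center (0-based index); overrides `center`.
#' @param pupil_radius,iris_radius radii in pixels; must satisfy
#'   `pupil_radius < iris_radius < min(height, width) / 2`.
#' @param iris_color base iris RGB; also the tint added to the band.
#' @param iris_texture_sd Gaussian texture amplitude on the iris (applied
#'   equally to all channels, emulating crypt structure).
#' @param sclera_color intrinsic sclera RGB before illumination.
#' @param pupil_color pupil RGB.
#' @param thickness_field `function(dr, dc)` mapping offsets from the eye
#'   center (pixels; `dr > 0` is below center) to lipid thickness in nm
#'   within `[0, 240]`; see [constant_field()], [gradient_field()],
#'   [patchy_field()].
#' @param band_outer outer limit of the interference band as a fraction of
#'   the iris radius (default 0.72, comfortably inside the 80% analysis
#'   circle).
#' @param illumination_gains per-channel scene tint (multiplied into the
#'   ideal colors; the pipeline's white balancing must undo it).
#' @param blink_frames 0-based indices of frames rendered as blinks.
#' @param blink_strength fraction of the remaining headroom to white added
#'   on a blink (default 0.7).
#' @param noise_sd per-channel Gaussian camera noise on the 8-bit scale
#'   (default 3).
#' @param eyelids logical; draw horizontal eyelid occluders over the top
#'   and bottom iris arcs.
#' @param eyelid_gap half-opening of the lids as a fraction of the iris
#'   radius (default 0.85).
#' @param eyelid_color eyelid (skin) RGB.
#' @param eyelashes logical; draw thin dark streaks across the band to
#'   exercise the shadow-exclusion rule.
#' @param seed RNG seed making rendering bit-reproducible.
#' @param fps nominal frame rate.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 240, width = 320,
                       center = NULL, center_path = NULL,
                       pupil_radius = 36, iris_radius = 90,
                       iris_color = c(60, 40, 30), iris_texture_sd = 4,
                       sclera_color = c(255, 255, 255),
                       pupil_color = c(10, 10, 10),
                       thickness_field = constant_field(70),
                       band_outer = 0.72,
                       illumination_gains = c(0.78, 0.75, 0.80),
                       blink_frames = integer(0), blink_strength = 0.7,
                       noise_sd = 3,
                       eyelids = FALSE, eyelid_gap = 0.85,
                       eyelid_color = c(170, 130, 110),
                       eyelashes = FALSE,
                       seed = 1L, fps = 30) {
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (!(pupil_radius < iris_radius && iris_radius < min(height, width) / 2))
    tf_error("need pupil_radius < iris_radius < min(height, width) / 2",
             "tf_bad_input")
  if (any(illumination_gains <= 0))
    tf_error("illumination gains must be positive", "tf_bad_input")
  structure(list(height = height, width = width, center = center,
                 center_path = center_path, pupil_radius = pupil_radius,
                 iris_radius = iris_radius, iris_color = iris_color,
                 iris_texture_sd = iris_texture_sd,
                 sclera_color = sclera_color, pupil_color = pupil_color,
                 thickness_field = thickness_field, band_outer = band_outer,
                 illumination_gains = illumination_gains,
                 blink_frames = as.integer(blink_frames),
                 blink_strength = blink_strength, noise_sd = noise_sd,
                 eyelids = eyelids, eyelid_gap = eyelid_gap,
                 eyelid_color = eyelid_color, eyelashes = eyelashes,
                 seed = as.integer(seed), fps = fps),
            class = "scene_spec")
}

#' Thickness fields for synthetic scenes
#'
#' `constant_field` gives a uniform lipid layer; `gradient_field` thickens
#' toward the lower lid (`base + slope * dr`); `patchy_field` adds a smooth
#' sinusoidal modulation. All clamp to `[0, 240]` nm.
#'
#' @param value,base thickness in nm.
#' @param slope nm per pixel of downward offset.
#' @param amplitude,scale modulation amplitude (nm) and length scale (px).
#' @return a `function(dr, dc)` usable as a `thickness_field`.
#' @export
constant_field <- function(value) {
  force(value)
  function(dr, dc) rep(clamp(value, 0, 240), length(dr))
}

#' @rdname constant_field
#' @export
gradient_field <- function(base = 30, slope = 0.6) {
  force(base); force(slope)
  function(dr, dc) clamp(base + slope * dr, 0, 240)
}

#' @rdname constant_field
#' @export
patchy_field <- function(base = 70, amplitude = 20, scale = 15) {
  force(base); force(amplitude); force(scale)
  function(dr, dc)
    clamp(base + amplitude * sin(dr / scale) * cos(dc / scale), 0, 240)
}

scene_center <- function(spec, frame_index) {
  if (is.null(spec$center_path)) spec$center
  else spec$center_path(frame_index)
}

# Iris texture as a reproducible field over offsets from the eye center, so
# it translates rigidly with the eye.
scene_texture <- function(spec) {
  r <- ceiling(spec$iris_radius)
  n <- 2L * r + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  matrix(rnorm(n * n, 0, spec$iris_texture_sd), n, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Render one synthetic frame with ground-truth labels
#'
#' @param spec a [scene_spec()].
#' @param frame_index 0-based frame number.
#' @param lut a `color_lut` used to color the interference band.
#' @return list with `frame` (a [tf_frame()]) and `labels`: `eye_center`,
#'   `pupil_radius`, `iris_radius`, `blink`, logical `roi` (the analyzable
#'   band region), `thickness` (H x W raster, NA outside the band),
#'   `iris_color`, `illumination_gains`.
#' @export
render_frame <- function(spec, frame_index, lut) {
  h <- spec$height; w <- spec$width
  ctr <- scene_center(spec, frame_index)
  dr <- matrix(seq_len(h) - ctr[1], h, w)
  dc <- matrix(seq_len(w) - ctr[2], h, w, byrow = TRUE)
  dist <- sqrt(dr^2 + dc^2)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- spec$sclera_color[ch]

  # iris annulus with rigid texture
  iris <- dist > spec$pupil_radius & dist <= spec$iris_radius
  tex <- scene_texture(spec)
  r0 <- ceiling(spec$iris_radius) + 1L
  ti <- clamp(round(dr) + r0, 1, nrow(tex))
  tj <- clamp(round(dc) + r0, 1, ncol(tex))
  tval <- matrix(tex[cbind(as.vector(ti), as.vector(tj))], h, w)
  # ideal (pre-sensor) radiance is not clamped; only the final 8-bit
  # quantization saturates
  for (ch in 1:3)
    img[, , ch][iris] <- pmax(spec$iris_color[ch] + tval[iris], 0)

  # interference band on the inferior iris
  band <- dr > 0 & dist <= spec$band_outer * spec$iris_radius &
    dist > spec$pupil_radius
  thickness <- matrix(NA_real_, h, w)
  if (any(band)) {
    tvals <- spec$thickness_field(dr[band], dc[band])
    if (any(tvals < 0 | tvals > 240))
      tf_error("thickness field leaves [0, 240] nm", "tf_bad_input")
    thickness[band] <- tvals
    cols <- lut_color_at(lut, tvals)
    for (ch in 1:3)
      img[, , ch][band] <- cols[, ch] + spec$iris_color[ch]
  }

  # pupil
  pupil <- dist <= spec$pupil_radius
  for (ch in 1:3) img[, , ch][pupil] <- spec$pupil_color[ch]

  # eyelash streaks through the band
  lash <- matrix(FALSE, h, w)
  if (spec$eyelashes) {
    for (off in c(-25, 0, 25)) {
      lash <- lash | (band & abs((dc - off) - 0.35 * dr) <= 1)
    }
    for (ch in 1:3) img[, , ch][lash] <- 5
  }

  # eyelid occluders on top
  if (spec$eyelids) {
    lid <- abs(dr) > spec$eyelid_gap * spec$iris_radius
    for (ch in 1:3) img[, , ch][lid] <- spec$eyelid_color[ch]
    band <- band & !lid
    thickness[lid] <- NA_real_
  }

  # illumination tint, blink brightening, camera noise, quantization
  for (ch in 1:3) img[, , ch] <- img[, , ch] * spec$illumination_gains[ch]
  blink <- frame_index %in% spec$blink_frames
  if (blink) img <- 255 - (255 - img) * (1 - spec$blink_strength)
  old <- .Random.seed_save()
  set.seed(spec$seed + 1009L * (frame_index + 1L))
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  .Random.seed_restore(old)
  img <- clamp(round(img))

  roi <- band & abs(dc) <= 0.8 * 0.8 * spec$iris_radius & !lash
  list(frame = tf_frame(img, index = as.integer(frame_index),
                        fps = spec$fps),
       labels = list(eye_center = c(row = ctr[1], col = ctr[2]),
                     pupil_radius = spec$pupil_radius,
                     iris_radius = spec$iris_radius,
                     blink = blink, roi = roi, thickness = thickness,
                     iris_color = spec$iris_color,
                     illumination_gains = spec$illumination_gains))
}

#' Render a labeled synthetic video
#'
#' @param spec a [scene_spec()].
#' @param n_frames number of frames (default 75, i.e. a 2.5 s analysis
#'   window at 30 frames/s).
#' @param lut a `color_lut`.
#' @param out_dir optional directory: frames are written as numbered PNGs
#'   together with a machine-readable `labels.json` (geometry, blink flags
#'   and per-frame mean true thickness; the full rasters stay in the
#'   returned object).
#' @return list with `frames` (list of [tf_frame()]) and `labels` (one
#'   label list per frame, as in [render_frame()]).
#' @export
render_video <- function(spec, n_frames = 75L, lut, out_dir = NULL) {
  if (n_frames < 1) tf_error("n_frames must be >= 1", "tf_bad_input")
  rendered <- lapply(seq_len(n_frames) - 1L,
                     function(i) render_frame(spec, i, lut))
  frames <- lapply(rendered, `[[`, "frame")
  labels <- lapply(rendered, `[[`, "labels")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_frames(frames, out_dir)
    slim <- lapply(seq_along(labels), function(i) {
      l <- labels[[i]]
      list(frame = i - 1L, time = frames[[i]]$time,
           eye_center = unname(l$eye_center),
           pupil_radius = l$pupil_radius, iris_radius = l$iris_radius,
           blink = l$blink, roi_pixels = sum(l$roi),
           mean_thickness_nm = mean(l$thickness[l$roi]))
    })
    jsonlite::write_json(slim, file.path(out_dir, "labels.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(frames = frames, labels = labels, spec = spec)
}

#' Preset synthetic scenes
#'
#' `"patient1"`, `"patient2"`, `"patient3"` carry uniform lipid layers of
#' 45, 70 and 95 nm (thin, normal and thick films mirroring hyposecretory,
#' unaffected and hypersecretory meibomian-gland states at the level a
#' synthetic test can represent); `"blinky"` inserts five blink bursts;
#' `"moving"` translates the eye along a smooth path (at most 10 px/frame)
#' under eyelid occluders; `"gradient"` thickens toward the lower lid;
#' `"lashes"` adds eyelash streaks.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @param ... overrides passed on to [scene_spec()].
#' @return a [scene_spec()].
#' @export
scene_preset <- function(preset = c("patient1", "patient2", "patient3",
                                    "blinky", "moving", "gradient",
                                    "lashes"),
                         seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    patient1 = list(thickness_field = constant_field(45)),
    patient2 = list(thickness_field = constant_field(70)),
    patient3 = list(thickness_field = constant_field(95)),
    blinky = list(blink_frames = c(10:12, 25:27, 40:41, 55:57, 68:70)),
    moving = list(eyelids = TRUE,
                  center_path = function(i)
                    c(120.5 + 12 * sin(2 * pi * i / 50),
                      160.5 + 18 * sin(2 * pi * i / 37 + 1))),
    gradient = list(thickness_field = gradient_field(30, 0.6),
                    noise_sd = 0),
    lashes = list(eyelashes = TRUE))
  do.call(scene_spec, utils::modifyList(c(base, list(seed = seed)),
                                        list(...)))
}
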
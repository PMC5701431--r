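# End-to-end analysis: blink filtering, per-frame geometry and ROI, color
# correction, thickness mapping, statistics and file outputs.

#' Analyze an eye video
#'
#' Runs the full six-phase pipeline over a frame sequence: frames brighter
#' than the blink threshold are discarded; each retained frame gets pupil /
#' eye-center / iris-radius geometry and an inferior-iris ROI (frames whose
#' geometry or ROI cannot be validated are dropped as occluded); ROI pixels
#' are corrected for iris color and illumination bias and mapped to
#' thicknesses through the lookup table; per-frame and pooled statistics,
#' a 50 x 50 surface grid (middle mapped frame) and an RGB scatter pooled
#' from three consecutive frames are computed.
#'
#' @param frames list of [tf_frame()] objects (see [read_frames()]).
#' @param lut a `color_lut` from [build_lut()] or [read_lut()].
#' @param blink_coef blink-filter coefficient (default 0.33).
#' @param expected_radius approximate iris radius in pixels at this zoom.
#' @param pupil_threshold,refine_threshold,blur_sigma,window,angular_tol,band,fill_threshold
#'   geometry parameters, see [eye_geometry()].
#' @param shadow_floor eyelash-shadow brightness floor, see [map_frame()].
#' @param bin_width histogram bin width in nm.
#' @param gains_mode `"first_frame"` (estimate sclera gains once, on the
#'   first valid frame) or `"per_frame"`.
#' @param out_dir optional output directory; when given, writes
#'   `stats.csv`, `histogram.json`, `selection_report.csv`,
#'   `correction_report.csv`, `surface_<frame>.csv`, `scatter.csv`,
#'   per-frame `llt_map_<frame>.tif` (16-bit, nm values, sentinel 65535)
#'   and the resolved `config.txt`.
#' @return list of class `llt_analysis` with `summary`
#'   (a `sequence_stats`), `frame_stats`, `maps`, `geometry`, `selection`,
#'   `correction` (per-frame iris color, sclera white, gains), `surface`,
#'   `scatter`, `config`.
#' @export
analyze_video <- function(frames, lut, blink_coef = 0.33,
                          expected_radius = 240,
                          pupil_threshold = 5, refine_threshold = 3,
                          blur_sigma = 5, window = 21L,
                          angular_tol = 15, band = c(0.8, 1.2),
                          fill_threshold = 25,
                          shadow_floor = 10, bin_width = 10,
                          gains_mode = c("first_frame", "per_frame"),
                          out_dir = NULL) {
  gains_mode <- match.arg(gains_mode)
  sel <- select_frames(frames, blink_coef)
  report <- sel$report

  maps <- list(); stats <- list(); geoms <- list(); corr <- list()
  gains <- NULL; sclera_white <- NULL
  for (fr in sel$frames) {
    res <- tryCatch({
      geom <- eye_geometry(fr$img, expected_radius = expected_radius,
                           pupil_threshold = pupil_threshold,
                           refine_threshold = refine_threshold,
                           blur_sigma = blur_sigma, window = window,
                           angular_tol = angular_tol, band = band,
                           fill_threshold = fill_threshold)
      roi <- extract_roi(fr$img, geom$eye_center, geom$iris_radius,
                         geom$pupil_mask)
      iris_col <- estimate_iris_color(fr$img, geom$eye_center,
                                      geom$iris_radius, roi$mask,
                                      geom$pupil_mask)
      if (is.null(gains) || gains_mode == "per_frame") {
        scl <- sample_sclera(fr$img, geom$eye_center, geom$iris_radius)
        sclera_white <- scl$color
        gains <- estimate_illumination_gains(scl$color)
      }
      px <- correct_roi(fr$img, roi$mask, iris_col, gains)
      m <- map_frame(px, roi$mask, lut, shadow_floor,
                     frame_index = fr$index)
      st <- frame_statistics(m, bin_width = bin_width, time = fr$time)
      list(geom = geom, map = m, stats = st,
           corr = data.frame(frame_index = fr$index,
                             iris_R = iris_col[1], iris_G = iris_col[2],
                             iris_B = iris_col[3],
                             sclera_R = sclera_white[1],
                             sclera_G = sclera_white[2],
                             sclera_B = sclera_white[3],
                             gain_R = gains[1], gain_G = gains[2],
                             gain_B = gains[3]))
    }, tearfilm_error = function(e) e)
    if (inherits(res, "tearfilm_error")) {
      i <- which(report$index == fr$index)
      report$kept[i] <- FALSE
      report$reason[i] <- conditionMessage(res)
      next
    }
    key <- as.character(fr$index)
    maps[[key]] <- res$map
    stats[[key]] <- res$stats
    geoms[[key]] <- res$geom
    corr[[key]] <- res$corr
  }
  if (length(maps) == 0)
    tf_error("no frames survived geometry validation", "tf_no_frames")

  summary <- sequence_statistics(stats)
  mid <- (length(maps) + 1L) %/% 2L
  surf <- surface_grid(maps[[mid]])
  sc_idx <- clamp(c(mid - 1L, mid, mid + 1L), 1L, length(maps))
  scatter <- suppressWarnings(rgb_scatter(maps[unique(sc_idx)]))
  config <- list(blink_coef = blink_coef, expected_radius = expected_radius,
                 pupil_threshold = pupil_threshold,
                 refine_threshold = refine_threshold,
                 blur_sigma = blur_sigma, window = window,
                 angular_tol = angular_tol, band_low = band[1],
                 band_high = band[2], fill_threshold = fill_threshold,
                 shadow_floor = shadow_floor, bin_width = bin_width,
                 gains_mode = gains_mode,
                 sd_definition = "population SD of pooled pixels")
  out <- structure(list(summary = summary, frame_stats = stats, maps = maps,
                        geometry = geoms, selection = report,
                        correction = do.call(rbind, corr),
                        surface = surf, surface_frame = maps[[mid]]$frame_index,
                        scatter = scatter, config = config),
                   class = "llt_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

write_analysis <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$summary$per_frame, file.path(out_dir, "stats.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(x$selection, file.path(out_dir, "selection_report.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(x$correction))
    write.csv(x$correction, file.path(out_dir, "correction_report.csv"),
              row.names = FALSE, quote = FALSE)
  hist <- lapply(x$frame_stats, function(st)
    list(frame_index = st$frame_index, time_s = st$time,
         breaks_nm = st$breaks, rel_freq = st$rel_freq))
  jsonlite::write_json(unname(hist), file.path(out_dir, "histogram.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(x$surface,
                     file.path(out_dir,
                               sprintf("surface_%04d.csv", x$surface_frame)),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  write.csv(x$scatter, file.path(out_dir, "scatter.csv"),
            row.names = FALSE, quote = FALSE)
  for (m in x$maps) {
    raster <- m$thickness
    raster[is.na(raster)] <- 65535
    tiff::writeTIFF(raster / 65535,
                    file.path(out_dir,
                              sprintf("llt_map_%04d.tif", m$frame_index)),
                    bits.per.sample = 16L)
  }
  cfg <- x$config
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            character(1))),
             file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

#' @export
print.llt_analysis <- function(x, ...) {
  cat(sprintf("tear-film LLT analysis: %d/%d frames used\n",
              x$summary$n_frames, nrow(x$selection)))
  cat(sprintf("pooled LLT: %.1f +/- %.1f nm over %d pixels\n",
              x$summary$mean_llt, x$summary$sd_llt, x$summary$n_pixels))
  invisible(x)
}
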
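# Frame containers and image sequence I/O.
#
# A frame is a list(index, time, img) where `index` is the 0-based position
# in the recording (time = index / fps) and `img` an H x W x 3 numeric array
# on the 8-bit scale, rows increasing downward. A frame sequence is a plain
# list of frames, in order.

#' Construct a video frame
#'
#' @param img numeric `H x W x 3` array, channels in `[0, 255]`.
#' @param index 0-based frame number in the recording.
#' @param fps frames per second (default 30); the timestamp is
#'   `index / fps`.
#' @return a list of class `tf_frame` with fields `index`, `time`, `img`.
#' @export
tf_frame <- function(img, index = 0L, fps = 30) {
  check_rgb_array(img)
  if (any(img < 0) || any(img > 255))
    tf_error("frame channels must lie in [0, 255]", "tf_bad_input")
  structure(list(index = as.integer(index), time = index / fps,
                 img = img, fps = fps),
            class = "tf_frame")
}

#' Read a directory of numbered image frames
#'
#' Loads sequentially numbered 8-bit PNG or TIFF frames (sorted by file
#' name) as a frame sequence. Video containers are not read directly:
#' extract frames to numbered images first (e.g. with ffmpeg).
#'
#' @param dir directory containing the frames.
#' @param fps frames per second used to derive timestamps (default 30).
#' @param pattern file-name regular expression (default PNG/TIFF).
#' @return a list of [tf_frame()] objects.
#' @export
read_frames <- function(dir, fps = 30, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0)
    tf_error(sprintf("no frames matching '%s' in %s", pattern, dir),
             "tf_bad_input")
  lapply(seq_along(files), function(i) {
    x <- if (grepl("\\.png$", files[i], ignore.case = TRUE)) {
      png::readPNG(files[i])
    } else {
      tiff::readTIFF(files[i])
    }
    if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
    if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
    tf_frame(x * 255, index = i - 1L, fps = fps)
  })
}

#' Write a frame sequence as numbered PNG files
#'
#' @param frames list of [tf_frame()] objects.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the written paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(frames, function(fr) {
    p <- file.path(dir, sprintf("%s_%04d.png", prefix, fr$index))
    png::writePNG(fr$img / 255, p)
    p
  }, character(1))
  invisible(paths)
}
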
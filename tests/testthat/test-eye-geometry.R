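# Pupil/eye-center localization, iris radius and ROI construction.

test_that("darkest-window search ties break to the top-left and match a scan", {
  u <- matrix(80, 40, 40)
  expect_equal(as.vector(find_darkest_seed(u, 21)), c(11, 11))
  set.seed(31)
  for (i in 1:5) {
    b <- matrix(runif(1600, 0, 255), 40, 40)
    expect_equal(as.vector(find_darkest_seed(b, 7)),
                 scan_darkest_window(b, 7))
  }
  expect_error(find_darkest_seed(matrix(0, 10, 10), 21),
               class = "tf_bad_input")
})

disk_mask <- function(h, w, ctr, r) {
  dr <- matrix(seq_len(h) - ctr[1], h, w)
  dc <- matrix(seq_len(w) - ctr[2], h, w, byrow = TRUE)
  dr^2 + dc^2 <= r^2
}

test_that("pupil refinement recovers the center of a ragged disk", {
  set.seed(41)
  h <- 101; w <- 101; ctr <- c(51, 51)
  disk <- disk_mask(h, w, ctr, 20)
  b <- matrix(120, h, w)
  b[disk] <- 10
  # ragged boundary: flip a noisy annulus
  ann <- disk_mask(h, w, ctr, 23) & !disk_mask(h, w, ctr, 17)
  flip <- ann & matrix(runif(h * w) < 0.5, h, w)
  b[flip] <- ifelse(b[flip] > 60, 10, 120)
  coarse <- flood_fill(b, c(51, 51), 5)
  ref <- refine_pupil(b, coarse, c(51, 51), blur_sigma = 3)
  expect_lt(sqrt(sum((ref$centroid - ctr)^2)), 2)
  # the refined boundary is no more ragged than the coarse one
  expect_lte(raggedness(ref$mask), raggedness(coarse))
  # centroid equals the first-moment oracle of the mask
  idx <- which(ref$mask, arr.ind = TRUE)
  expect_equal(unname(ref$centroid),
               c(mean(idx[, 1]), mean(idx[, 2])))
})

test_that("an already smooth disk keeps its centroid through refinement", {
  h <- 101; w <- 101; ctr <- c(51, 51)
  b <- matrix(120, h, w)
  b[disk_mask(h, w, ctr, 20)] <- 10
  coarse <- flood_fill(b, c(51, 51), 5)
  ref <- refine_pupil(b, coarse, c(51, 51), blur_sigma = 3)
  expect_lt(sqrt(sum((ref$centroid - mask_centroid_oracle(coarse))^2)), 0.5)
})


test_that("the eye-center fallback rule is inclusive at the boundary", {
  p <- c(50, 50)
  expect_equal(unname(choose_eye_center(p, p, 10)), c(50, 50))
  seedpt <- c(50, 62)
  # distance 12: just above a max_distance of 11.9 -> fall back to the seed
  expect_equal(unname(choose_eye_center(p, seedpt, 11.9)), c(50, 62))
  # distance exactly at max_distance -> keep the centroid
  expect_equal(unname(choose_eye_center(p, seedpt, 12)), c(50, 50))
})

test_that("iris radius is recovered within 5%, with and without eyelids", {
  for (lids in c(FALSE, TRUE)) {
    spec <- scene_preset("patient2", seed = 13, eyelids = lids)
    rf <- render_frame(spec, 0, test_lut)
    g <- syn_geometry(rf$frame$img)
    expect_lt(abs(g$iris_radius - 90) / 90, 0.05)
    expect_lt(sqrt(sum((g$eye_center - rf$labels$eye_center)^2)), 3)
  }
})

test_that("kept boundary pixels average to the reported radius", {
  spec <- scene_preset("patient2", seed = 13)
  rf <- render_frame(spec, 0, test_lut)
  g <- syn_geometry(rf$frame$img)
  ir <- estimate_iris_radius(rf$frame$img, g$eye_center,
                             expected_radius = 90)
  expect_equal(ir$radius, mean(ir$points[, "dist"]))
  expect_error(estimate_iris_radius(matrix(100, 50, 50), c(25, 25), 20),
               class = "tf_iris_not_found")
})

test_that("every ROI pixel satisfies the four defining conditions", {
  spec <- scene_preset("patient2", seed = 19)
  rf <- render_frame(spec, 0, test_lut)
  img <- rf$frame$img
  g <- syn_geometry(img)
  roi <- extract_roi(img, g$eye_center, g$iris_radius, g$pupil_mask)
  b <- pixel_brightness(img)
  idx <- which(roi$mask, arr.ind = TRUE)
  dr <- idx[, 1] - g$eye_center[1]
  dc <- idx[, 2] - g$eye_center[2]
  r_in <- 0.8 * g$iris_radius
  expect_true(all(dr^2 + dc^2 <= r_in^2))            # (a) inner circle
  expect_true(all(dr > 0))                           # (b) below center
  expect_true(all(abs(dc) <= 0.8 * r_in))            # (c) lateral crop
  expect_true(all(b[roi$mask] >= roi$mean_brightness))  # (d) brightness
  expect_false(any(roi$mask & g$pupil_mask))
  # nothing above the center row
  expect_false(any(idx[, 1] <= g$eye_center[1]))
})

test_that("degenerate geometry yields an empty-ROI error", {
  img <- array(120, dim = c(60, 60, 3))
  expect_error(extract_roi(img, c(60, 30), 40), class = "tf_empty_roi")
})

test_that("ROI size is invariant under whole-pixel translation of the eye", {
  counts <- vapply(c(0, 7), function(shift) {
    spec <- scene_preset("patient2", seed = 29, noise_sd = 0,
                         center = c(110.5 + shift, 150.5 + shift))
    rf <- render_frame(spec, 0, test_lut)
    g <- syn_geometry(rf$frame$img)
    extract_roi(rf$frame$img, g$eye_center, g$iris_radius,
                g$pupil_mask)$pixel_count
  }, numeric(1))
  expect_equal(counts[1], counts[2])
})

test_that("geometry is deterministic for identical frames", {
  spec <- scene_preset("patient1", seed = 37)
  rf <- render_frame(spec, 5, test_lut)
  g1 <- syn_geometry(rf$frame$img)
  g2 <- syn_geometry(rf$frame$img)
  expect_identical(g1$pupil_mask, g2$pupil_mask)
  expect_identical(g1$eye_center, g2$eye_center)
  expect_identical(g1$iris_radius, g2$iris_radius)
})
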
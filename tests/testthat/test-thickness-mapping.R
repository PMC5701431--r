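# Nearest-color inversion and statistical outputs.

test_that("exact LUT colors return their own thickness and ties go thin", {
  expect_equal(assign_thickness(unlist(test_lut[71, c("R", "G", "B")]),
                                test_lut), 70)
  # hand-built integer LUT with an exactly equidistant pixel
  toy <- structure(data.frame(thickness_nm = c(10, 20),
                              R = c(100, 104), G = c(50, 50), B = c(50, 50)),
                   class = c("color_lut", "data.frame"))
  expect_equal(assign_thickness(c(102, 50, 50), toy), 10)
})

test_that("assignment agrees with the exhaustive linear-scan oracle", {
  set.seed(47)
  px <- matrix(runif(3000, 0, 255), ncol = 3)
  expect_equal(assign_thickness(px, test_lut),
               unname(scan_nearest_thickness(px, test_lut)))
})

test_that("a LUT-rendered field is recovered exactly and noise degrades gracefully", {
  set.seed(53)
  mask <- matrix(FALSE, 40, 40)
  mask[10:35, 5:36] <- TRUE
  truth <- sample(seq(20, 120, by = 1), sum(mask), replace = TRUE)
  px <- tearfilm:::lut_color_at(test_lut, truth)
  m <- map_frame(px, mask, test_lut)
  expect_equal(m$values, truth)
  expect_equal(sum(!is.na(m$thickness)), sum(mask))
  # per-channel noise sigma = 2: accuracy set by the LUT's local color speed
  for (mu in c(45, 70, 95)) {
    tr <- rep(mu, sum(mask))
    noisy <- tearfilm:::lut_color_at(test_lut, tr) +
      matrix(rnorm(3 * sum(mask), 0, 2), ncol = 3)
    th <- map_frame(noisy, mask, test_lut)$values
    expect_gt(mean(abs(th - mu) <= 2), 0.85)
    expect_lt(mean(abs(th - mu)), 1.5)
  }
})

test_that("an all-black ROI is rejected as shadow", {
  mask <- matrix(TRUE, 5, 5)
  px <- matrix(0, 25, 3)
  expect_error(map_frame(px, mask, test_lut), class = "tf_empty_roi")
})

test_that("frame statistics match closed forms and a two-pass oracle", {
  mask <- matrix(c(rep(TRUE, 100), rep(FALSE, 0)), 10, 10)
  m <- map_frame(tearfilm:::lut_color_at(test_lut, rep(70, 100)), mask,
                 test_lut)
  st <- frame_statistics(m)
  expect_equal(st$mean_llt, 70)
  expect_equal(st$sd_llt, 0)
  expect_equal(sum(st$rel_freq), 1)
  expect_equal(st$rel_freq[st$breaks[-length(st$breaks)] == 70], 1)

  two <- map_frame(tearfilm:::lut_color_at(test_lut, rep(c(60, 80), 50)),
                   mask, test_lut)
  st2 <- frame_statistics(two)
  expect_equal(st2$mean_llt, 70)
  expect_equal(st2$sd_llt, 10)  # population SD

  set.seed(59)
  vals <- sample(0:240, 100, replace = TRUE)
  st3 <- frame_statistics(map_frame(tearfilm:::lut_color_at(test_lut, vals),
                                    mask, test_lut))
  s1 <- sum(vals); s2 <- sum(vals^2)  # streaming two-pass oracle
  expect_equal(st3$mean_llt, s1 / 100)
  expect_equal(st3$sd_llt, sqrt(s2 / 100 - (s1 / 100)^2))
  expect_equal(sum(st3$rel_freq), 1)
})

test_that("pooled statistics equal flattening all pixels", {
  mask <- matrix(TRUE, 10, 10)
  mk <- function(vals, idx)
    frame_statistics(map_frame(tearfilm:::lut_color_at(test_lut, vals),
                               mask, test_lut, frame_index = idx))
  set.seed(61)
  v1 <- sample(10:200, 100, replace = TRUE)
  v2 <- sample(10:200, 100, replace = TRUE)
  pooled <- sequence_statistics(list(mk(v1, 0), mk(v2, 1)))
  allv <- c(v1, v2)
  expect_equal(pooled$mean_llt, mean(allv))
  expect_equal(pooled$sd_llt, sqrt(mean((allv - mean(allv))^2)))
  expect_equal(pooled$n_pixels, 200)
  # equal pixel counts: pooled mean is the mean of frame means
  expect_equal(pooled$mean_llt, mean(c(mean(v1), mean(v2))))
  single <- sequence_statistics(list(mk(v1, 0)))
  expect_equal(single$mean_llt, mean(v1))
})

test_that("surface grids cover small ROIs and preserve structure", {
  mask <- matrix(FALSE, 60, 60)
  mask[20:49, 15:44] <- TRUE  # 30 x 30 block, smaller than the grid
  vals <- rep(70, sum(mask))
  m <- map_frame(tearfilm:::lut_color_at(test_lut, vals), mask, test_lut)
  g <- surface_grid(m)
  expect_equal(dim(g), c(50, 50))
  expect_true(all(g == 70))
  # vertical gradient: row means increase downward
  idx <- which(mask, arr.ind = TRUE)
  grad <- clamp(round(30 + 2 * (idx[, 1] - 20)), 0, 240)
  mg <- map_frame(tearfilm:::lut_color_at(test_lut, grad), mask, test_lut)
  gg <- surface_grid(mg)
  rm_ <- rowMeans(gg, na.rm = TRUE)
  expect_true(all(diff(rm_) >= 0) && sum(diff(rm_) > 0) > 20)
  # every source pixel appears at least once
  expect_true(all(unique(grad) %in% unique(as.vector(gg))))
})

test_that("the RGB scatter downsamples deterministically and stays on the LUT", {
  mask <- matrix(TRUE, 50, 60)  # 3000 px per frame
  maps <- lapply(0:2, function(i) {
    vals <- rep(seq(20, 119), 30)
    map_frame(tearfilm:::lut_color_at(test_lut, vals), mask, test_lut,
              frame_index = i)
  })
  sc <- rgb_scatter(maps)
  expect_equal(nrow(sc), 3000)  # 9000 pooled, every 3rd kept
  expect_equal(assign_thickness(as.matrix(sc[, c("R", "G", "B")]), test_lut),
               sc$thickness_nm)
  expect_warning(rgb_scatter(maps[1:2]), "fewer than three")
})
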
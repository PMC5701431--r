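# Independent reference implementations used as oracles. These deliberately
# use plain scalar loops and stay independent of the package's code paths.

# Scalar stack-based flood fill (8- or 4-connectivity), strict threshold on
# the difference to the seed pixel.
bfs_flood_fill <- function(b, seed, threshold, connectivity = 8) {
  h <- nrow(b); w <- ncol(b)
  ref <- b[seed[1], seed[2]]
  mask <- matrix(FALSE, h, w)
  stack <- list(seed)
  mask[seed[1], seed[2]] <- TRUE
  dirs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in dirs) {
      q <- p + d
      if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w) next
      if (mask[q[1], q[2]]) next
      if (abs(b[q[1], q[2]] - ref) < threshold) {
        mask[q[1], q[2]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
  }
  mask
}

# Exhaustive window scan for the darkest mean-brightness window.
scan_darkest_window <- function(b, window) {
  h <- nrow(b); w <- ncol(b)
  best <- Inf; best_pos <- NULL
  for (r in seq_len(h - window + 1)) {
    for (cc in seq_len(w - window + 1)) {
      s <- mean(b[r:(r + window - 1), cc:(cc + window - 1)])
      if (s < best - 1e-12) {
        best <- s
        best_pos <- c(r, cc)
      }
    }
  }
  half <- (window - 1) %/% 2
  c(best_pos[1] + half, best_pos[2] + half)
}

# Exhaustive nearest-color scan with smaller-thickness tie-breaking.
scan_nearest_thickness <- function(px, lut) {
  cols <- as.matrix(lut[, c("R", "G", "B")])
  apply(rbind(px), 1, function(p) {
    d2 <- colSums((t(cols) - p)^2)
    lut$thickness_nm[which.min(d2)]  # which.min keeps the first minimum
  })
}

# 8-connectivity audit: every mask pixel must be reachable from the seed.
is_8_connected_to_seed <- function(mask, seed) {
  reach <- bfs_flood_fill(mask * 1, seed, 0.5, connectivity = 8)
  identical(reach, mask)
}

random_rgb_frame <- function(h, w) {
  array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
}

# mask perimeter (4-neighbor boundary count) squared over area: a
# dimensionless boundary-raggedness score.
raggedness <- function(mask) {
  per <- sum(mask & !(shift_down(mask) & shift_up(mask) &
                        shift_left(mask) & shift_right(mask)))
  per^2 / sum(mask)
}
shift_down <- function(m) rbind(FALSE, m[-nrow(m), , drop = FALSE])
shift_up <- function(m) rbind(m[-1, , drop = FALSE], FALSE)
shift_right <- function(m) cbind(FALSE, m[, -ncol(m), drop = FALSE])
shift_left <- function(m) cbind(m[, -1, drop = FALSE], FALSE)

mask_centroid_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}
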
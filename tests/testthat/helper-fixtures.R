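# Shared in-code fixtures for the test suite.

# a tile built directly in optical-density space from explicit disk positions,
# bypassing make_tile's placement logic (for constructed-geometry tests)
tile_from_disks <- function(width, height, centers, radius, amp = 1.0,
                            background = c(0.95, 0.87, 0.92)) {
  h_vec <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
  od <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) od[, , ch] <- -log10(background[ch])
  for (r in seq_len(nrow(centers))) {
    cx <- centers[r, 1]; cy <- centers[r, 2]
    for (y in max(1, floor(cy - radius)):min(height, ceiling(cy + radius))) {
      for (x in max(1, floor(cx - radius)):min(width, ceiling(cx + radius))) {
        if ((x - cx)^2 + (y - cy)^2 <= radius^2) {
          od[y, x, ] <- od[y, x, ] + amp * h_vec
        }
      }
    }
  }
  radpath::tile_image(10^(-od))
}

# rasterized pixel count of one disk of given radius at an integer centre
disk_pixel_count <- function(radius) {
  g <- expand.grid(x = -ceiling(radius):ceiling(radius),
                   y = -ceiling(radius):ceiling(radius))
  sum(g$x^2 + g$y^2 <= radius^2)
}

# solid ellipsoid mask on an isotropic grid, for shape tests
test_ellipsoid <- function(semi_axes, spacing = c(1, 1, 1), pad = 3) {
  shape <- ceiling(2 * semi_axes / spacing) + 2 * pad + 1
  cen <- (shape - 1) / 2 * spacing
  x <- (seq_len(shape[1]) - 1) * spacing[1] - cen[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2] - cen[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3] - cen[3]
  q <- outer(outer((x / semi_axes[1])^2, (y / semi_axes[2])^2, `+`),
             (z / semi_axes[3])^2, `+`)
  q <= 1
}

# constant-level cuboid as a discretized_volume
const_dvol <- function(dims = c(4, 4, 4), ng = 8) {
  make_dvol(array(1L, dim = dims), ng, values = rep(0.5, prod(dims)))
}
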
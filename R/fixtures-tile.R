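# Synthetic H&E-like histology tiles with known nucleus ground truth.
#
# Nuclei are filled ellipses in optical-density space: the tile is rendered as
# transmitted light I = 10^(-OD) with OD = eosin background + per-nucleus
# hematoxylin contributions, so stain deconvolution downstream recovers the
# hematoxylin channel exactly as it would on scanned H&E.

# Ruifrok-Johnston H&E optical-density unit vectors
HEMATOXYLIN_OD <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
EOSIN_OD <- c(0.072, 0.990, 0.105) / sqrt(sum(c(0.072, 0.990, 0.105)^2))

#' Specification of a synthetic H&E tile
#'
#' @param width_px,height_px tile size in pixels (> 0).
#' @param n_nuclei number of nuclei to draw (>= 0).
#' @param radius_mean,radius_sd nucleus radius distribution in pixels. With
#'   `radius_sd = 0` all nuclei are identical circles; otherwise radii vary and
#'   an elongation jitter proportional to `radius_sd / radius_mean` turns them
#'   into randomly oriented ellipses of equal expected area.
#' @param stain_mean,stain_sd hematoxylin stain intensity in `[0, 1]`.
#' @param background_color RGB triple in `[0, 1]` of the eosin-like background.
#' @param overlap_fraction allowed centre-distance overlap between nuclei in
#'   `[0, 1)`: 0 forbids any overlap of the nominal radii.
#' @param seed integer RNG seed; identical seeds give bit-identical tiles.
#' @return an object of class `tile_spec`.
#' @export
tile_spec <- function(width_px = 256, height_px = 256, n_nuclei = 50,
                      radius_mean = 6, radius_sd = 1,
                      stain_mean = 0.7, stain_sd = 0.1,
                      background_color = c(0.95, 0.87, 0.92),
                      overlap_fraction = 0, seed = 1) {
  stop_if_not(width_px > 0 && height_px > 0, "tile dimensions must be positive")
  stop_if_not(n_nuclei >= 0, "n_nuclei must be >= 0")
  stop_if_not(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  stop_if_not(radius_mean > 0, "radius_mean must be positive")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 n_nuclei = as.integer(n_nuclei),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 stain_mean = stain_mean, stain_sd = stain_sd,
                 background_color = background_color,
                 overlap_fraction = overlap_fraction, seed = as.integer(seed)),
            class = "tile_spec")
}

#' An RGB histology tile
#'
#' @param pixels `height x width x 3` numeric array in `[0, 1]`.
#' @param magnification nominal magnification level (e.g. 40 or 4).
#' @param origin `(x, y)` pixel offset of the tile in slide coordinates.
#' @return object of class `tile_image`.
#' @export
tile_image <- function(pixels, magnification = 40, origin = c(0L, 0L)) {
  stop_if_not(length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
              "pixels must be an H x W x 3 array")
  structure(list(pixels = pixels, magnification = magnification,
                 origin = as.integer(origin),
                 tile_size = c(dim(pixels)[2], dim(pixels)[1])),
            class = "tile_image")
}

#' @export
print.tile_image <- function(x, ...) {
  cat(sprintf("<tile_image %dx%d px, %gX, origin (%d, %d)>\n",
              x$tile_size[1], x$tile_size[2], x$magnification,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# pixel set of an ellipse on the integer grid (pixel centres at integers)
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  ra <- ceiling(max(a, b))
  xs <- max(1L, floor(cx - ra)):min(width, ceiling(cx + ra))
  ys <- max(1L, floor(cy - ra)):min(height, ceiling(cy + ra))
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - cx; dy <- g$y - cy
  if (a == b) {
    # circle: avoid the rotation so boundary pixels are orientation-invariant
    return(g[dx^2 + dy^2 <= a^2, , drop = FALSE])
  }
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  g[u^2 + v^2 <= 1, , drop = FALSE]
}

#' Render a synthetic H&E tile with ground-truth nuclei
#'
#' Draws `n_nuclei` hematoxylin-stained elliptical nuclei on an eosin-like
#' background. Nucleus centres are sampled on the integer pixel grid; with zero
#' radius spread every nucleus rasterizes to the identical disk. Placement
#' respects `overlap_fraction` by rejection sampling on centre distances; an
#' infeasible packing raises an error.
#'
#' @param spec a [tile_spec()].
#' @param magnification magnification tag attached to the tile.
#' @param origin slide-coordinate origin attached to the tile.
#' @return list with `tile` (a [tile_image()]) and `nuclei`, a data frame of
#'   ground truth (centroid, drawn radius, semi-axes, orientation, rasterized
#'   area in pixels, stain intensity).
#' @export
make_tile <- function(spec, magnification = 40, origin = c(0L, 0L)) {
  stop_if_not(inherits(spec, "tile_spec"), "spec must be a tile_spec")
  w <- spec$width_px; h <- spec$height_px; n <- spec$n_nuclei
  with_seed(spec$seed, {
    gt <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                     radius = numeric(), a = numeric(), b = numeric(),
                     theta = numeric(), area_px = numeric(), stain = numeric())
    od <- array(0, dim = c(h, w, 3))
    bg_od <- -log10(pmax(spec$background_color, 1e-3))
    for (ch in 1:3) od[, , ch] <- bg_od[ch]
    if (n > 0) {
      # feasibility: nominal disk area at zero overlap must fit loosely
      if (spec$overlap_fraction == 0 &&
          n * pi * spec$radius_mean^2 > 0.55 * w * h) {
        stop("infeasible packing: too many nuclei for tile area at overlap_fraction = 0")
      }
      radii <- pmax(1.5, rnorm(n, spec$radius_mean, spec$radius_sd))
      elong_max <- if (spec$radius_sd > 0) min(0.3, spec$radius_sd / spec$radius_mean) else 0
      elong <- runif(n, 0, elong_max)
      theta <- runif(n, 0, pi)
      stain <- pmin(1, pmax(0.05, rnorm(n, spec$stain_mean, spec$stain_sd)))
      cxs <- numeric(n); cys <- numeric(n)
      max_attempts <- 400L * n
      attempts <- 0L
      placed <- 0L
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("infeasible packing: could not place all nuclei at the requested overlap_fraction")
        }
        i <- placed + 1L
        ri <- radii[i] * (1 + elong[i])
        if (2 * ri + 2 >= min(w, h)) stop("nucleus radius too large for tile")
        cx <- sample(seq(ceiling(ri) + 1L, w - ceiling(ri) - 1L), 1L)
        cy <- sample(seq(ceiling(ri) + 1L, h - ceiling(ri) - 1L), 1L)
        ok <- TRUE
        if (placed > 0L) {
          dmin <- (radii[seq_len(placed)] + radii[i]) * (1 - spec$overlap_fraction)
          ok <- all((cxs[seq_len(placed)] - cx)^2 + (cys[seq_len(placed)] - cy)^2 >= dmin^2)
        }
        if (ok) {
          placed <- i
          cxs[i] <- cx; cys[i] <- cy
        }
      }
      for (i in seq_len(n)) {
        a <- radii[i] * (1 + elong[i]); b <- radii[i] / (1 + elong[i])
        px <- ellipse_pixels(cxs[i], cys[i], a, b, theta[i], w, h)
        amp <- 0.25 + 1.1 * stain[i]
        for (ch in 1:3) {
          idx <- cbind(px$y, px$x, ch)
          od[idx] <- od[idx] + amp * HEMATOXYLIN_OD[ch]
        }
        gt[i, ] <- list(i, cxs[i], cys[i], radii[i], a, b, theta[i], nrow(px), stain[i])
      }
    }
    pixels <- 10^(-od)
    list(tile = tile_image(pixels, magnification = magnification, origin = origin),
         nuclei = gt)
  })
}

#' Write a tile to a PNG file
#' @param tile a [tile_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tile_png <- function(tile, path) {
  png::writePNG(tile$pixels, path)
  invisible(path)
}

#' Read a tile from a PNG file
#' @param path PNG path.
#' @inheritParams tile_image
#' @return a [tile_image()].
#' @export
read_tile_png <- function(path, magnification = 40, origin = c(0L, 0L)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  tile_image(px, magnification = magnification, origin = origin)
}
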
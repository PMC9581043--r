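# Automated histology ROI selection: HSV tissue masking, stain deconvolution
# with marker-controlled watershed nuclei detection, the highest-cell-density
# tile, and HSV-histogram representative tiles.

# Ruifrok-Johnston stain matrix (rows: hematoxylin, eosin, residual)
stain_matrix_he <- function() {
  r <- c(HEMATOXYLIN_OD[2] * 0.105 - HEMATOXYLIN_OD[3] * 0.990,
         HEMATOXYLIN_OD[3] * 0.072 - HEMATOXYLIN_OD[1] * 0.105,
         HEMATOXYLIN_OD[1] * 0.990 - HEMATOXYLIN_OD[2] * 0.072)
  r <- r / sqrt(sum(r^2))
  rbind(H = HEMATOXYLIN_OD, E = EOSIN_OD, R = r)
}

rgb_to_hsv_mat <- function(pixels) {
  n <- prod(dim(pixels)[1:2])
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

#' HSV tissue mask of a tile
#'
#' A pixel is tissue when its saturation is at least `sat_min` and its value
#' (brightness) at most `val_max`, which separates stained tissue from the
#' near-white glass background.
#'
#' @param tile a [tile_image()].
#' @param sat_min minimum saturation.
#' @param val_max maximum value/brightness.
#' @return logical matrix (rows = y, cols = x); may be empty (all `FALSE`).
#' @export
tissue_mask <- function(tile, sat_min = 0.05, val_max = 0.98) {
  hsv <- rgb_to_hsv_mat(tile$pixels)
  matrix(hsv[2, ] >= sat_min & hsv[3, ] <= val_max, nrow = dim(tile$pixels)[1])
}

#' Hematoxylin optical density of a tile
#'
#' Converts RGB transmittance to optical density and deconvolves with the
#' standard H&E stain vectors, returning the hematoxylin concentration image.
#'
#' @param tile a [tile_image()].
#' @return numeric matrix (rows = y), hematoxylin OD per pixel (>= 0).
#' @export
hematoxylin_od <- function(tile) {
  px <- tile$pixels
  od <- -log10(pmax(px, 1e-3))
  odmat <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- odmat %*% solve(stain_matrix_he())
  matrix(pmax(conc[, 1], 0), nrow = dim(px)[1])
}

#' Detect nuclei on a high-magnification tile
#'
#' Stain deconvolution to hematoxylin OD, Otsu thresholding, hole filling and
#' small-object removal, then a distance-transform watershed to split touching
#' nuclei. Per-nucleus morphometry is measured on the final label image.
#'
#' @param tile a [tile_image()].
#' @param min_area minimum nucleus area in pixels (default 40, intended for
#'   40X tiles).
#' @param od_floor minimum peak hematoxylin OD for the tile to be considered
#'   stained at all (guards Otsu on blank tiles).
#' @return object of class `nucleus_set`: `labels` (integer matrix, 0
#'   background, k = nucleus k, contiguous 1..K) and `measurements`, a data
#'   frame with centroid (`cx`, `cy`), `area_px`, `perimeter`, `major_axis`,
#'   `minor_axis`, `eccentricity`, `solidity`, `extent`, `equivalent_diameter`,
#'   `circularity` and `mean_h_od` per nucleus.
#' @export
detect_nuclei <- function(tile, min_area = 40, od_floor = 0.15) {
  hc <- hematoxylin_od(tile)
  h <- nrow(hc); w <- ncol(hc)
  empty <- function() {
    structure(list(labels = matrix(0L, h, w),
                   measurements = data.frame(
                     id = integer(), cx = numeric(), cy = numeric(),
                     area_px = numeric(), perimeter = numeric(),
                     major_axis = numeric(), minor_axis = numeric(),
                     eccentricity = numeric(), solidity = numeric(),
                     extent = numeric(), equivalent_diameter = numeric(),
                     circularity = numeric(), mean_h_od = numeric())),
              class = "nucleus_set")
  }
  if (max(hc) < od_floor) return(empty())

  img <- EBImage::Image(t(hc / max(hc)))            # EBImage is x-major
  thr <- EBImage::otsu(img, range = c(0, 1))
  bin <- img > thr
  bin <- EBImage::fillHull(bin)
  lab0 <- EBImage::bwlabel(bin)
  sizes <- tabulate(as.integer(lab0))
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) return(empty())
  bin2 <- EBImage::Image(array(as.integer(lab0) %in% keep, dim = dim(lab0)))
  dmap <- EBImage::distmap(bin2)
  labs <- EBImage::watershed(dmap, tolerance = 1, ext = 1)
  lm <- t(as.matrix(EBImage::imageData(labs)))      # back to row = y

  # drop fragments below min_area produced by the watershed split
  sizes <- tabulate(lm)
  drop <- which(sizes < min_area)
  if (length(drop)) lm[lm %in% drop] <- 0L
  old <- sort(unique(lm[lm > 0L]))
  lm <- matrix(match(lm, old, nomatch = 0L), h, w)  # relabel 1..K
  K <- length(old)
  if (K == 0) return(empty())

  meas <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(lm == k, arr.ind = TRUE)
    ys <- idx[, 1]; xs <- idx[, 2]
    area <- nrow(idx)
    cx <- mean(xs); cy <- mean(ys)
    # second moments for the axis lengths
    mxx <- mean((xs - cx)^2); myy <- mean((ys - cy)^2); mxy <- mean((xs - cx) * (ys - cy))
    tr <- mxx + myy; det2 <- mxx * myy - mxy^2
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det2, 0))
    l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det2, 0))
    major <- 4 * sqrt(pmax(l1, 0)); minor <- 4 * sqrt(pmax(l2, 0))
    ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
    # perimeter: count exposed 4-neighbour edges
    inmask <- matrix(FALSE, h, w); inmask[idx] <- TRUE
    per <- sum(inmask & !rbind(inmask[-1, , drop = FALSE], FALSE)) +
      sum(inmask & !rbind(FALSE, inmask[-h, , drop = FALSE])) +
      sum(inmask & !cbind(inmask[, -1, drop = FALSE], FALSE)) +
      sum(inmask & !cbind(FALSE, inmask[, -w, drop = FALSE]))
    hull_area <- tryCatch({
      ch <- grDevices::chull(xs, ys)
      px <- xs[ch]; py <- ys[ch]
      abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2 + per / 2
    }, error = function(e) area)
    bbox <- (max(xs) - min(xs) + 1) * (max(ys) - min(ys) + 1)
    meas[[k]] <- data.frame(
      id = k, cx = cx, cy = cy, area_px = area, perimeter = per,
      major_axis = major, minor_axis = minor, eccentricity = ecc,
      solidity = min(1, area / max(hull_area, area)),
      extent = area / bbox,
      equivalent_diameter = 2 * sqrt(area / pi),
      circularity = min(1, 4 * pi * area / per^2),
      mean_h_od = mean(hc[idx]))
  }
  structure(list(labels = lm, measurements = do.call(rbind, meas)),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set: %d nuclei>\n", nrow(x$measurements)))
  invisible(x)
}

#' Select the highest-cell-density tile
#'
#' Runs [detect_nuclei()] on every candidate and returns the tile maximizing
#' nucleus count per tissue-pixel. Ties are broken by lowest `(y, x)` origin,
#' making the choice invariant to candidate order.
#'
#' @param tiles list of [tile_image()] candidates.
#' @param min_area passed to [detect_nuclei()].
#' @param ... further arguments to [detect_nuclei()].
#' @return the selected [tile_image()], with attributes `nucleus_count` and
#'   `density`.
#' @export
select_density_tile <- function(tiles, min_area = 40, ...) {
  stop_if_not(length(tiles) >= 1, "need at least one candidate tile")
  stats <- lapply(tiles, function(tl) {
    ta <- sum(tissue_mask(tl))
    if (ta == 0) return(c(0, 0))
    ns <- detect_nuclei(tl, min_area = min_area, ...)
    c(nrow(ns$measurements), nrow(ns$measurements) / ta)
  })
  counts <- vapply(stats, `[`, 0, 1)
  dens <- vapply(stats, `[`, 0, 2)
  if (all(vapply(tiles, function(tl) sum(tissue_mask(tl)), 0) == 0)) {
    stop("no tissue found on any candidate tile")
  }
  best <- which(abs(dens - max(dens)) < 1e-12)
  if (length(best) > 1) {
    oy <- vapply(tiles[best], function(tl) tl$origin[2], 0)
    ox <- vapply(tiles[best], function(tl) tl$origin[1], 0)
    best <- best[order(oy, ox)]
  }
  out <- tiles[[best[1]]]
  attr(out, "nucleus_count") <- counts[best[1]]
  attr(out, "density") <- dens[best[1]]
  out
}

#' HSV histogram profile of tissue pixels
#'
#' Joint Hue x Saturation x Value histogram (default 16 x 8 x 8 bins) over the
#' tissue pixels of one or more tiles, normalized to sum to 1.
#'
#' @param tiles a [tile_image()] or list of them.
#' @param bins histogram bins per channel.
#' @param sat_min,val_max tissue-mask thresholds.
#' @return normalized histogram vector (length `prod(bins)`); attribute
#'   `n_pixels` carries the tissue pixel count.
#' @export
hsv_profile <- function(tiles, bins = c(16, 8, 8), sat_min = 0.05, val_max = 0.98) {
  if (inherits(tiles, "tile_image")) tiles <- list(tiles)
  counts <- numeric(prod(bins))
  npix <- 0
  for (tl in tiles) {
    hsv <- rgb_to_hsv_mat(tl$pixels)
    keep <- hsv[2, ] >= sat_min & hsv[3, ] <= val_max
    if (!any(keep)) next
    cut_ch <- function(v, nb) pmin(pmax(ceiling(v * nb), 1L), nb)
    b1 <- cut_ch(hsv[1, keep], bins[1])
    b2 <- cut_ch(hsv[2, keep], bins[2])
    b3 <- cut_ch(hsv[3, keep], bins[3])
    cell <- b1 + bins[1] * (b2 - 1L) + bins[1] * bins[2] * (b3 - 1L)
    tb <- tabulate(cell, nbins = prod(bins))
    counts <- counts + tb
    npix <- npix + sum(keep)
  }
  prof <- if (sum(counts) > 0) counts / sum(counts) else counts
  attr(prof, "n_pixels") <- npix
  prof
}

#' Chi-squared distance between two histograms
#' @param a,b normalized histograms of equal length.
#' @return non-negative distance (0 for identical histograms).
#' @export
chisq_distance <- function(a, b) {
  s <- a + b
  nz <- s > 0
  0.5 * sum((a[nz] - b[nz])^2 / s[nz])
}

tiles_adjacent <- function(t1, t2) {
  dx <- abs(t1$origin[1] - t2$origin[1]); dy <- abs(t1$origin[2] - t2$origin[2])
  (dx == t1$tile_size[1] && dy == 0) || (dy == t1$tile_size[2] && dx == 0)
}

#' Select representative tiles by HSV-profile similarity
#'
#' Scores every candidate by the chi-squared distance between its HSV tissue
#' profile and the pooled whole-slide profile, then greedily takes the `k`
#' lowest-distance tiles subject to no two selected tiles sharing an edge.
#' Ties are broken by candidate order. If fewer than `k` tiles contain tissue
#' all tissue tiles are returned with attribute `warning_flag = TRUE`; if the
#' adjacency constraint cannot be met, remaining slots are filled by score.
#'
#' @param tiles list of [tile_image()] candidates (one magnification level).
#' @param k number of tiles to select.
#' @param bins,sat_min,val_max see [hsv_profile()].
#' @return list of selected tiles, attribute `distances` (their chi-squared
#'   scores) and possibly `warning_flag`.
#' @export
select_representative_tiles <- function(tiles, k = 5, bins = c(16, 8, 8),
                                        sat_min = 0.05, val_max = 0.98) {
  profs <- lapply(tiles, hsv_profile, bins = bins, sat_min = sat_min, val_max = val_max)
  has_tissue <- vapply(profs, function(p) attr(p, "n_pixels") > 0, TRUE)
  if (sum(has_tissue) < k) {
    out <- tiles[has_tissue]
    attr(out, "warning_flag") <- TRUE
    attr(out, "distances") <- rep(NA_real_, length(out))
    return(out)
  }
  slide <- hsv_profile(tiles[has_tissue], bins = bins, sat_min = sat_min,
                       val_max = val_max)
  dists <- rep(Inf, length(tiles))
  dists[has_tissue] <- vapply(profs[has_tissue], chisq_distance, 0, b = slide)
  ord <- order(dists)                      # stable: ties by candidate order
  chosen <- integer(0)
  for (i in ord) {
    if (!has_tissue[i]) next
    if (length(chosen) == k) break
    if (!any(vapply(chosen, function(j) tiles_adjacent(tiles[[i]], tiles[[j]]), TRUE))) {
      chosen <- c(chosen, i)
    }
  }
  if (length(chosen) < k) {               # adjacency exhausted; fill by score
    extra <- setdiff(ord[has_tissue[ord]], chosen)
    chosen <- c(chosen, head(extra, k - length(chosen)))
  }
  out <- tiles[chosen]
  attr(out, "distances") <- dists[chosen]
  out
}
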
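# 3D shape features of a binary mask in physical (mm) units.

# physical coordinates (mm) of mask voxel centres, n x 3
mask_coords_mm <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (ncol(idx) == 2) idx <- cbind(idx, 1L)
  sweep(idx - 1, 2, spacing, `*`)
}

# voxels with at least one exposed face (6-neighbourhood)
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, ax, by) {
    n <- dim(m)[ax]
    pad <- function(i) pmin(pmax(i, 1L), n)
    idx <- pad(seq_len(n) + by)
    out <- switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                  m[, , idx, drop = FALSE])
    # voxels at the grid edge are surface by definition
    edge <- seq_len(n) + by
    bad <- edge < 1L | edge > n
    if (any(bad)) {
      switch(ax, out[bad, , ] <- FALSE, out[, bad, ] <- FALSE, out[, , bad] <- FALSE)
    }
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) interior <- interior & shift_and(mask, ax, by)
  mask & !interior
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 1500) {  # deterministic stride subsample to bound O(n^2)
    pts <- pts[seq(1, nrow(pts), length.out = 1500), , drop = FALSE]
  }
  sqrt(max(as.vector(dist(pts))^2))
}

#' 3D shape features of a mask
#'
#' Fourteen shape descriptors of the volume of interest: voxel volume, face-
#' counted surface area, surface-to-volume ratio, sphericity, compactness,
#' maximum 3D and in-plane diameters, and principal-component axis lengths
#' (\eqn{4\sqrt{\lambda}}) with Elongation \eqn{=\sqrt{\lambda_{minor}/\lambda_{major}}}
#' and Flatness \eqn{= \sqrt{\lambda_{least}/\lambda_{major}}}
#' (the least/major principal-axis length ratio; 1 for a ball, 0 for a
#' degenerate coplanar mask).
#'
#' @param mask logical 3D array with >= 1 voxel set.
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of 14 features (`shape__*`).
#' @export
shape3d <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  stop_if_not(length(dim(mask)) == 3, "mask must be 3D")
  nv <- sum(mask)
  stop_if_not(nv >= 1, "mask must contain at least one voxel")
  spacing <- rep(spacing, length.out = 3)
  vol <- nv * prod(spacing)

  # surface area by counting exposed faces
  d <- dim(mask)
  sa <- 0
  for (ax in 1:3) {
    face_area <- prod(spacing[-ax])
    n <- d[ax]
    sub <- function(i) switch(ax, mask[i, , , drop = FALSE],
                              mask[, i, , drop = FALSE], mask[, , i, drop = FALSE])
    inner_exposed <- sum(sub(seq_len(n - 1)) != sub(seq_len(n - 1) + 1) &
                           (sub(seq_len(n - 1)) | sub(seq_len(n - 1) + 1)))
    border_exposed <- sum(sub(1)) + sum(sub(n))
    sa <- sa + face_area * (inner_exposed + border_exposed)
  }

  surf <- mask_coords_mm(surface_voxels(mask), spacing)
  d3 <- max_pairwise_dist(surf)
  plane_diam <- function(drop_ax) {
    if (nrow(surf) < 2) return(0)
    key <- surf[, drop_ax]
    m <- 0
    for (u in unique(key)) {
      m <- max(m, max_pairwise_dist(surf[key == u, -drop_ax, drop = FALSE]))
    }
    m
  }

  coords <- mask_coords_mm(mask, spacing)
  if (nv >= 2) {
    ev <- sort(pmax(eigen(cov(coords), symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)

  f <- c(
    VoxelVolume = vol,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / sa,
    Compactness = 36 * pi * vol^2 / sa^3,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = plane_diam(3),
    Maximum2DDiameterColumn = plane_diam(2),
    Maximum2DDiameterRow = plane_diam(1),
    MajorAxisLength = axis_len[1],
    MinorAxisLength = axis_len[2],
    LeastAxisLength = axis_len[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
  names(f) <- paste0("shape__", SHAPE_NAMES)
  f
}
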
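#' Discretize in-mask intensities to integer gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_bins` levels
#' `1..Ng`. Bins are right-closed (`level = ceiling((x - min) / w)`, with the
#' minimum mapped to level 1), so a value exactly on an interior edge falls in
#' the lower bin. A constant region occupies the single level 1.
#'
#' @param volume numeric array (2D or 3D).
#' @param mask logical array of the same shape; must select >= 1 voxel.
#' @param n_bins number of gray levels (>= 2).
#' @param spacing voxel spacing in mm (carried along for volume-weighted
#'   features).
#' @return object of class `discretized_volume`: `levels` (integer array, 0
#'   outside the mask), `ng`, `values` (raw in-mask intensities), `n_voxels`,
#'   `dims`, `spacing`.
#' @export
discretize <- function(volume, mask, n_bins = 32, spacing = c(1, 1, 1)) {
  stop_if_not(identical(dim(volume), dim(mask)), "volume and mask shapes differ")
  stop_if_not(n_bins >= 2, "n_bins must be >= 2")
  mask <- array(as.logical(mask), dim = dim(mask))
  nv <- sum(mask)
  if (nv == 0) stop("empty mask")
  vals <- volume[mask]
  rng <- range(vals)
  lev <- array(0L, dim = dim(volume))
  if (rng[2] > rng[1]) {
    w <- (rng[2] - rng[1]) / n_bins
    l <- as.integer(ceiling((vals - rng[1]) / w))
    l[l < 1L] <- 1L
    l[l > n_bins] <- n_bins
  } else {
    l <- rep(1L, nv)
  }
  lev[mask] <- l
  d <- dim(volume)
  if (length(d) == 2) d <- c(d, 1L)
  structure(list(levels = lev, ng = as.integer(n_bins), values = vals,
                 n_voxels = nv, dims = as.integer(d),
                 spacing = rep(spacing, length.out = 3)),
            class = "discretized_volume")
}
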
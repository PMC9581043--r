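# Separable image filtering for 3D volumes: Gaussian / Laplacian-of-Gaussian
# banks in physical units, and a one-level orthogonal 3D wavelet transform
# whose eight sub-bands are projected back to the original grid.

# Convolve a 3D array along one axis with a 1D kernel.
# boundary: "reflect" (symmetric half-sample) or "periodic".
conv_axis <- function(arr, kernel, axis, boundary = "reflect") {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- dim(x)[1]
  m <- prod(dim(x)[-1])
  dim(x) <- c(n, m)
  L <- length(kernel)
  half <- (L - 1L) %/% 2L
  pad_idx <- (1 - half):(n + (L - 1L - half))
  if (boundary == "periodic") {
    pad_idx <- ((pad_idx - 1L) %% n) + 1L
  } else {
    # symmetric reflection without repeating the edge sample's neighbour twice
    pad_idx <- ifelse(pad_idx < 1L, 2L - pad_idx, pad_idx)
    pad_idx <- ifelse(pad_idx > n, 2L * n - pad_idx, pad_idx)
    pad_idx <- pmin(pmax(pad_idx, 1L), n)
  }
  xp <- x[pad_idx, , drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_len(L)) {
    out <- out + kernel[t] * xp[t:(t + n - 1L), , drop = FALSE]
  }
  dim(out) <- dim(aperm(arr, perm))
  aperm(out, order(perm))
}

gaussian_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# second derivative of a Gaussian, corrected to sum exactly to zero so a
# constant image gives an exactly zero response
gaussian_d2_kernel <- function(sigma, truncate = 4) {
  r <- max(2L, ceiling(truncate * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- g * (x^2 - sigma^2) / sigma^4
  k - mean(k)
}

# Gaussian smoothing with per-axis sigma in voxel units
gaussian_smooth <- function(vol, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  out <- vol
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) out <- conv_axis(out, gaussian_kernel(sigma_vox[ax]), ax)
  }
  out
}

#' Laplacian-of-Gaussian filter bank
#'
#' Applies scale-normalized Laplacian-of-Gaussian filters at a set of physical
#' scales. The response is \eqn{\sigma^2 \nabla^2 (G_\sigma * I)}, computed
#' separably with per-axis voxel sigmas \eqn{\sigma / s_{ax}} for voxel spacing
#' \eqn{s_{ax}}. The \eqn{\sigma^2} normalization makes the response magnitude
#' at the centre of a bright ball of radius \eqn{r} peak near
#' \eqn{\sigma = r/\sqrt{3}}.
#'
#' @param vol 3D numeric array.
#' @param spacing voxel spacing in mm, length 3.
#' @param sigmas_mm filter scales in mm (all > 0).
#' @return named list of filtered volumes, `log-sigma-<s>-mm`.
#' @export
log_bank <- function(vol, spacing = c(1, 1, 1), sigmas_mm = c(1, 2, 3, 4)) {
  stop_if_not(all(sigmas_mm > 0), "LoG sigmas must be > 0")
  stop_if_not(length(dim(vol)) == 3, "volume must be a 3D array")
  spacing <- rep(spacing, length.out = 3)
  out <- vector("list", length(sigmas_mm))
  names(out) <- sprintf("log-sigma-%g-mm", sigmas_mm)
  for (s in seq_along(sigmas_mm)) {
    sv <- sigmas_mm[s] / spacing
    resp <- 0
    for (ax in 1:3) {
      r <- conv_axis(vol, gaussian_d2_kernel(sv[ax]), ax)  # d2 in voxel units
      for (ax2 in setdiff(1:3, ax)) r <- conv_axis(r, gaussian_kernel(sv[ax2]), ax2)
      # convert second derivative from voxel^-2 to mm^-2
      resp <- resp + r / spacing[ax]^2
    }
    out[[s]] <- sigmas_mm[s]^2 * resp
  }
  out
}

# -- one-level periodized orthogonal DWT (coiflet-1) -------------------------

# coiflet-1 analysis filters (orthonormal: sum of squares 1)
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

# forward periodized DWT along the first dim of a matrix (n even)
dwt_step <- function(x, filt) {
  n <- nrow(x)
  L <- length(filt)
  nh <- n %/% 2L
  out <- matrix(0, nh, ncol(x))
  base <- 2L * (seq_len(nh) - 1L)           # 0-based start of each window
  for (t in seq_len(L)) {
    rows <- ((base + t - 1L) %% n) + 1L
    out <- out + filt[t] * x[rows, , drop = FALSE]
  }
  out
}

# transpose (adjoint) of dwt_step: scatter coefficients back to length n
idwt_step <- function(cf, filt, n) {
  nh <- nrow(cf)
  L <- length(filt)
  out <- matrix(0, n, ncol(cf))
  base <- 2L * (seq_len(nh) - 1L)
  for (t in seq_len(L)) {
    rows <- ((base + t - 1L) %% n) + 1L
    acc <- rowsum(cf * filt[t], group = rows)
    out[as.integer(rownames(acc)), ] <- out[as.integer(rownames(acc)), , drop = FALSE] + acc
  }
  out
}

# apply forward (band = "L"/"H") transform along an axis; array size halves
dwt_axis <- function(arr, axis, band) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  dim(x) <- c(dp[1], prod(dp[-1]))
  filt <- if (band == "L") coif1_lo else coif1_hi
  cf <- dwt_step(x, filt)
  dim(cf) <- c(dp[1] %/% 2L, dp[2], dp[3])
  aperm(cf, order(perm))
}

idwt_axis <- function(cf, axis, band, n_full) {
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(cf, perm)
  dp <- dim(x)
  dim(x) <- c(dp[1], prod(dp[-1]))
  filt <- if (band == "L") coif1_lo else coif1_hi
  rec <- idwt_step(x, filt, n_full)
  dim(rec) <- c(n_full, dp[2], dp[3])
  aperm(rec, order(perm))
}

#' One-level 3D wavelet sub-band decomposition
#'
#' Separable one-level discrete wavelet transform (orthogonal coiflet-1,
#' periodic boundary) along each axis, producing the eight sub-band
#' combinations LLL..HHH. Each sub-band is reconstructed back to the original
#' grid by inverting the transform with the other seven bands set to zero, so
#' the outputs are orthogonal projections of the input: they sum to the input
#' volume and their energies sum to the input energy (exactly for even axis
#' lengths; odd axes are symmetrically padded by one sample and cropped).
#'
#' @param vol 3D numeric array with all dimensions >= 6 (the filter length).
#' @return named list of 8 volumes (`wavelet-LLL` ... `wavelet-HHH`), each the
#'   same shape as `vol`. Band letters index axes 1, 2, 3 in order.
#' @export
wavelet_bank <- function(vol) {
  stop_if_not(length(dim(vol)) == 3, "volume must be a 3D array")
  stop_if_not(all(dim(vol) >= 6), "volume too small for the wavelet filter (need >= 6 per axis)")
  d0 <- dim(vol)
  # pad odd axes to even length by reflecting the last sample
  x <- vol
  for (ax in 1:3) {
    if (dim(x)[ax] %% 2L == 1L) {
      idx <- c(seq_len(dim(x)[ax]), dim(x)[ax])
      x <- switch(ax, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
    }
  }
  d <- dim(x)
  bands <- expand.grid(b1 = c("L", "H"), b2 = c("L", "H"), b3 = c("L", "H"),
                       stringsAsFactors = FALSE)
  bands <- bands[order(bands$b1, bands$b2, bands$b3), ]
  out <- vector("list", 8)
  nm <- character(8)
  for (i in seq_len(8)) {
    b <- unlist(bands[i, ])
    cf <- x
    for (ax in 1:3) cf <- dwt_axis(cf, ax, b[ax])
    rec <- cf
    for (ax in 3:1) rec <- idwt_axis(rec, ax, b[ax], d[ax])
    out[[i]] <- rec[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
    nm[i] <- paste0("wavelet-", paste(b, collapse = ""))
  }
  names(out) <- nm
  out
}
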
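# Histopathology feature banks: 22 visual (nuclear morphometry) features and
# 171 sub-visual (intensity + co-occurrence texture) features per tile, with
# feature-wise mean aggregation from tiles to one per-slide vector.

#' Registry of the histology feature banks
#'
#' @return data frame with columns `name`, `bank` (`visual`/`subvisual`),
#'   `class`, `feature`: 22 visual + 171 sub-visual rows.
#' @export
histo_bank_registry <- function() {
  vis <- c(paste0("visual__", rep(VISUAL_MEASURES, each = 2), "__",
                  c("mean", "sd")),
           "visual__nucleus_count", "visual__nucleus_density")
  vrows <- data.frame(name = vis, bank = "visual", class = "morphometry",
                      feature = sub("^visual__", "", vis))
  fo <- paste0("subvisual__firstorder__", c(FIRSTORDER_NAMES, "StandardDeviation"))
  frows <- data.frame(name = fo, bank = "subvisual", class = "firstorder",
                      feature = sub(".*__", "", fo))
  gl <- character(0)
  for (dst in c(1, 2)) for (ang in names(HISTO_GLCM_DIRS)) {
    gl <- c(gl, paste0("subvisual__glcm__", HISTO_GLCM_NAMES, "__d", dst, "_", ang))
  }
  grows <- data.frame(name = gl, bank = "subvisual", class = "glcm",
                      feature = sub("^subvisual__glcm__", "", gl))
  rbind(vrows, frows, grows)
}

#' Visual (morphometric) histology features
#'
#' Ten per-nucleus measures (area, perimeter, major/minor axis, eccentricity,
#' solidity, extent, circularity, equivalent diameter, mean hematoxylin OD),
#' each aggregated as mean and standard deviation, plus nucleus count and
#' nucleus density (count per tissue pixel): 22 features. An empty nucleus
#' set yields count and density 0 and `NA` (imputable missing) elsewhere.
#'
#' @param nuclei a [detect_nuclei()] result (or ground-truth equivalent with
#'   the same measurement columns).
#' @param tile the [tile_image()] the nuclei were detected on.
#' @param sat_min,val_max tissue-mask thresholds for the density denominator.
#' @return named numeric vector of 22 features (`visual__*`).
#' @export
visual_features <- function(nuclei, tile, sat_min = 0.05, val_max = 0.98) {
  m <- nuclei$measurements
  ta <- sum(tissue_mask(tile, sat_min, val_max))
  out <- numeric(0)
  for (v in VISUAL_MEASURES) {
    if (nrow(m) == 0) {
      mu <- NA_real_; s <- NA_real_
    } else {
      mu <- mean(m[[v]]); s <- if (nrow(m) > 1) sd(m[[v]]) else 0
    }
    out <- c(out, setNames(c(mu, s), paste0("visual__", v, "__", c("mean", "sd"))))
  }
  c(out, visual__nucleus_count = nrow(m),
    visual__nucleus_density = if (ta > 0) nrow(m) / ta else 0)
}

#' Sub-visual (intensity and co-occurrence) histology features
#'
#' On the luminance image restricted to tissue pixels: 19 first-order
#' features (the standard 18 plus StandardDeviation) and 19 co-occurrence
#' features for each of 4 directions (0, 45, 90, 135 degrees) and 2 pixel
#' distances (1, 2) after discretization to `n_bins` gray levels:
#' 19 + 19 x 8 = 171 features. An empty tissue mask yields all-`NA`.
#'
#' @param tile a [tile_image()].
#' @param n_bins gray levels for discretization.
#' @param sat_min,val_max tissue-mask thresholds.
#' @return named numeric vector of 171 features (`subvisual__*`).
#' @export
subvisual_features <- function(tile, n_bins = 32, sat_min = 0.05, val_max = 0.98) {
  reg <- histo_bank_registry()
  nms <- reg$name[reg$bank == "subvisual"]
  px <- tile$pixels
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  msk <- tissue_mask(tile, sat_min, val_max)
  if (!any(msk)) return(setNames(rep(NA_real_, length(nms)), nms))
  d <- discretize(array(gray, dim = c(dim(gray), 1L)),
                  array(msk, dim = c(dim(msk), 1L)), n_bins = n_bins)
  fo <- first_order(d, include_sd = TRUE)
  names(fo) <- paste0("subvisual__", names(fo))
  gl <- numeric(0)
  for (dst in c(1L, 2L)) for (ang in names(HISTO_GLCM_DIRS)) {
    off <- matrix(HISTO_GLCM_DIRS[[ang]] * dst, 1, 3)
    P <- cpp_glcm(as.integer(d$levels), d$dims, d$ng, off)
    f <- glcm_features_from_matrix(matrix(P, d$ng, d$ng))[HISTO_GLCM_NAMES]
    names(f) <- paste0("subvisual__glcm__", HISTO_GLCM_NAMES, "__d", dst, "_", ang)
    gl <- c(gl, f)
  }
  out <- c(fo, gl)
  out[nms]
}

#' Aggregate per-tile feature vectors to one per-slide vector
#'
#' Feature-wise mean across tiles, ignoring missing (`NA`) values; a feature
#' missing on every tile stays missing at the slide level.
#'
#' @param tile_vectors list of equally named numeric vectors.
#' @return named numeric vector.
#' @export
aggregate_slide <- function(tile_vectors) {
  stop_if_not(length(tile_vectors) >= 1, "need at least one tile vector")
  m <- do.call(rbind, tile_vectors)
  out <- colMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' All histology features for one slide
#'
#' Convenience wrapper: detects nuclei and computes the visual and sub-visual
#' banks on each tile, then aggregates with [aggregate_slide()].
#'
#' @param tiles list of [tile_image()] (the selected ROIs of one slide).
#' @param min_area passed to [detect_nuclei()].
#' @param n_bins passed to [subvisual_features()].
#' @return named numeric vector of 193 slide-level features.
#' @export
histo_features_slide <- function(tiles, min_area = 40, n_bins = 32) {
  vecs <- lapply(tiles, function(tl) {
    ns <- detect_nuclei(tl, min_area = min_area)
    c(visual_features(ns, tl), subvisual_features(tl, n_bins = n_bins))
  })
  aggregate_slide(vecs)
}
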
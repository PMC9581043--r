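# Full radiomics bank: 13 image types (original, 4 LoG, 8 wavelet) x
# {18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM} + 14 shape features
# on the original mask = 1,132 features per volume of interest.

#' Registry of the MRI radiomics feature bank
#'
#' Enumerates the full feature bank in extraction order, with per-feature
#' provenance (image filter, feature class, feature name). The default bank
#' has 1,132 entries: 13 image types x 86 features + 14 shape features.
#' Setting `include_ngtdm = TRUE` appends the 5 NGTDM features per image type.
#'
#' @param sigmas_mm LoG scales in mm.
#' @param include_ngtdm include the optional NGTDM class.
#' @return data frame with columns `name`, `filter`, `class`, `feature`.
#' @export
mri_bank_registry <- function(sigmas_mm = c(1, 2, 3, 4), include_ngtdm = FALSE) {
  filters <- c("original", sprintf("log-sigma-%g-mm", sigmas_mm),
               paste0("wavelet-", c("HHH", "HHL", "HLH", "HLL",
                                    "LHH", "LHL", "LLH", "LLL")))
  classes <- list(firstorder = FIRSTORDER_NAMES, glcm = GLCM_NAMES,
                  glrlm = GLRLM_NAMES, glszm = GLSZM_NAMES, gldm = GLDM_NAMES)
  if (include_ngtdm) classes$ngtdm <- NGTDM_NAMES
  rows <- list(data.frame(filter = "mask", class = "shape", feature = SHAPE_NAMES))
  for (f in filters) for (cl in names(classes)) {
    rows[[length(rows) + 1]] <- data.frame(filter = f, class = cl,
                                           feature = classes[[cl]])
  }
  reg <- do.call(rbind, rows)
  reg$name <- ifelse(reg$class == "shape",
                     paste0("shape__", reg$feature),
                     paste0(reg$filter, "__", reg$class, "__", reg$feature))
  reg[, c("name", "filter", "class", "feature")]
}

#' Fingerprint of a feature-bank registry
#'
#' @param registry a registry data frame (see [mri_bank_registry()]).
#' @return hex string hash of the ordered feature names.
#' @export
bank_hash <- function(registry) fnv1a_hash(registry$name)

texture_feature_set <- function(d, include_ngtdm = FALSE) {
  out <- c(glcm_features(d), glrlm_features(d), glszm_features(d),
           gldm_features(d))
  if (include_ngtdm) out <- c(out, ngtdm_features(d))
  out
}

#' Extract the full radiomics feature bank from one volume of interest
#'
#' Computes 14 shape features on the mask, then for each of the 13 image
#' types (original volume, Laplacian-of-Gaussian at each sigma, and the eight
#' one-level wavelet sub-bands) discretizes the in-mask intensities to
#' `n_bins` gray levels and computes 18 first-order and 68 texture features.
#'
#' @param volume 3D numeric array.
#' @param mask logical 3D array (same shape, >= 1 voxel).
#' @param spacing voxel spacing in mm.
#' @param n_bins gray levels for discretization.
#' @param sigmas_mm LoG scales in mm.
#' @param include_ngtdm include the optional NGTDM class per image type.
#' @return named numeric vector of 1,132 features (more with NGTDM), ordered
#'   and named as in [mri_bank_registry()].
#' @export
extract_all <- function(volume, mask, spacing = c(1, 1, 1), n_bins = 32,
                        sigmas_mm = c(1, 2, 3, 4), include_ngtdm = FALSE) {
  mask <- array(as.logical(mask), dim = dim(mask))
  stop_if_not(identical(dim(volume), dim(mask)), "volume/mask shapes differ")
  if (sum(mask) == 0) stop("empty mask")
  spacing <- rep(spacing, length.out = 3)
  images <- c(list(original = volume),
              log_bank(volume, spacing, sigmas_mm),
              wavelet_bank(volume))
  # registry order: wavelet bands alphabetical
  wb <- grep("^wavelet-", names(images))
  images <- c(images[-wb], images[wb][order(names(images)[wb])])
  images <- images[c("original", sprintf("log-sigma-%g-mm", sigmas_mm),
                     sort(grep("^wavelet-", names(images), value = TRUE)))]
  out <- shape3d(mask, spacing)
  for (f in names(images)) {
    d <- discretize(images[[f]], mask, n_bins = n_bins, spacing = spacing)
    v <- c(first_order(d), texture_feature_set(d, include_ngtdm))
    names(v) <- paste0(f, "__", names(v))
    out <- c(out, v)
  }
  out
}

#' Extract radiomics features for every (sequence, mask) pair of a subject
#'
#' @param volumes named list of 3D arrays (e.g. `t1ce`, `flair`).
#' @param masks named list of logical arrays (e.g. `enhancing`, `necrosis`,
#'   `edema`).
#' @param spacing voxel spacing in mm.
#' @param ... passed to [extract_all()].
#' @return named numeric vector; names are `<sequence>__<mask>__<feature>`.
#' @export
extract_subject <- function(volumes, masks, spacing = c(1, 1, 1), ...) {
  out <- numeric(0)
  for (sq in names(volumes)) for (mk in names(masks)) {
    if (sum(masks[[mk]]) == 0) next
    v <- extract_all(volumes[[sq]], masks[[mk]], spacing = spacing, ...)
    names(v) <- paste0(sq, "__", mk, "__", names(v))
    out <- c(out, v)
  }
  out
}
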
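# Phantom MR volumes: nested ellipsoidal tumor compartments (necrosis inside
# enhancing tumor inside peritumoral edema) on a background, rendered for two
# modalities (T1CE-like, FLAIR-like) that share the same masks, with
# Gaussian-correlated noise whose statistics shift with the class label.

MASK_LABELS <- c(enhancing = 1L, necrosis = 2L, edema = 3L)

#' Specification of a phantom MR volume
#'
#' @param shape_voxels volume dimensions `(nx, ny, nz)`.
#' @param spacing_mm voxel spacing in mm.
#' @param semi_axes_mm named list with entries `edema`, `enhancing`, `necrosis`,
#'   each a length-3 vector of ellipsoid semi-axes in mm. Must nest strictly:
#'   necrosis inside enhancing inside edema.
#' @param means named list per modality (`t1ce`, `flair`), each a named vector
#'   of compartment means: `background`, `edema`, `enhancing`, `necrosis`.
#' @param noise_sd noise standard deviation (same units as the means).
#' @param texture_scale_mm correlation length of the Gaussian-smoothed noise.
#' @param class_effect effect size in noise-sd units: for a mutant label the
#'   tumor-compartment means shift by `class_effect * noise_sd` and the noise
#'   correlation length is multiplied by `1 + class_effect / 2`, so intensity
#'   and co-occurrence texture statistics separate the classes.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(36, 36, 26), spacing_mm = c(1, 1, 1),
                         semi_axes_mm = list(edema = c(14, 11, 9),
                                             enhancing = c(9, 7, 6),
                                             necrosis = c(4.5, 3.5, 3)),
                         means = list(t1ce = c(background = 0.30, edema = 0.45,
                                               enhancing = 0.75, necrosis = 0.25),
                                      flair = c(background = 0.30, edema = 0.80,
                                                enhancing = 0.55, necrosis = 0.35)),
                         noise_sd = 0.06, texture_scale_mm = 2,
                         class_effect = 0, seed = 1) {
  stop_if_not(all(shape_voxels >= 4), "shape_voxels must all be >= 4")
  stop_if_not(all(spacing_mm > 0), "spacing must be positive")
  ax <- semi_axes_mm
  stop_if_not(all(unlist(ax) > 0), "all semi-axes must be positive")
  stop_if_not(all(ax$necrosis < ax$enhancing) && all(ax$enhancing < ax$edema),
              "compartments must nest: necrosis < enhancing < edema on every axis")
  half_extent <- (shape_voxels - 1) / 2 * spacing_mm
  if (any(ax$edema >= half_extent)) {
    stop("compartment exceeds volume bounds: edema semi-axes must fit inside the grid")
  }
  structure(list(shape_voxels = as.integer(shape_voxels), spacing_mm = spacing_mm,
                 semi_axes_mm = ax, means = means, noise_sd = noise_sd,
                 texture_scale_mm = texture_scale_mm, class_effect = class_effect,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, spacing, semi_axes, center_mm = NULL) {
  if (is.null(center_mm)) center_mm <- (shape - 1) / 2 * spacing
  cx <- (seq_len(shape[1]) - 1) * spacing[1] - center_mm[1]
  cy <- (seq_len(shape[2]) - 1) * spacing[2] - center_mm[2]
  cz <- (seq_len(shape[3]) - 1) * spacing[3] - center_mm[3]
  q <- outer(outer((cx / semi_axes[1])^2, (cy / semi_axes[2])^2, `+`),
             (cz / semi_axes[3])^2, `+`)
  q <= 1
}

# unit-sd correlated noise field
correlated_noise <- function(shape, spacing, scale_mm) {
  z <- array(rnorm(prod(shape)), dim = shape)
  if (scale_mm > 0) {
    z <- gaussian_smooth(z, scale_mm / spacing)
    s <- sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

#' Generate a phantom MR study (two modalities plus masks)
#'
#' Builds nested ellipsoid compartment masks and two co-registered volumes.
#' Masks are identical across modalities and labels; the class effect only
#' perturbs voxel intensities.
#'
#' @param spec a [phantom_spec()].
#' @param label `"mutant"` or `"wildtype"`; the spec's `class_effect` is applied
#'   iff `label == "mutant"`.
#' @return list with `volumes` (named list `t1ce`, `flair` of 3D arrays),
#'   `masks` (named list of logical arrays `enhancing`, `necrosis`, `edema`,
#'   mutually exclusive), `label_array` (integer array, 0 background,
#'   1 enhancing, 2 necrosis, 3 edema) and `spacing_mm`.
#' @export
make_phantom <- function(spec, label = c("wildtype", "mutant")) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  label <- match.arg(label)
  shape <- spec$shape_voxels; spacing <- spec$spacing_mm
  ax <- spec$semi_axes_mm
  ell_ede <- ellipsoid_mask(shape, spacing, ax$edema)
  ell_enh <- ellipsoid_mask(shape, spacing, ax$enhancing)
  ell_nec <- ellipsoid_mask(shape, spacing, ax$necrosis)
  masks <- list(enhancing = ell_enh & !ell_nec,
                necrosis = ell_nec,
                edema = ell_ede & !ell_enh)
  label_array <- array(0L, dim = shape)
  for (nm in names(MASK_LABELS)) label_array[masks[[nm]]] <- MASK_LABELS[[nm]]

  eff <- if (label == "mutant") spec$class_effect else 0
  scale_mm <- spec$texture_scale_mm * (1 + eff / 2)
  volumes <- with_seed(spec$seed, {
    lapply(spec$means, function(mu) {
      vol <- array(mu[["background"]], dim = shape)
      for (nm in c("edema", "enhancing", "necrosis")) {
        vol[masks[[nm]]] <- mu[[nm]] + eff * spec$noise_sd
      }
      if (spec$noise_sd > 0) {
        vol <- vol + spec$noise_sd * correlated_noise(shape, spacing, scale_mm)
      }
      vol
    })
  })
  list(volumes = volumes, masks = masks, label_array = label_array,
       spacing_mm = spacing)
}

#' Write a phantom study as NIfTI files
#'
#' Mask label convention: 1 = enhancing tumor, 2 = necrosis, 3 = edema.
#'
#' @param phantom result of [make_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths.
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(t1ce = file.path(dir, paste0(prefix, "_t1ce.nii.gz")),
             flair = file.path(dir, paste0(prefix, "_flair.nii.gz")),
             mask = file.path(dir, paste0(prefix, "_mask.nii.gz")))
  sp <- phantom$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(phantom$volumes$t1ce, pixdim = sp), paths[["t1ce"]])
  RNifti::writeNifti(RNifti::asNifti(phantom$volumes$flair, pixdim = sp), paths[["flair"]])
  RNifti::writeNifti(RNifti::asNifti(phantom$label_array, pixdim = sp, datatype = "int16"),
                     paths[["mask"]])
  paths
}

#' Read a volume and mask set written by [write_phantom_nifti()]
#'
#' @param volume_path NIfTI scalar volume.
#' @param mask_path NIfTI integer label mask (1 = enhancing, 2 = necrosis,
#'   3 = edema).
#' @return list with `volume`, `label_array`, `masks` and `spacing_mm`.
#' @export
read_volume_nifti <- function(volume_path, mask_path) {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(vol)[1:3]
  lab <- array(as.integer(round(as.array(msk))), dim = dim(msk))
  masks <- lapply(MASK_LABELS, function(l) lab == l)
  list(volume = array(as.numeric(vol), dim = dim(vol)), label_array = lab,
       masks = masks, spacing_mm = sp)
}
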
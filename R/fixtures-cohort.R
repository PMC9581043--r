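# Labeled synthetic cohorts: per-subject histology tiles + MR phantoms written
# to disk with a manifest, plus a purely tabular cohort generator for
# model-level simulations.

#' Generate a synthetic labeled cohort on disk
#'
#' Writes, per subject, a set of H&E-like tiles (PNG), a two-modality MR
#' phantom with compartment masks (NIfTI) and a manifest CSV. The injected
#' class effect acts on every channel a real IDH effect would touch:
#' tile nucleus density and stain intensity, phantom compartment intensity and
#' noise texture, and age at diagnosis (mutant subjects younger; the shift is
#' 4.27 years per unit effect so that at the default large effect of 3 the age
#' channel alone separates the classes at roughly the 0.74 accuracy expected
#' of age in this disease).
#'
#' @param n_subjects number of subjects (>= 4).
#' @param class_balance fraction of mutant subjects; the mutant count is
#'   `round(n_subjects * class_balance)` exactly.
#' @param effect_size injected class effect in noise-sd units; 0 gives
#'   label-independent data.
#' @param seed integer RNG seed.
#' @param dir output directory.
#' @param n_tiles tiles per subject.
#' @param tile_px tile side length in pixels.
#' @param base_nuclei mean nuclei per tile for wildtype subjects.
#' @param phantom_shape phantom grid size passed to [phantom_spec()].
#' @return the manifest as a data frame (also written to `dir/manifest.csv`):
#'   subject_id, label, age, sex, tile paths, volume and mask paths.
#' @export
make_cohort <- function(n_subjects, class_balance = 0.5, effect_size = 3,
                        seed = 1, dir = tempfile("cohort_"),
                        n_tiles = 6, tile_px = 96, base_nuclei = 22,
                        phantom_shape = c(30, 30, 22)) {
  stop_if_not(n_subjects >= 4, "need at least 4 subjects")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("could not create output directory: ", dir)
  n_mut <- round(n_subjects * class_balance)
  labels <- rep(c("mutant", "wildtype"), c(n_mut, n_subjects - n_mut))
  rows <- vector("list", n_subjects)
  meta <- with_seed(derive_seed(seed, "cohort-meta"), {
    sex <- sample(c("M", "F"), n_subjects, replace = TRUE)
    age_mu <- ifelse(labels == "mutant", 56 - 4.27 * effect_size, 56)
    age <- round(pmax(18, rnorm(n_subjects, age_mu, 10)), 1)
    list(sex = sex, age = age)
  })
  # phantom geometry scaled to the requested grid
  sc <- min(phantom_shape) / 30
  axes <- list(edema = c(11, 9, 7.5) * sc, enhancing = c(7, 5.5, 4.5) * sc,
               necrosis = c(3.5, 2.75, 2.2) * sc)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subj_%03d", i)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    mut <- labels[i] == "mutant"
    tile_seed <- derive_seed(seed, paste0("tiles-", sid))
    lam <- base_nuclei * (1 + (if (mut) 0.12 * effect_size else 0))
    tile_paths <- character(n_tiles)
    with_seed(tile_seed, {
      counts <- rpois(n_tiles, lam)
      specseeds <- sample.int(1e6, n_tiles)
      for (t in seq_len(n_tiles)) {
        sp <- tile_spec(tile_px, tile_px, n_nuclei = counts[t],
                        radius_mean = 4.2, radius_sd = 0.7,
                        stain_mean = min(0.95, 0.65 + (if (mut) 0.05 * effect_size else 0)),
                        stain_sd = 0.08, overlap_fraction = 0.3,
                        seed = specseeds[t])
        tl <- make_tile(sp, magnification = 40,
                        origin = c((t - 1L) %% 3L, (t - 1L) %/% 3L) * tile_px)
        tile_paths[t] <- file.path(sdir, sprintf("tile_%02d.png", t))
        write_tile_png(tl$tile, tile_paths[t])
      }
    })
    psp <- phantom_spec(shape_voxels = phantom_shape, semi_axes_mm = axes,
                        class_effect = effect_size,
                        seed = derive_seed(seed, paste0("phantom-", sid)))
    ph <- make_phantom(psp, label = labels[i])
    ppaths <- write_phantom_nifti(ph, sdir, prefix = sid)
    rows[[i]] <- data.frame(subject_id = sid, label = labels[i],
                            age = meta$age[i], sex = meta$sex[i],
                            tile_dir = sdir,
                            t1ce = ppaths[["t1ce"]], flair = ppaths[["flair"]],
                            mask = ppaths[["mask"]], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Generate a tabular synthetic cohort with injected informative features
#'
#' A feature table with `p_informative` features whose class-conditional means
#' differ by `effect_size` standard deviations, `p_noise` pure-noise features,
#' plus age (label-shifted as in [make_cohort()]) and sex, for model-level
#' simulations of feature selection and cross-validation.
#'
#' @inheritParams make_cohort
#' @param p_informative,p_noise numbers of informative and noise features.
#' @return data frame with columns `subject_id`, `inf_*`, `noise_*`, `age`,
#'   `sex`, `label`.
#' @export
make_feature_table <- function(n_subjects, p_informative = 2, p_noise = 50,
                               effect_size = 3, class_balance = 0.5, seed = 1) {
  stop_if_not(n_subjects >= 4, "need at least 4 subjects")
  n_mut <- round(n_subjects * class_balance)
  labels <- rep(c("mutant", "wildtype"), c(n_mut, n_subjects - n_mut))
  with_seed(seed, {
    shift <- ifelse(labels == "mutant", effect_size, 0)
    inf <- sapply(seq_len(p_informative), function(j) rnorm(n_subjects, shift, 1))
    noise <- matrix(rnorm(n_subjects * p_noise), n_subjects, p_noise)
    age <- round(pmax(18, rnorm(n_subjects,
                                ifelse(labels == "mutant", 56 - 4.27 * effect_size, 56),
                                10)), 1)
    sex <- sample(c("M", "F"), n_subjects, replace = TRUE)
    df <- data.frame(subject_id = sprintf("subj_%03d", seq_len(n_subjects)))
    if (p_informative > 0) {
      inf <- matrix(inf, n_subjects, p_informative)
      colnames(inf) <- sprintf("inf_%d", seq_len(p_informative))
      df <- cbind(df, inf)
    }
    if (p_noise > 0) {
      colnames(noise) <- sprintf("noise_%d", seq_len(p_noise))
      df <- cbind(df, noise)
    }
    df$age <- age
    df$sex <- sex
    df$label <- labels
    df
  })
}
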
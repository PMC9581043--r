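# End-to-end orchestration: synthetic cohort -> ROI selection -> histology and
# MRI feature tables -> fusion + nested CV -> final model -> explanations ->
# human-readable report. Every stage writes versioned outputs under
# config$paths$out_dir; reruns with the same config and seed reproduce
# identical feature CSVs.

default_config <- function() {
  list(
    paths = list(data_dir = NULL, out_dir = NULL),
    cohort = list(n_subjects = 12, class_balance = 0.5, effect_size = 3,
                  n_tiles = 6, tile_px = 96, phantom_shape = c(28, 28, 20)),
    roi = list(k = 3, min_area = 40, low_mag_factor = 4),
    bank = list(n_bins = 32, sigmas_mm = c(1, 2, 3), include_ngtdm = FALSE),
    cv = list(folds = 4, step = 0.2, num_trees = 300, inner_folds = 3,
              target_size = NULL, per_modality = FALSE),
    explain = list(n_samples = 1000, k = 8, n_cases = 2),
    seed = 1
  )
}

#' Validate a pipeline run configuration
#'
#' Merges a user configuration (list, or path to a YAML/JSON file) over the
#' defaults, rejecting unknown keys and invalid values (e.g. fewer than 2 CV
#' folds) before any computation starts.
#'
#' @param config named list, or path to a YAML or JSON config file.
#' @return the validated, fully populated config list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk)) stop("unknown config keys in ", sec, ": ",
                             paste(badk, collapse = ", "))
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  stop_if_not(def$cv$folds >= 2, "cv$folds must be >= 2")
  stop_if_not(def$cohort$n_subjects >= 4, "cohort$n_subjects must be >= 4")
  stop_if_not(def$roi$k >= 1, "roi$k must be >= 1")
  stop_if_not(def$bank$n_bins >= 2, "bank$n_bins must be >= 2")
  def
}

# 4x average-pooling to emulate a low-magnification read of the same tile
downsample_tile <- function(tile, factor = 4) {
  px <- tile$pixels
  h <- nrow(px) %/% factor * factor
  w <- ncol(px) %/% factor * factor
  out <- array(0, dim = c(h %/% factor, w %/% factor, 3))
  for (ch in 1:3) {
    m <- px[seq_len(h), seq_len(w), ch]
    m <- (array(m, dim = c(factor, h %/% factor, w)))
    m <- apply(m, c(2, 3), mean)
    m <- array(m, dim = c(h %/% factor, factor, w %/% factor))
    out[, , ch] <- apply(m, c(1, 3), mean)
  }
  tile_image(out, magnification = tile$magnification / factor,
             origin = tile$origin %/% factor)
}

#' Select all histology ROIs for one slide
#'
#' The three-step ROI scheme: the single highest-cell-density tile, `k`
#' HSV-representative tiles at the native (high) magnification, and `k`
#' HSV-representative tiles at the low magnification (emulated by
#' average-pooling when only one level is on disk). The density tile is kept
#' distinct from the representative set.
#'
#' @param tiles list of [tile_image()] at the high magnification.
#' @param k representative tiles per level.
#' @param min_area nucleus area threshold at the high magnification.
#' @param low_mag_factor downsampling factor for the low-magnification level.
#' @return list with `density`, `representative_high`, `representative_low`.
#' @export
roi_select_slide <- function(tiles, k = 5, min_area = 40, low_mag_factor = 4) {
  density <- select_density_tile(tiles, min_area = min_area)
  rep_hi <- select_representative_tiles(tiles, k = k)
  low <- lapply(tiles, downsample_tile, factor = low_mag_factor)
  rep_lo <- select_representative_tiles(low, k = k)
  list(density = density, representative_high = rep_hi,
       representative_low = rep_lo)
}

read_subject_tiles <- function(tile_dir) {
  paths <- sort(list.files(tile_dir, pattern = "^tile_.*\\.png$",
                           full.names = TRUE))
  lapply(seq_along(paths), function(i) {
    tl <- read_tile_png(paths[i], magnification = 40)
    tl$origin <- c((i - 1L) %% 3L, (i - 1L) %/% 3L) * tl$tile_size
    tl
  })
}

stage_msg <- function(stage, ...) {
  message(sprintf("[radpath:%s] %s", stage, sprintf(...)))
}

run_stage <- function(stage, out_dir, expr) {
  marker <- file.path(out_dir, paste0(".", stage, "_INCOMPLETE"))
  file.create(marker)
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  unlink(marker)
  res
}

#' Run the end-to-end pipeline
#'
#' Executes, in order: cohort simulation, ROI selection, histology feature
#' extraction, MRI radiomics extraction, fusion + nested cross-validation +
#' final model, per-case explanations, and the summary report. Each stage
#' writes its outputs under `config$paths$out_dir` together with a log line;
#' a failing stage aborts with a stage-named error and leaves an
#' `.<stage>_INCOMPLETE` marker.
#'
#' @param config see [validate_config()].
#' @param stages character vector of stages to run (default all, in order):
#'   `simulate`, `roi`, `features_histo`, `features_mri`, `fit`, `explain`,
#'   `report`.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "roi", "features_histo",
                                    "features_mri", "fit", "explain", "report")) {
  cfg <- validate_config(config)
  out_dir <- cfg$paths$out_dir %||% tempfile("radpath_run_")
  data_dir <- cfg$paths$data_dir %||% file.path(out_dir, "cohort")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  res <- list(config = cfg, out_dir = out_dir)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"),
             file.path(out_dir, "config.json"))

  if ("simulate" %in% stages) {
    res$manifest <- run_stage("simulate", out_dir, {
      stage_msg("simulate", "cohort of %d subjects -> %s",
                cfg$cohort$n_subjects, data_dir)
      make_cohort(cfg$cohort$n_subjects, cfg$cohort$class_balance,
                  cfg$cohort$effect_size, seed = seed, dir = data_dir,
                  n_tiles = cfg$cohort$n_tiles, tile_px = cfg$cohort$tile_px,
                  phantom_shape = cfg$cohort$phantom_shape)
    })
  }
  manifest <- res$manifest %||% read.csv(file.path(data_dir, "manifest.csv"),
                                         stringsAsFactors = FALSE)

  if ("roi" %in% stages) {
    res$roi <- run_stage("roi", out_dir, {
      stage_msg("roi", "selecting ROIs for %d subjects", nrow(manifest))
      rois <- lapply(seq_len(nrow(manifest)), function(i) {
        tiles <- read_subject_tiles(manifest$tile_dir[i])
        roi_select_slide(tiles, k = cfg$roi$k, min_area = cfg$roi$min_area,
                         low_mag_factor = cfg$roi$low_mag_factor)
      })
      names(rois) <- manifest$subject_id
      man <- lapply(rois, function(r) {
        list(density_origin = r$density$origin,
             nucleus_count = attr(r$density, "nucleus_count"),
             representative_high = lapply(r$representative_high, `[[`, "origin"),
             representative_low = lapply(r$representative_low, `[[`, "origin"))
      })
      jsonlite::write_json(man, file.path(out_dir, "roi_manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      rois
    })
  }

  if ("features_histo" %in% stages) {
    res$histo <- run_stage("features_histo", out_dir, {
      stage_msg("features_histo", "histology banks for %d subjects", nrow(manifest))
      rows <- lapply(manifest$subject_id, function(sid) {
        r <- res$roi[[sid]]
        hi <- c(list(r$density), r$representative_high)
        lo <- r$representative_low
        vec_hi <- lapply(hi, function(tl) {
          ns <- detect_nuclei(tl, min_area = cfg$roi$min_area)
          c(visual_features(ns, tl), subvisual_features(tl, n_bins = cfg$bank$n_bins))
        })
        lo_min_area <- max(4, cfg$roi$min_area / cfg$roi$low_mag_factor^2)
        vec_lo <- lapply(lo, function(tl) {
          ns <- detect_nuclei(tl, min_area = lo_min_area)
          c(visual_features(ns, tl), subvisual_features(tl, n_bins = cfg$bank$n_bins))
        })
        aggregate_slide(c(vec_hi, vec_lo))
      })
      tb <- data.frame(subject_id = manifest$subject_id,
                       do.call(rbind, rows), check.names = FALSE)
      names(tb)[-1] <- paste0("histology__", names(tb)[-1])
      write.csv(tb, file.path(out_dir, "features_histo.csv"), row.names = FALSE)
      tb
    })
  }

  if ("features_mri" %in% stages) {
    res$mri <- run_stage("features_mri", out_dir, {
      stage_msg("features_mri", "radiomics bank for %d subjects", nrow(manifest))
      reg <- mri_bank_registry(cfg$bank$sigmas_mm, cfg$bank$include_ngtdm)
      jsonlite::write_json(reg, file.path(out_dir, "bank_registry.json"),
                           auto_unbox = TRUE, digits = NA)
      rows <- lapply(seq_len(nrow(manifest)), function(i) {
        t1 <- read_volume_nifti(manifest$t1ce[i], manifest$mask[i])
        fl <- read_volume_nifti(manifest$flair[i], manifest$mask[i])
        extract_subject(list(t1ce = t1$volume, flair = fl$volume), t1$masks,
                        spacing = t1$spacing_mm, n_bins = cfg$bank$n_bins,
                        sigmas_mm = cfg$bank$sigmas_mm,
                        include_ngtdm = cfg$bank$include_ngtdm)
      })
      tb <- data.frame(subject_id = manifest$subject_id,
                       do.call(rbind, rows), check.names = FALSE)
      write.csv(tb, file.path(out_dir, "features_mri.csv"), row.names = FALSE)
      tb
    })
  }

  if ("fit" %in% stages) {
    res$fit <- run_stage("fit", out_dir, {
      clinical <- manifest[, c("subject_id", "age", "sex", "label")]
      fused <- fuse(list(histology = res$histo, mri = res$mri), clinical)
      stage_msg("fit", "nested %d-fold CV on %d subjects x %d features",
                cfg$cv$folds, nrow(fused), ncol(fused) - 2L)
      cvs <- list()
      if (isTRUE(cfg$cv$per_modality)) {
        cvs$histology <- cv_evaluate(fuse(list(histology = res$histo), clinical),
                                     k = cfg$cv$folds, seed = seed,
                                     step = cfg$cv$step, num_trees = cfg$cv$num_trees,
                                     inner_folds = cfg$cv$inner_folds,
                                     target_size = cfg$cv$target_size)
        cvs$mri <- cv_evaluate(fuse(list(mri = res$mri), clinical),
                               k = cfg$cv$folds, seed = seed,
                               step = cfg$cv$step, num_trees = cfg$cv$num_trees,
                               inner_folds = cfg$cv$inner_folds,
                               target_size = cfg$cv$target_size)
      }
      cvs$fused <- cv_evaluate(fused, k = cfg$cv$folds, seed = seed,
                               step = cfg$cv$step, num_trees = cfg$cv$num_trees,
                               inner_folds = cfg$cv$inner_folds,
                               target_size = cfg$cv$target_size)
      final <- idh_rf(fused, seed = seed, num_trees = cfg$cv$num_trees,
                      step = cfg$cv$step, inner_folds = cfg$cv$inner_folds,
                      target_size = cfg$cv$target_size)
      report <- lapply(cvs, function(cv) {
        list(fold_accuracy = cv$fold_accuracy, accuracy_mean = cv$accuracy_mean,
             accuracy_sd = cv$accuracy_sd, auc = cv$auc, folds = cv$k,
             seed = cv$seed, selected = cv$selected)
      })
      jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                           auto_unbox = TRUE, digits = NA)
      write.csv(data.frame(feature = final$features),
                file.path(out_dir, "selected_features.csv"), row.names = FALSE)
      saveRDS(final, file.path(out_dir, "model.rds"))
      list(cvs = cvs, final = final, fused = fused)
    })
  }

  if ("explain" %in% stages) {
    res$explanations <- run_stage("explain", out_dir, {
      edir <- file.path(out_dir, "explanations")
      dir.create(edir, showWarnings = FALSE)
      n_cases <- min(cfg$explain$n_cases, nrow(res$fit$fused))
      stage_msg("explain", "local surrogates for %d cases", n_cases)
      ex <- lapply(seq_len(n_cases), function(i) {
        e <- explain_instance(res$fit$final, res$fit$fused[i, ],
                              n_samples = cfg$explain$n_samples,
                              k = cfg$explain$k,
                              seed = derive_seed(seed, paste0("explain", i)))
        write_explanation_json(e, file.path(edir, paste0(res$fit$fused$subject_id[i], ".json")))
        e
      })
      names(ex) <- res$fit$fused$subject_id[seq_len(n_cases)]
      ex
    })
  }

  if ("report" %in% stages) {
    res$report <- run_stage("report", out_dir, {
      rep <- pipeline_report(res$fit$cvs, res$fit$final)
      write.csv(rep$table, file.path(out_dir, "report.csv"), row.names = FALSE)
      grDevices::pdf(file.path(out_dir, "roc.pdf"), width = 5, height = 5)
      tryCatch({
        first <- TRUE
        for (nm in names(res$fit$cvs)) {
          cv <- res$fit$cvs[[nm]]
          ord <- order(1 - cv$roc_points$specificity, cv$roc_points$sensitivity)
          if (first) {
            plot(1 - cv$roc_points$specificity[ord], cv$roc_points$sensitivity[ord],
                 type = "l", col = which(names(res$fit$cvs) == nm),
                 xlab = "1 - specificity", ylab = "sensitivity", main = "ROC")
            first <- FALSE
          } else {
            lines(1 - cv$roc_points$specificity[ord],
                  cv$roc_points$sensitivity[ord],
                  col = which(names(res$fit$cvs) == nm))
          }
        }
        abline(0, 1, lty = 3)
        legend("bottomright", legend = names(res$fit$cvs),
               col = seq_along(res$fit$cvs), lty = 1, bty = "n")
      }, finally = grDevices::dev.off())
      rep
    })
  }
  invisible(res)
}

#' Summarize cross-validation results across modalities
#'
#' @param cvs named list of [cv_evaluate()] results (one per modality, e.g.
#'   `histology`, `mri`, `fused`).
#' @param final optional [idh_rf()] fit whose selected features are listed.
#' @return list with `table` (modality, accuracy mean ± sd, AUC) and
#'   `selected_features`.
#' @export
pipeline_report <- function(cvs, final = NULL) {
  stop_if_not(length(cvs) >= 1, "missing stage outputs: no CV results")
  tab <- do.call(rbind, lapply(names(cvs), function(nm) {
    data.frame(modality = nm, accuracy_mean = cvs[[nm]]$accuracy_mean,
               accuracy_sd = cvs[[nm]]$accuracy_sd, auc = cvs[[nm]]$auc)
  }))
  list(table = tab,
       selected_features = if (!is.null(final)) final$features else NULL)
}
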
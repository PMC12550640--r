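# Assembling the subject x wave x modality x region ROI score table from
# meshes and volumes, and reshaping between tidy and wide layouts.

#' Build the ROI score table from per-subject neural data
#'
#' For each subject and wave: the EEG-only score is the ROI mean of the
#' CDR difference map, the fMRI-only score the ROI mean of the contrast
#' volume, and the fusion score the ROI mean of their voxelwise product
#' over mapped voxels.  A missing modality propagates: no mesh means no
#' EEG and no fusion score; no contrast volume means no fMRI and no fusion
#' score.  Nothing is ever imputed here.
#'
#' @param neural result of [generate_neural_data()], or a list with the
#'   same shape (`geometry` + `subjects[[id]][[wave]]` holding `mesh` and
#'   `contrast`, either possibly `NULL`)
#' @param peaks optional ERN peak table ([ern_peak_table()]) to record the
#'   latency provenance per subject/wave
#' @return tidy data.frame: subject_id, wave, modality, region, score,
#'   n_units, ern_latency_ms
#' @export
build_roi_score_table <- function(neural, peaks = NULL) {
  geom <- neural$geometry
  rows <- list()
  for (sid in names(neural$subjects)) {
    for (wave in names(neural$subjects[[sid]])) {
      sw <- neural$subjects[[sid]][[wave]]
      lat <- NA_real_
      if (!is.null(peaks)) {
        hit <- peaks$subject == sid & peaks$wave == wave
        if (any(hit)) lat <- peaks$latency_ms[hit][1]
      }
      diff <- NULL
      fusion <- NULL
      if (!is.null(sw$mesh)) diff <- cdr_difference(sw$mesh, lat)
      if (!is.null(sw$mesh) && !is.null(sw$contrast)) {
        fusion <- fuse(sw$contrast, diff, geom$map)
      }
      for (reg in c("dacc", "pcc")) {
        add <- function(modality, val) {
          rows[[length(rows) + 1]] <<- data.frame(
            subject_id = sid, wave = wave, modality = modality, region = reg,
            score = as.numeric(val),
            n_units = as.integer(attr(val, "n_voxels") %||%
                                   attr(val, "n_elements") %||% 0L),
            ern_latency_ms = lat)
        }
        add("eeg", if (is.null(diff)) NA_real_ else
          roi_mean_mesh(diff, geom$mask, reg))
        add("fmri", if (is.null(sw$contrast)) NA_real_ else
          roi_mean_volume(sw$contrast, geom$mask, reg))
        add("fusion", if (is.null(fusion)) NA_real_ else
          roi_mean_volume(fusion, geom$mask, reg))
      }
    }
  }
  do.call(rbind, rows)
}

#' Reshape a tidy score table to one row per subject
#'
#' @param tidy tidy score table from [build_roi_score_table()]
#' @return data.frame with a `subject_id` column and one
#'   `<modality>_<region>_<wave>` column per score
#' @export
scores_wide <- function(tidy) {
  ids <- unique(tidy$subject_id)
  out <- data.frame(subject_id = ids)
  for (mod in unique(tidy$modality)) for (reg in unique(tidy$region)) {
    for (wave in unique(tidy$wave)) {
      sel <- tidy$modality == mod & tidy$region == reg & tidy$wave == wave
      col <- paste(mod, reg, wave, sep = "_")
      out[[col]] <- tidy$score[sel][match(ids, tidy$subject_id[sel])]
    }
  }
  out
}

#' Wide score table taken directly from the generator's latent truth
#'
#' Bypasses the imaging geometry: the true per-subject ROI activations act
#' as noise-free observed scores.  Used for score-level simulation studies
#' where the imaging stage is not under test.
#'
#' @param truth truth table from [generate_cohort()]
#' @return wide score data.frame
#' @export
truth_scores_wide <- function(truth) {
  cols <- grep("^(eeg|fmri|fusion)_", names(truth), value = TRUE)
  cbind(data.frame(subject_id = truth$subject_id), truth[, cols])
}

#' Write the tidy score table as CSV
#' @param tidy tidy score table
#' @param path output path
#' @export
write_scores_csv <- function(tidy, path) {
  utils::write.csv(tidy, path, row.names = FALSE, na = "")
  invisible(path)
}
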
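# Synthetic neuroimaging geometry: a shared bounding box holds a
# tetrahedral source mesh (Kuhn subdivision of a hexahedral grid) and an
# isotropic voxel grid with two disjoint box-shaped ROIs (dACC, PCC).
# Per-subject CDR and contrast values are planted so that the downstream
# ROI means recover each subject's true activation plus configured noise.

#' Build the shared synthetic geometry
#'
#' @param config a [generator_config()]; `config$geometry` gives the box
#'   size, mesh spacing, voxel size and the two ROI boxes (mm)
#' @return list: `mesh` (a bare `tet_mesh`), `template` (an `ern_volume` of
#'   zeros), `mask` (label volume), `map` (voxel-to-element map),
#'   `element_region` (label per element)
#' @export
build_geometry <- function(config = generator_config()) {
  g <- config$geometry
  # mesh nodes on a regular grid; 6 Kuhn tetrahedra per cube cell
  ax <- seq(0, g$box_mm, by = g$mesh_spacing_mm)
  nn <- length(ax)
  nodes <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  nid <- function(i, j, k) i + (j - 1) * nn + (k - 1) * nn * nn
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- expand.grid(i = 1:(nn - 1), j = 1:(nn - 1), k = 1:(nn - 1))
  el <- matrix(0L, nrow(cells) * 6, 4)
  row <- 0L
  unit <- diag(3)
  for (c_ in seq_len(nrow(cells))) {
    base <- c(cells$i[c_], cells$j[c_], cells$k[c_])
    for (p in perms) {
      row <- row + 1L
      v0 <- base
      v1 <- v0 + unit[p[1], ]
      v2 <- v1 + unit[p[2], ]
      v3 <- v2 + unit[p[3], ]
      el[row, ] <- c(nid(v0[1], v0[2], v0[3]), nid(v1[1], v1[2], v1[3]),
                     nid(v2[1], v2[2], v2[3]), nid(v3[1], v3[2], v3[3]))
    }
  }
  mesh <- tet_mesh(nodes, el)
  nvox <- g$box_mm / g$voxel_mm
  affine <- diag(c(g$voxel_mm, g$voxel_mm, g$voxel_mm, 1))
  affine[1:3, 4] <- g$voxel_mm / 2       # voxel centers at half spacing
  template <- volume(array(0, rep(nvox, 3)), affine)
  cent <- voxel_centroids(template)
  in_box <- function(box) {
    cent[, 1] >= box$lower[1] & cent[, 1] <= box$upper[1] &
      cent[, 2] >= box$lower[2] & cent[, 2] <= box$upper[2] &
      cent[, 3] >= box$lower[3] & cent[, 3] <= box$upper[3]
  }
  lab <- integer(nrow(cent))
  lab[in_box(g$dacc_box)] <- 1L
  lab[in_box(g$pcc_box)] <- 2L
  if (!any(lab == 1L) || !any(lab == 2L)) {
    stop("an ROI box contains no voxels; enlarge it or refine the grid")
  }
  if (any(in_box(g$dacc_box) & in_box(g$pcc_box))) {
    stop("ROI boxes overlap; dACC and PCC must be disjoint")
  }
  mask <- volume(array(lab, rep(nvox, 3)), affine)
  map <- map_voxels_to_elements(template, mesh)
  ereg <- element_regions(mesh, mask)
  # elements to plant signal on: centroid inside the ROI, or containing an
  # ROI voxel centroid (so ROI voxel products see the ROI signal too)
  plant <- list()
  for (r in c("dacc", "pcc")) {
    l <- region_label(r)
    if (!any(ereg == l)) stop("no mesh elements in region ", r)
    if (!any(lab == l & !is.na(map))) stop("no mapped voxels in region ", r)
    plant[[r]] <- sort(unique(c(which(ereg == l),
                                map[lab == l & !is.na(map)])))
  }
  if (length(intersect(plant$dacc, plant$pcc))) {
    stop("ROI boxes too close: planted element sets overlap")
  }
  list(mesh = mesh, template = template, mask = mask, map = map,
       element_region = ereg, element_plant = plant)
}

#' Generate per-subject/wave meshes and contrast volumes with planted ROI
#' signal
#'
#' Inside each ROI, the CDR difference is the subject's true EEG activation
#' and the contrast value the true fMRI activation (each plus zero-mean
#' noise); outside the ROIs both are zero-mean noise.  The multiplicative
#' fusion ROI mean therefore recovers the product of the EEG and fMRI
#' truths (exactly, when noise is zero).
#'
#' @param truth truth table from [generate_cohort()]
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param geometry optionally a prebuilt [build_geometry()] result
#' @param subjects optional subset of subject ids
#' @return list: `geometry`, `subjects` (per subject, per wave: `mesh`,
#'   `contrast`)
#' @export
generate_neural_data <- function(truth, config = generator_config(), seed = 1,
                                 geometry = NULL, subjects = NULL) {
  set.seed(seed)
  geom <- geometry %||% build_geometry(config)
  ids <- subjects %||% truth$subject_id
  nel <- nrow(geom$mesh$elements)
  nvox <- length(geom$template$data)
  el_sd <- config$noise$element_cdr_sd
  vx_sd <- config$noise$roi_voxel_sd
  out <- list()
  for (sid in ids) {
    tr <- truth[truth$subject_id == sid, ]
    waves <- list()
    for (wave in c("13", "15")) {
      cdr_correct <- rep(0.5, nel)
      cdr_error <- 0.5 + stats::rnorm(nel, 0, el_sd)
      contrast <- stats::rnorm(nvox, 0, vx_sd)
      for (reg in c("dacc", "pcc")) {
        lreg <- region_label(reg)
        e_true <- tr[[paste("eeg", reg, wave, sep = "_")]]
        f_true <- tr[[paste("fmri", reg, wave, sep = "_")]]
        esel <- seq_len(nel) %in% geom$element_plant[[reg]]
        cdr_error[esel] <- 0.5 + e_true + stats::rnorm(sum(esel), 0, el_sd)
        vsel <- as.vector(geom$mask$data) == lreg
        contrast[vsel] <- f_true + stats::rnorm(sum(vsel), 0, vx_sd)
      }
      waves[[wave]] <- list(
        mesh = tet_mesh(geom$mesh$nodes, geom$mesh$elements,
                        cdr_error = cdr_error, cdr_correct = cdr_correct),
        contrast = volume(array(contrast, dim(geom$template$data)),
                          geom$template$affine))
    }
    out[[sid]] <- waves
  }
  list(geometry = geom, subjects = out)
}

#' Generate response-locked flanker epochs with a planted ERN
#'
#' Error trials carry a negative-going Gaussian deflection at the
#' configured latency on the frontocentral cluster, with amplitude
#' proportional to the subject's true wave-specific EEG dACC activation;
#' correct trials carry noise only.
#'
#' @param truth truth table from [generate_cohort()]
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param subjects optional subset of subject ids
#' @return nested list `epochs[[subject]][[wave]]` of [epoch_set()]s
#' @export
generate_epochs <- function(truth, config = generator_config(), seed = 1,
                            subjects = NULL) {
  set.seed(seed)
  ec <- config$epochs
  time_ms <- seq(ec$window_ms[1], ec$window_ms[2], by = 1000 / ec$srate)
  if (ec$ern_latency_ms < min(time_ms) || ec$ern_latency_ms > max(time_ms)) {
    stop("epoch window does not cover the configured ERN latency")
  }
  nch <- length(ec$channels)
  bump <- exp(-0.5 * ((time_ms - ec$ern_latency_ms) / ec$ern_width_ms)^2)
  chan_w <- ifelse(ec$channels %in% ec$cluster, 1, 0.3)
  ids <- subjects %||% truth$subject_id
  out <- list()
  for (sid in ids) {
    tr <- truth[truth$subject_id == sid, ]
    waves <- list()
    for (wave in c("13", "15")) {
      amp <- ec$amp_per_unit * tr[[paste("eeg", "dacc", wave, sep = "_")]]
      ntr <- ec$n_trials_error + ec$n_trials_correct
      cond <- rep(c("inc_error", "inc_correct"),
                  c(ec$n_trials_error, ec$n_trials_correct))
      dat <- array(stats::rnorm(nch * length(time_ms) * ntr,
                                0, config$noise$epoch_noise_sd),
                   c(nch, length(time_ms), ntr))
      signal <- outer(chan_w, bump) * amp
      for (t_ in which(cond == "inc_error")) {
        dat[, , t_] <- dat[, , t_] + signal
      }
      waves[[wave]] <- epoch_set(dat, time_ms, ec$channels, cond, ec$srate)
    }
    out[[sid]] <- waves
  }
  out
}
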
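# CDR differences, voxel-element mapping, multiplicative fusion, ROI means.

test_that("CDR difference is error minus correct, per element", {
  mesh <- toy_two_tet_mesh(cdr_error = c(2, 1), cdr_correct = c(0.5, 1))
  d <- cdr_difference(mesh)
  expect_equal(d$diff, c(1.5, 0))
  same <- toy_two_tet_mesh(cdr_error = c(1, 1), cdr_correct = c(1, 1))
  expect_equal(cdr_difference(same)$diff, c(0, 0))
  null_sub <- toy_two_tet_mesh(cdr_error = c(3, -2), cdr_correct = c(0, 0))
  expect_equal(cdr_difference(null_sub)$diff, c(3, -2))
  bare <- tet_mesh(mesh$nodes, mesh$elements)
  expect_error(cdr_difference(bare), "cdr_error")
})

test_that("degenerate elements are rejected at mesh construction", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))  # coplanar
  expect_error(tet_mesh(nodes, rbind(c(1, 2, 3, 4))), "degenerate")
})

test_that("voxel-element containment follows the barycentric rule", {
  mesh <- toy_two_tet_mesh()
  # one centroid strictly inside element 2 (above z = 0), one outside hull
  vol_in <- volume(array(0, c(1, 1, 1)),
                   rbind(c(1, 0, 0, 0.1), c(0, 1, 0, 0.1), c(0, 0, 1, 0.2),
                         c(0, 0, 0, 1)))
  expect_equal(map_voxels_to_elements(vol_in, mesh), 2L)
  vol_out <- volume(array(0, c(1, 1, 1)),
                    rbind(c(1, 0, 0, 5), c(0, 1, 0, 5), c(0, 0, 1, 5),
                          c(0, 0, 0, 1)))
  expect_true(is.na(map_voxels_to_elements(vol_out, mesh)))
  # centroid exactly on the shared face: the lower element index wins
  vol_face <- volume(array(0, c(1, 1, 1)),
                     rbind(c(1, 0, 0, 0.25), c(0, 1, 0, 0.25), c(0, 0, 1, 0),
                           c(0, 0, 0, 1)))
  expect_equal(map_voxels_to_elements(vol_face, mesh), 1L)
})

test_that("pruned mapping agrees with exhaustive containment", {
  cfg <- small_config()
  cfg$geometry$box_mm <- 12; cfg$geometry$mesh_spacing_mm <- 6
  cfg$geometry$voxel_mm <- 3
  ax <- seq(0, 12, by = 6); nn <- length(ax)
  # reuse the package mesh builder through build_geometry-sized settings
  cfg$geometry$dacc_box <- list(lower = c(0, 0, 0), upper = c(6, 6, 6))
  cfg$geometry$pcc_box <- list(lower = c(6, 6, 6), upper = c(12, 12, 12))
  geom <- build_geometry(cfg)
  expect_lte(nrow(geom$mesh$elements), 100)
  m1 <- map_voxels_to_elements(geom$template, geom$mesh)
  m2 <- map_voxels_to_elements(geom$template, geom$mesh, exhaustive = TRUE)
  expect_identical(m1, m2)
})

test_that("fusion multiplies mapped voxels and stays undefined elsewhere", {
  mesh <- toy_two_tet_mesh(cdr_error = c(2, 0.5), cdr_correct = c(0.5, 0.5))
  vol <- toy_volume(seq_len(64) / 10)
  map <- map_voxels_to_elements(vol, mesh)
  expect_true(any(!is.na(map)) && any(is.na(map)))
  fused <- fuse(vol, cdr_difference(mesh), map)
  # hand enumeration: value x diff of the containing element
  diffs <- c(1.5, 0)
  for (v in which(!is.na(map))) {
    expect_equal(as.vector(fused$data)[v],
                 as.vector(vol$data)[v] * diffs[map[v]])
  }
  expect_true(all(is.na(as.vector(fused$data)[is.na(map)])))
  # identity and annihilation
  ones <- toy_two_tet_mesh(cdr_error = c(1.5, 1.5), cdr_correct = c(0.5, 0.5))
  f1 <- fuse(vol, cdr_difference(ones), map)
  expect_equal(as.vector(f1$data)[!is.na(map)],
               as.vector(vol$data)[!is.na(map)])
  zvol <- vol; zvol$data[] <- 0
  f0 <- fuse(zvol, cdr_difference(mesh), map)
  expect_true(all(f0$data[!is.na(map)] == 0))
})

test_that("ROI volume means average defined labeled voxels only", {
  vals <- toy_volume(rep(NA_real_, 64))
  mask <- toy_volume(rep(0L, 64))
  mask$data[1:6] <- 1L
  vals$data[1:3] <- c(1, 2, 3)
  m <- roi_mean_volume(vals, mask, "dacc")
  expect_equal(as.numeric(m), 2)
  expect_equal(attr(m, "n_voxels"), 3L)
  # all-undefined ROI: missing with a reason, not zero
  vals$data[1:6] <- NA
  m2 <- roi_mean_volume(vals, mask, "dacc")
  expect_true(is.na(m2))
  expect_match(attr(m2, "reason"), "dacc")
  expect_error(roi_mean_volume(vals, mask, "pcc"), "absent")
  # brute-force enumeration on a random mixed configuration
  set.seed(2)
  vals$data[] <- ifelse(runif(64) < 0.4, NA, rnorm(64))
  mask$data[] <- sample(0:2, 64, replace = TRUE)
  for (reg in c("dacc", "pcc")) {
    lab <- if (reg == "dacc") 1 else 2
    sel <- mask$data == lab & !is.na(vals$data)
    expected <- if (any(sel)) mean(vals$data[sel]) else NA_real_
    expect_equal(as.numeric(roi_mean_volume(vals, mask, reg)), expected)
  }
})

test_that("ROI mesh means use element centroids against the label grid", {
  mesh <- toy_two_tet_mesh(cdr_error = c(1, 2.5), cdr_correct = c(0.5, 0.5))
  # mask grid covering both tetrahedra; label the upper half-space dacc
  aff <- diag(c(0.5, 0.5, 0.5, 1)); aff[1:3, 4] <- c(-0.75, -0.75, -0.75)
  lab <- array(0L, c(4, 4, 4))
  mask <- volume(lab, aff)
  cent <- voxel_centroids(mask)
  mask$data[cent[, 3] > 0] <- 1L
  d <- cdr_difference(mesh)
  m <- roi_mean_mesh(d, mask, "dacc")   # only element 2's centroid has z > 0
  expect_equal(as.numeric(m), 2.0)
  expect_equal(attr(m, "n_elements"), 1L)
  mask$data[] <- 0L; mask$data[1] <- 1L  # corner away from both centroids
  expect_true(is.na(roi_mean_mesh(d, mask, "dacc")))
})

test_that("fusion ROI means are bilinear in contrast and CDR difference", {
  cfg <- small_config(n = 2L)
  cfg$noise$roi_voxel_sd <- 0.02; cfg$noise$element_cdr_sd <- 0.02
  g <- generate_cohort(cfg, 13)
  nd <- generate_neural_data(g$truth, cfg, seed = 14)
  geom <- nd$geometry
  sw <- nd$subjects[[1]][["13"]]
  d <- cdr_difference(sw$mesh)
  base <- roi_mean_volume(fuse(sw$contrast, d, geom$map), geom$mask, "dacc")
  # scale the contrast
  v2 <- sw$contrast; v2$data <- v2$data * 3
  expect_equal(as.numeric(roi_mean_volume(fuse(v2, d, geom$map),
                                          geom$mask, "dacc")),
               3 * as.numeric(base), tolerance = 1e-10)
  # scale the CDR difference
  d2 <- d; d2$diff <- d2$diff * -2
  expect_equal(as.numeric(roi_mean_volume(fuse(sw$contrast, d2, geom$map),
                                          geom$mask, "dacc")),
               -2 * as.numeric(base), tolerance = 1e-10)
})

test_that("noise-free generation round-trips truths through all modalities", {
  cfg <- small_config(n = 4L)
  cfg$noise$roi_voxel_sd <- 0; cfg$noise$element_cdr_sd <- 0
  g <- generate_cohort(cfg, 7)
  nd <- generate_neural_data(g$truth, cfg, seed = 8)
  w <- scores_wide(build_roi_score_table(nd))
  expect_equal(w$fmri_dacc_13, g$truth$fmri_dacc_13, tolerance = 1e-12)
  expect_equal(w$eeg_pcc_15, g$truth$eeg_pcc_15, tolerance = 1e-12)
  expect_equal(w$fusion_dacc_13,
               g$truth$fmri_dacc_13 * g$truth$eeg_dacc_13, tolerance = 1e-12)
})

test_that("noisy ROI recovery tracks the closed-form attenuation bound", {
  cfg <- small_config(n = 120L)
  cfg$noise$roi_voxel_sd <- 0.05
  g <- generate_cohort(cfg, 31)
  nd <- generate_neural_data(g$truth, cfg, seed = 32)
  w <- scores_wide(build_roi_score_table(nd))
  n_vox <- sum(nd$geometry$mask$data == 1)
  # score = truth + mean of n_vox iid noise voxels, so
  # cor(score, truth) ~ sqrt(var_t / (var_t + sd^2 / n_vox))
  var_t <- cfg$neural$fmri$dacc$var_13
  rho <- sqrt(var_t / (var_t + cfg$noise$roi_voxel_sd^2 / n_vox))
  r_obs <- cor(w$fmri_dacc_13, g$truth$fmri_dacc_13)
  expect_gt(r_obs, rho - 0.02)
})

test_that("score table propagates partially missing modalities", {
  cfg <- small_config(n = 2L)
  g <- generate_cohort(cfg, 3)
  nd <- generate_neural_data(g$truth, cfg, seed = 4)
  # subject 2 loses its wave-15 contrast volume
  nd$subjects[[2]][["15"]]$contrast <- NULL
  tidy <- build_roi_score_table(nd)
  s2 <- tidy[tidy$subject_id == names(nd$subjects)[2] & tidy$wave == "15", ]
  expect_true(all(is.na(s2$score[s2$modality %in% c("fmri", "fusion")])))
  expect_true(all(!is.na(s2$score[s2$modality == "eeg"])))
  s1 <- tidy[tidy$subject_id == names(nd$subjects)[1], ]
  expect_equal(sum(!is.na(s1$score)), 12)  # complete subject: all 12 scores
})

test_that("mesh CSV and NIfTI round trips preserve geometry and values", {
  mesh <- toy_two_tet_mesh()
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  write_mesh_csv(mesh, np, ep)
  back <- read_mesh_csv(np, ep)
  expect_equal(back$nodes, mesh$nodes, ignore_attr = TRUE)
  expect_equal(back$cdr_error, mesh$cdr_error)
  vol <- toy_volume(rnorm(64))
  vp <- tempfile(fileext = ".nii")
  write_volume_nifti(vol, vp)
  vback <- read_volume_nifti(vp)
  expect_equal(vback$data, vol$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unclass(vback$affine), unclass(vol$affine), tolerance = 1e-6,
               ignore_attr = TRUE)
})
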
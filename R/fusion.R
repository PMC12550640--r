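# EEG-fMRI fusion: current-density-reconstruction (CDR) difference maps on
# a tetrahedral source mesh, voxel-to-element intersection, multiplicative
# fusion with the fMRI error contrast, and ROI means for all modalities.

#' Construct a tetrahedral source mesh
#'
#' @param nodes numeric matrix (n x 3) of node coordinates in mm, in the
#'   same world (RAS) space as the volume affines
#' @param elements integer matrix (m x 4) of node indices
#' @param cdr_error,cdr_correct per-element current-density values for the
#'   two trial conditions (may be `NULL` until filled)
#' @return a `tet_mesh`; elements are re-oriented to positive volume, and a
#'   degenerate (zero-volume) element is an error
#' @export
tet_mesh <- function(nodes, elements, cdr_error = NULL, cdr_correct = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elements) == 4)
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("element node indices out of range")
  }
  vol6 <- tet_signed_volumes(nodes, elements)
  if (any(abs(vol6) < 1e-12)) {
    stop("degenerate (zero-volume) element(s): ",
         paste(utils::head(which(abs(vol6) < 1e-12)), collapse = ", "))
  }
  flip <- vol6 < 0
  if (any(flip)) elements[flip, c(1, 2)] <- elements[flip, c(2, 1)]
  m <- nrow(elements)
  check_vals <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (length(v) != m || any(!is.finite(v))) {
      stop(what, " must be a finite vector with one value per element")
    }
    as.numeric(v)
  }
  structure(list(nodes = nodes, elements = elements,
                 cdr_error = check_vals(cdr_error, "cdr_error"),
                 cdr_correct = check_vals(cdr_correct, "cdr_correct")),
            class = "tet_mesh")
}

tet_signed_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE]
  c_ <- nodes[elements[, 3], , drop = FALSE]
  d <- nodes[elements[, 4], , drop = FALSE]
  u <- a - d; v <- b - d; w <- c_ - d
  u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
    u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
    u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
}

#' Construct a volume (value grid plus RAS affine)
#'
#' @param data 3-D numeric array
#' @param affine 4 x 4 matrix mapping 0-based voxel indices (i, j, k, 1) to
#'   world mm; must be invertible
#' @export
volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("volume affine is singular")
  structure(list(data = data, affine = affine), class = "ern_volume")
}

#' World coordinates of all voxel centroids
#' @param vol an `ern_volume`
#' @return (n_voxels x 3) matrix, voxels in array order
#' @export
voxel_centroids <- function(vol) {
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  xyz <- cbind(idx, 1) %*% t(vol$affine)
  xyz[, 1:3, drop = FALSE]
}

#' CDR difference map (error minus correct)
#'
#' @param mesh a `tet_mesh` with both conditions' CDR values
#' @param ern_latency_ms optional peak latency provenance to carry along
#' @return a `cdr_diff_map`: the mesh geometry plus per-element difference
#' @export
cdr_difference <- function(mesh, ern_latency_ms = NA_real_) {
  if (is.null(mesh$cdr_error) || is.null(mesh$cdr_correct)) {
    stop("mesh must carry cdr_error and cdr_correct values")
  }
  structure(list(nodes = mesh$nodes, elements = mesh$elements,
                 diff = mesh$cdr_error - mesh$cdr_correct,
                 ern_latency_ms = ern_latency_ms),
            class = "cdr_diff_map")
}

#' Map fMRI voxels to containing mesh elements
#'
#' A voxel "overlaps" an element when its centroid lies inside the
#' tetrahedron (barycentric containment, tolerance 1e-9).  A centroid on a
#' shared face belongs to the containing element with the lowest index;
#' centroids outside the mesh hull map to nothing.
#'
#' @param vol an `ern_volume` (defines the voxel grid)
#' @param mesh a `tet_mesh` or `cdr_diff_map` sharing the volume's world
#'   space
#' @param exhaustive test every voxel against every element (reference
#'   path, quadratic; the default uses bounding-box candidate pruning)
#' @return integer vector, one entry per voxel in array order: element
#'   index or `NA`
#' @export
map_voxels_to_elements <- function(vol, mesh, exhaustive = FALSE) {
  tol <- 1e-9
  pts <- voxel_centroids(vol)
  nvox <- nrow(pts)
  assign_el <- rep(NA_integer_, nvox)
  nel <- nrow(mesh$elements)
  inv_aff <- solve(vol$affine)
  d <- dim(vol$data)
  contains <- function(el, cand) {
    v <- mesh$nodes[mesh$elements[el, ], , drop = FALSE]
    t_inv <- tryCatch(solve(t(v[1:3, ] - matrix(v[4, ], 3, 3, byrow = TRUE))),
                      error = function(e) NULL)
    if (is.null(t_inv)) stop("degenerate element ", el)
    rel <- sweep(pts[cand, , drop = FALSE], 2, v[4, ])
    b <- rel %*% t(t_inv)
    cand[b[, 1] >= -tol & b[, 2] >= -tol & b[, 3] >= -tol &
           (b[, 1] + b[, 2] + b[, 3]) <= 1 + tol]
  }
  if (exhaustive) {
    for (el in seq_len(nel)) {
      cand <- which(is.na(assign_el))
      if (!length(cand)) break
      hit <- contains(el, cand)
      assign_el[hit] <- el
    }
    return(assign_el)
  }
  # candidate pruning: voxel-index bounding box of each element
  for (el in seq_len(nel)) {
    v <- mesh$nodes[mesh$elements[el, ], , drop = FALSE]
    corners <- cbind(v, 1) %*% t(inv_aff)
    lo <- pmax(floor(apply(corners[, 1:3, drop = FALSE], 2, min) - 1e-6), 0)
    hi <- pmin(ceiling(apply(corners[, 1:3, drop = FALSE], 2, max) + 1e-6),
               d - 1)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    cand <- as.vector(outer(outer(ii + 1L, jj * d[1], "+"),
                            kk * d[1] * d[2], "+"))
    cand <- cand[is.na(assign_el[cand])]
    if (!length(cand)) next
    hit <- contains(el, cand)
    assign_el[hit] <- el
  }
  assign_el
}

#' Multiply the fMRI contrast into the CDR difference map
#'
#' Each mapped voxel's contrast value is multiplied by the CDR-difference
#' value of its containing element; unmapped voxels remain undefined.
#'
#' @param vol contrast `ern_volume`
#' @param diff a `cdr_diff_map`
#' @param map voxel-to-element map from [map_voxels_to_elements()] built
#'   against this volume and mesh
#' @return a `fusion_volume`: value array (NA where undefined) + affine
#' @export
fuse <- function(vol, diff, map) {
  if (length(map) != length(vol$data)) {
    stop("voxel-element map does not match the volume grid")
  }
  if (max(map, na.rm = TRUE) > length(diff$diff)) {
    stop("voxel-element map references elements beyond the difference map")
  }
  fused <- rep(NA_real_, length(vol$data))
  ok <- !is.na(map)
  fused[ok] <- as.vector(vol$data)[ok] * diff$diff[map[ok]]
  structure(list(data = array(fused, dim(vol$data)), affine = vol$affine,
                 defined = array(ok, dim(vol$data))),
            class = "fusion_volume")
}

region_label <- function(region) {
  switch(match.arg(region, c("dacc", "pcc")), dacc = 1L, pcc = 2L)
}

#' ROI mean of a contrast or fusion volume
#'
#' Arithmetic mean over voxels carrying the region label and a defined
#' value.  An empty contributing set yields `NA` with a `reason` attribute
#' (never a silent zero); the contributing voxel count is attached as
#' `n_voxels`.
#'
#' @param values an `ern_volume` or `fusion_volume`
#' @param mask an `ern_volume` of integer labels (0 background, 1 dACC,
#'   2 PCC) on the same grid/affine
#' @param region `"dacc"` or `"pcc"`
#' @export
roi_mean_volume <- function(values, mask, region) {
  if (!identical(dim(values$data), dim(mask$data)) ||
      max(abs(values$affine - mask$affine)) > 1e-8) {
    stop("mask grid/affine does not match the value volume")
  }
  lab <- region_label(region)
  if (!any(mask$data == lab)) stop("region ", region, " absent from mask")
  sel <- mask$data == lab & !is.na(values$data)
  if (!any(sel)) {
    return(structure(NA_real_, n_voxels = 0L,
                     reason = paste0("no defined voxels in ", region)))
  }
  structure(mean(values$data[sel]), n_voxels = sum(sel))
}

#' ROI mean of a CDR difference map
#'
#' Mean difference over elements whose centroid falls inside a voxel
#' carrying the region label (the mesh-side mirror of the voxel rule).
#'
#' @param diff a `cdr_diff_map`
#' @param mask label `ern_volume`
#' @param region `"dacc"` or `"pcc"`
#' @export
roi_mean_mesh <- function(diff, mask, region) {
  lab <- region_label(region)
  if (!any(mask$data == lab)) stop("region ", region, " absent from mask")
  labs <- element_regions(diff, mask)
  sel <- labs == lab
  if (!any(sel)) {
    return(structure(NA_real_, n_elements = 0L,
                     reason = paste0("no element centroids in ", region)))
  }
  structure(mean(diff$diff[sel]), n_elements = sum(sel))
}

#' Region label of each mesh element (by centroid voxel membership)
#' @keywords internal
element_regions <- function(mesh, mask) {
  cent <- (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
             mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
  ijk <- cbind(cent, 1) %*% t(solve(mask$affine))
  ijk <- round(ijk[, 1:3, drop = FALSE])
  d <- dim(mask$data)
  inside <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
    ijk[, 3] >= 0 & ijk[, 3] < d[3]
  labs <- rep(0L, nrow(ijk))
  labs[inside] <- mask$data[ijk[inside, , drop = FALSE] + 1]
  labs
}

#' NIfTI-1 I/O for volumes
#'
#' @param vol an `ern_volume`
#' @param path output `.nii` path
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  volume(array(as.numeric(img), dim(img)[1:3]),
         structure(RNifti::xform(img), class = "matrix"))
}

#' Mesh CSV I/O (nodes: id,x,y,z; elements: id,n1..n4,cdr_error,cdr_correct)
#' @param mesh a `tet_mesh`
#' @param nodes_path,elements_path output CSV paths
#' @export
write_mesh_csv <- function(mesh, nodes_path, elements_path) {
  utils::write.csv(data.frame(id = seq_len(nrow(mesh$nodes)),
                              x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                              z = mesh$nodes[, 3]),
                   nodes_path, row.names = FALSE)
  utils::write.csv(data.frame(id = seq_len(nrow(mesh$elements)),
                              n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                              n3 = mesh$elements[, 3], n4 = mesh$elements[, 4],
                              cdr_error = mesh$cdr_error %||% NA,
                              cdr_correct = mesh$cdr_correct %||% NA),
                   elements_path, row.names = FALSE)
  invisible(c(nodes_path, elements_path))
}

#' @rdname write_mesh_csv
#' @export
read_mesh_csv <- function(nodes_path, elements_path) {
  nd <- utils::read.csv(nodes_path)
  el <- utils::read.csv(elements_path)
  tet_mesh(as.matrix(nd[, c("x", "y", "z")]),
           as.matrix(el[, c("n1", "n2", "n3", "n4")]),
           cdr_error = if (all(is.na(el$cdr_error))) NULL else el$cdr_error,
           cdr_correct = if (all(is.na(el$cdr_correct))) NULL else el$cdr_correct)
}
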
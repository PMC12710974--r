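# Voxel grids (voxel-center convention, mm) and the gridded field containers:
# unit-vector orientation fields and scalar strain maps.

#' Construct a voxel grid
#'
#' Axis-aligned grid with isotropic spacing; `origin` is the center of voxel
#' (1,1,1). All package volumes (orientation fields, similarity and strain
#' maps) share this geometry, and it maps directly onto a NIfTI affine.
#'
#' @param origin length-3 numeric, center of the first voxel (mm).
#' @param spacing voxel edge length (mm); the fiber pipeline default is
#'   0.325 mm.
#' @param dim length-3 integer vector of voxel counts.
#' @return object of class `vox_grid`.
#' @export
vox_grid <- function(origin, spacing, dim) {
  stopifnot(length(origin) == 3, spacing > 0, length(dim) == 3, all(dim >= 1))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = as.integer(dim)), class = "vox_grid")
}

#' Grid covering a bounding box
#'
#' @param lo,hi corners of the box (mm).
#' @param spacing voxel edge (mm).
#' @param pad voxels of padding on each side.
#' @return a [vox_grid()].
#' @export
grid_from_bbox <- function(lo, hi, spacing = 0.325, pad = 1L) {
  n <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 2L * pad)
  # first voxel center half a voxel inside the padded box
  vox_grid(as.numeric(lo - pad * spacing + spacing / 2), spacing, n)
}

#' Number of voxels in a grid
#' @param grid a [vox_grid()].
#' @return integer count.
#' @export
n_voxels <- function(grid) prod(grid$dim)

#' Map world coordinates to integer voxel triplets
#' @param grid a [vox_grid()]; @param p N x 3 positions (mm).
#' @return N x 3 integer matrix (1-based; may fall outside the grid).
#' @export
world_to_voxel <- function(grid, p) {
  p <- to_points(p)
  v <- sweep(p, 2, grid$origin) / grid$spacing
  matrix(as.integer(round(v)), ncol = 3) + 1L
}

voxel_in_grid <- function(grid, v) {
  v[, 1] >= 1L & v[, 1] <= grid$dim[1] &
  v[, 2] >= 1L & v[, 2] <= grid$dim[2] &
  v[, 3] >= 1L & v[, 3] <= grid$dim[3]
}

#' Linear voxel ids of voxel triplets
#' @param grid a [vox_grid()]; @param v N x 3 voxel triplets.
#' @return integer vector (NA outside the grid).
#' @export
voxel_id <- function(grid, v) {
  ok <- voxel_in_grid(grid, v)
  id <- (v[, 3] - 1L) * grid$dim[1] * grid$dim[2] +
        (v[, 2] - 1L) * grid$dim[1] + v[, 1]
  id[!ok] <- NA_integer_
  id
}

#' World coordinates of voxel centers
#' @param grid a [vox_grid()]; @param ids linear voxel ids (default: all).
#' @return N x 3 matrix of centers (mm).
#' @export
voxel_centers <- function(grid, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(n_voxels(grid))
  ids0 <- ids - 1L
  nx <- grid$dim[1]; nxy <- nx * grid$dim[2]
  k <- ids0 %/% nxy
  j <- (ids0 %% nxy) %/% nx
  i <- ids0 %% nx
  cbind(i, j, k) * grid$spacing +
    matrix(grid$origin, length(ids), 3, byrow = TRUE)
}

#' Orientation field on a voxel grid
#'
#' Per-voxel unit 3-vectors; empty voxels hold `NA`. Sign is not meaningful
#' downstream (axial data, compared by absolute cosine).
#'
#' @param grid a [vox_grid()].
#' @param vectors `n_voxels x 3` matrix of unit vectors or NA rows.
#' @param ambiguous optional logical vector flagging voxels whose principal
#'   direction was degenerate (eigenvalue tie).
#' @return object of class `orientation_field`.
#' @export
orientation_field <- function(grid, vectors, ambiguous = NULL) {
  stopifnot(nrow(vectors) == n_voxels(grid), ncol(vectors) == 3)
  structure(list(grid = grid, vectors = vectors, ambiguous = ambiguous),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s voxels @ %.3g mm, %d non-empty\n",
              paste(x$grid$dim, collapse = "x"), x$grid$spacing,
              sum(!is.na(x$vectors[, 1]))))
  invisible(x)
}

#' Rasterize an analytic direction field onto a grid
#' @param afield an [analytic_slab_orientation()]-style field.
#' @param grid a [vox_grid()]; @param mask_ids optional voxel ids to fill.
#' @return an [orientation_field()].
#' @export
rasterize_field <- function(afield, grid, mask_ids = NULL) {
  ids <- if (is.null(mask_ids)) seq_len(n_voxels(grid)) else mask_ids
  ctr <- voxel_centers(grid, ids)
  vec <- matrix(NA_real_, n_voxels(grid), 3)
  vec[ids, ] <- afield$direction(ctr)
  orientation_field(grid, vec)
}

#' Scalar strain map on a voxel grid
#'
#' @param grid a [vox_grid()].
#' @param values per-voxel strain (elongation ratio minus one); `NA` where no
#'   fiber was sampled.
#' @param counts per-voxel fiber sample counts.
#' @return object of class `strain_map`.
#' @export
strain_map_grid <- function(grid, values, counts) {
  stopifnot(length(values) == n_voxels(grid))
  structure(list(grid = grid, values = values, counts = counts),
            class = "strain_map")
}

#' @export
print.strain_map <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("<strain_map> %s voxels, %d sampled, strain range [%.3g, %.3g]\n",
              paste(x$grid$dim, collapse = "x"), sum(ok),
              if (any(ok)) min(x$values[ok]) else NA,
              if (any(ok)) max(x$values[ok]) else NA))
  invisible(x)
}
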
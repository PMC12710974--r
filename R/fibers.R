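# Fiber machinery: voxelized inward-normal fields, radial-fiber generation by
# advection through the field, fiber advection through the deformation map,
# randomized quadratic Bezier bundles, and per-voxel primary-peak extraction
# via the orientation tensor.

#' Construct a fiber set
#'
#' @param fibers list of polylines (each an `n x 3` matrix, `n >= 2`,
#'   consecutive points distinct).
#' @param seeds optional matrix of seed surface points (one row per fiber).
#' @return object of class `fiber_set`.
#' @export
fiber_set <- function(fibers, seeds = NULL) {
  stopifnot(is.list(fibers))
  for (f in fibers) {
    if (nrow(f) < 2L) stop("each fiber needs at least 2 points")
  }
  structure(list(fibers = fibers, seeds = seeds), class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  np <- vapply(x$fibers, nrow, integer(1))
  cat(sprintf("<fiber_set> %d fibers, %d points total (median %d per fiber)\n",
              length(x$fibers), sum(np), as.integer(stats::median(np))))
  invisible(x)
}

#' Fiber lengths
#' @param fibers a [fiber_set()].
#' @return numeric vector of polyline lengths (mm).
#' @export
fiber_lengths <- function(fibers) {
  vapply(fibers$fibers, function(f) {
    sum(sqrt(rowSums((f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE])^2)))
  }, numeric(1))
}

#' Voxel occupancy of a tetrahedral mesh
#' @param mesh a [tet_mesh()]; @param grid a [vox_grid()].
#' @return logical vector: voxel centers inside the mesh.
#' @export
mesh_occupancy <- function(mesh, grid) {
  ctr <- voxel_centers(grid)
  loc <- cpp_locate_points(mesh$nodes, mesh$tets - 1L, ctr, 1e-6)
  !is.na(loc$tet)
}

#' Voxelized inward-normal field of a surface
#'
#' Voxelizes the cortical surface: each cortical face is densely sampled, its
#' inward-flipped unit normal splatted into every voxel crossed while
#' marching from the surface sample along the inward normal down to `depth`;
#' vectors are averaged per voxel, smoothed by `smooth_iters` passes of
#' 6-neighborhood vector averaging (which also diffuses the field into
#' adjacent empty voxels), and renormalized to unit length. Voxels never
#' reached stay empty.
#'
#' @param mesh a [tet_mesh()]; cortical faces from the metadata (all surface
#'   faces if absent).
#' @param voxel_size voxel edge (mm), default 0.325.
#' @param smooth_iters smoothing passes.
#' @param depth how far inward to propagate the normals (mm).
#' @param grid optional [vox_grid()] to use instead of one fitted to the mesh.
#' @return an [orientation_field()].
#' @export
inward_normal_field <- function(mesh, voxel_size = 0.325, smooth_iters = 2L,
                                depth = 4, grid = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (is.null(grid))
    grid <- grid_from_bbox(apply(mesh$nodes, 2, min),
                           apply(mesh$nodes, 2, max), voxel_size)
  cf <- mesh$metadata$cortical_faces
  if (is.null(cf)) cf <- seq_len(nrow(mesh$faces))
  faces <- mesh$faces[cf, , drop = FALSE]
  nrm <- -face_normals(mesh$nodes, faces)      # inward
  step <- grid$spacing / 2

  acc <- matrix(0, n_voxels(grid), 3)
  cnt <- numeric(n_voxels(grid))
  nsub <- max(1L, ceiling(sqrt(max(face_areas(mesh$nodes, faces))) / step))
  # barycentric subsample lattice of each face
  bc <- expand.grid(a = seq(0, 1, length.out = nsub + 1L),
                    b = seq(0, 1, length.out = nsub + 1L))
  bc <- bc[bc$a + bc$b <= 1 + 1e-12, ]
  bc$c <- pmax(0, 1 - bc$a - bc$b)
  depths <- seq(0, depth, by = step)
  for (kk in seq_len(nrow(bc))) {
    s <- bc$a[kk] * mesh$nodes[faces[, 1], , drop = FALSE] +
         bc$b[kk] * mesh$nodes[faces[, 2], , drop = FALSE] +
         bc$c[kk] * mesh$nodes[faces[, 3], , drop = FALSE]
    for (dpt in depths) {
      p <- s + dpt * nrm
      id <- voxel_id(grid, world_to_voxel(grid, p))
      ok <- !is.na(id)
      if (!any(ok)) next
      sub <- id[ok]
      acc[sub, ] <- acc[sub, ] + nrm[ok, , drop = FALSE]
      cnt[sub] <- cnt[sub] + 1
    }
  }
  vec <- acc / pmax(cnt, 1)
  vec[cnt == 0, ] <- NA_real_
  vec <- smooth_vector_grid(grid, vec, smooth_iters)
  nn <- sqrt(rowSums(vec^2))
  vec <- vec / pmax(nn, 1e-12)
  vec[is.na(nn) | nn < 1e-9, ] <- NA_real_
  orientation_field(grid, vec)
}

# 6-neighborhood vector averaging; empty voxels adjacent to filled ones get
# the neighbour average (diffusion), filled voxels are re-averaged with their
# filled neighbours.
smooth_vector_grid <- function(grid, vec, iters) {
  if (iters <= 0L) return(vec)
  dims <- grid$dim
  nv <- n_voxels(grid)
  ids <- seq_len(nv)
  i0 <- (ids - 1L) %% dims[1]
  j0 <- ((ids - 1L) %/% dims[1]) %% dims[2]
  k0 <- (ids - 1L) %/% (dims[1] * dims[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- lapply(shifts, function(s) {
    i <- i0 + s[1]; j <- j0 + s[2]; k <- k0 + s[3]
    ok <- i >= 0 & i < dims[1] & j >= 0 & j < dims[2] & k >= 0 & k < dims[3]
    idx <- ifelse(ok, k * dims[1] * dims[2] + j * dims[1] + i + 1L, NA_integer_)
    idx
  })
  for (it in seq_len(iters)) {
    filled <- !is.na(vec[, 1])
    acc <- ifelse(filled, 1, 0) * ifelse(is.na(vec), 0, vec)
    acc[is.na(acc)] <- 0
    wt <- as.numeric(filled)
    for (idx in nb) {
      ok <- !is.na(idx)
      vsub <- matrix(0, nv, 3)
      fsub <- logical(nv)
      vsub[ok, ] <- vec[idx[ok], , drop = FALSE]
      fsub[ok] <- filled[idx[ok]]
      vsub[!fsub | is.na(vsub[, 1]), ] <- 0
      acc <- acc + vsub
      wt <- wt + as.numeric(fsub)
    }
    new <- acc / pmax(wt, 1)
    new[wt == 0, ] <- NA_real_
    vec <- new
  }
  vec
}

# field lookup: vectors at world points (NA rows when empty/outside)
field_at <- function(field, p) {
  id <- voxel_id(field$grid, world_to_voxel(field$grid, to_points(p)))
  out <- matrix(NA_real_, length(id), 3)
  ok <- !is.na(id)
  out[ok, ] <- field$vectors[id[ok], , drop = FALSE]
  out
}

#' Generate radial fibers from a normal field
#'
#' Seeds points uniformly by area on the cortical surface (seeded RNG) and
#' integrates each fiber inward through the (smoothed) inward-normal field
#' with fixed step length, terminating at `max_len`, on leaving the mesh, or
#' on entering an empty voxel. With `smooth_iters = 0` at field construction
#' and a single step this reduces to strictly straight normal fibers.
#'
#' @param mesh a [tet_mesh()].
#' @param field an [inward_normal_field()].
#' @param step advection step (mm).
#' @param max_len maximum fiber length (mm).
#' @param n_seeds number of surface seed points.
#' @param seed RNG seed (integer) for reproducible seeding.
#' @return a [fiber_set()]; the number of skipped seeds (landing in empty
#'   voxels) is attached as attribute `n_skipped`.
#' @export
generate_radial_fibers <- function(mesh, field, step = 0.2, max_len = 3,
                                   n_seeds = 500L, seed = 1L) {
  if (is.null(field$vectors) || !any(!is.na(field$vectors[, 1])))
    stop("empty orientation field")
  cf <- mesh$metadata$cortical_faces
  if (is.null(cf)) cf <- seq_len(nrow(mesh$faces))
  faces <- mesh$faces[cf, , drop = FALSE]
  areas <- face_areas(mesh$nodes, faces)
  occ <- mesh_occupancy(mesh, field$grid)

  set.seed(seed)
  fi <- sample.int(nrow(faces), n_seeds, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(n_seeds))
  r2 <- runif(n_seeds)
  a <- 1 - r1
  b <- r1 * (1 - r2)
  cc <- r1 * r2
  seeds <- a * mesh$nodes[faces[fi, 1], , drop = FALSE] +
           b * mesh$nodes[faces[fi, 2], , drop = FALSE] +
           cc * mesh$nodes[faces[fi, 3], , drop = FALSE]

  n_steps <- ceiling(max_len / step)
  fibers <- vector("list", n_seeds)
  skipped <- 0L
  for (k in seq_len(n_seeds)) {
    # nudge the surface seed half a step inward so it lands in a filled voxel
    v0 <- field_at(field, seeds[k, , drop = FALSE])
    if (is.na(v0[1])) { skipped <- skipped + 1L; next }
    p <- seeds[k, ] + 0.5 * step * as.numeric(v0)
    pts <- matrix(seeds[k, ], 1, 3)
    len <- 0.5 * step
    for (s in seq_len(n_steps)) {
      id <- voxel_id(field$grid, world_to_voxel(field$grid, matrix(p, 1)))
      if (is.na(id) || !occ[id]) break
      v <- field$vectors[id, ]
      if (is.na(v[1])) break
      pts <- rbind(pts, p)
      if (len >= max_len) break
      p <- p + step * v
      len <- len + step
    }
    if (nrow(pts) >= 2L) fibers[[k]] <- pts
  }
  keep <- !vapply(fibers, is.null, logical(1))
  structure(fiber_set(fibers[keep], seeds = seeds[keep, , drop = FALSE]),
            n_skipped = n_seeds - sum(keep))
}

#' Advect fibers through the deformation map
#'
#' Maps every polyline vertex by `Phi_t`, preserving connectivity and fiber
#' order. Fibers with unlocatable vertices are flagged (and dropped when
#' `drop_unlocatable`).
#'
#' @param map a [deformation_map()].
#' @param fibers a [fiber_set()] in reference (t = 0) space.
#' @param t normalized time.
#' @param drop_unlocatable drop fibers with points outside the reference
#'   mesh instead of erroring.
#' @return a [fiber_set()] at time `t`; attribute `flagged` lists dropped
#'   fiber indices.
#' @export
advect_fibers <- function(map, fibers, t, drop_unlocatable = FALSE) {
  np <- vapply(fibers$fibers, nrow, integer(1))
  allp <- do.call(rbind, fibers$fibers)
  mapped <- map_point(map, allp, t,
                      on_outside = if (drop_unlocatable) "na" else "error")
  idx <- rep(seq_along(fibers$fibers), np)
  out <- lapply(seq_along(fibers$fibers), function(k) {
    m <- mapped[idx == k, , drop = FALSE]
    if (anyNA(m)) NULL else m
  })
  flagged <- which(vapply(out, is.null, logical(1)))
  keep <- setdiff(seq_along(out), flagged)
  res <- fiber_set(out[keep],
                   seeds = if (!is.null(fibers$seeds))
                     fibers$seeds[keep, , drop = FALSE] else NULL)
  attr(res, "flagged") <- flagged
  res
}

#' Synthesize a randomized Bezier bundle
#'
#' Connects two endpoint sets with quadratic Bezier curves: per fiber the
#' endpoints are drawn (seeded RNG) from sets A and B, the single control
#' point is their midpoint plus isotropic Gaussian jitter, and the curve is
#' sampled at a fixed vertex count. Curves interpolate both endpoints
#' exactly.
#'
#' @param endpoints_a,endpoints_b matrices of candidate endpoints (mm), in
#'   unfolded space.
#' @param n_fibers number of curves.
#' @param sigma control-point jitter standard deviation (mm) per axis.
#' @param n_points vertices per curve.
#' @param seed RNG seed.
#' @return a [fiber_set()].
#' @export
bezier_bundle <- function(endpoints_a, endpoints_b, n_fibers = 100L,
                          sigma = NULL, n_points = 32L, seed = 1L) {
  endpoints_a <- to_points(endpoints_a)
  endpoints_b <- to_points(endpoints_b)
  if (nrow(endpoints_a) == 0L || nrow(endpoints_b) == 0L)
    stop("both endpoint sets must be non-empty")
  set.seed(seed)
  ia <- sample.int(nrow(endpoints_a), n_fibers, replace = TRUE)
  ib <- sample.int(nrow(endpoints_b), n_fibers, replace = TRUE)
  u <- seq(0, 1, length.out = n_points)
  fibers <- vector("list", n_fibers)
  for (k in seq_len(n_fibers)) {
    p0 <- endpoints_a[ia[k], ]
    p2 <- endpoints_b[ib[k], ]
    s <- if (is.null(sigma)) 0.1 * sqrt(sum((p2 - p0)^2)) else sigma
    ctrl <- (p0 + p2) / 2 + rnorm(3, 0, s)
    crv <- outer((1 - u)^2, p0) + outer(2 * u * (1 - u), ctrl) +
           outer(u^2, p2)
    fibers[[k]] <- crv
  }
  fiber_set(fibers)
}

#' Extract per-voxel primary peaks from fiber segments
#'
#' Accumulates the orientation tensor `sum_i d_i d_i^T` of the unit segment
#' directions of all fiber segments crossing each voxel (segments are sampled
#' at sub-voxel spacing) and returns the principal eigenvector per voxel —
#' the standard sign-invariant estimator for axial data (a plain mean would
#' cancel antipodal segments). Voxels with an eigenvalue tie within `tie_tol`
#' are flagged ambiguous and left empty.
#'
#' @param fibers a [fiber_set()].
#' @param grid a [vox_grid()].
#' @param tie_tol relative eigenvalue tie tolerance.
#' @return an [orientation_field()] with `ambiguous` flags.
#' @export
extract_primary_peaks <- function(fibers, grid, tie_tol = 1e-6) {
  if (length(fibers$fibers) == 0L) stop("empty fiber set")
  step <- grid$spacing / 2
  ids_all <- integer(0)
  dirs_all <- NULL
  for (f in fibers$fibers) {
    seg <- f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    ok <- len > 1e-12
    if (!any(ok)) next
    seg <- seg[ok, , drop = FALSE]
    len <- len[ok]
    d <- seg / len
    start <- f[-nrow(f), , drop = FALSE][ok, , drop = FALSE]
    nsub <- pmax(1L, ceiling(len / step))
    reps <- rep(seq_along(len), nsub)
    frac <- unlist(lapply(nsub, function(n) (seq_len(n) - 0.5) / n))
    pts <- start[reps, , drop = FALSE] + d[reps, , drop = FALSE] * (frac * len[reps])
    ids <- voxel_id(grid, world_to_voxel(grid, pts))
    okv <- !is.na(ids)
    ids_all <- c(ids_all, ids[okv])
    dirs_all <- rbind(dirs_all, d[reps[okv], , drop = FALSE])
  }
  if (length(ids_all) == 0L)
    return(orientation_field(grid, matrix(NA_real_, n_voxels(grid), 3)))
  # accumulate the 6 unique orientation-tensor entries per voxel
  comp <- cbind(dirs_all[, 1]^2, dirs_all[, 2]^2, dirs_all[, 3]^2,
                dirs_all[, 1] * dirs_all[, 2],
                dirs_all[, 1] * dirs_all[, 3],
                dirs_all[, 2] * dirs_all[, 3])
  agg <- rowsum(comp, ids_all)
  vox <- as.integer(rownames(agg))
  vec <- matrix(NA_real_, n_voxels(grid), 3)
  amb <- logical(n_voxels(grid))
  for (r in seq_along(vox)) {
    Tm <- matrix(c(agg[r, 1], agg[r, 4], agg[r, 5],
                   agg[r, 4], agg[r, 2], agg[r, 6],
                   agg[r, 5], agg[r, 6], agg[r, 3]), 3, 3)
    e <- eigen(Tm, symmetric = TRUE)
    if (e$values[1] - e$values[2] <= tie_tol * max(e$values[1], 1e-300)) {
      amb[vox[r]] <- TRUE
    } else {
      vec[vox[r], ] <- e$vectors[, 1]
    }
  }
  orientation_field(grid, vec, ambiguous = amb)
}

#' Voxel strain map from paired fiber sets
#'
#' For index-paired unfolded/folded fiber sets, computes per fiber the
#' elongation ratio (folded length over unfolded length), deposits it into
#' every voxel the folded polyline crosses, and reports the per-voxel mean
#' ratio minus one: positive strain is stretching, negative is compression.
#' Voxels not crossed by any fiber are empty.
#'
#' @param fibers_unfolded,fibers_folded index-paired [fiber_set()]s (same
#'   fiber count and seeding).
#' @param grid a [vox_grid()] in folded space.
#' @return a [strain_map_grid()] object.
#' @export
strain_map <- function(fibers_unfolded, fibers_folded, grid) {
  n <- length(fibers_unfolded$fibers)
  if (n != length(fibers_folded$fibers))
    stop("fiber sets must be index-paired (equal fiber counts)")
  l0 <- fiber_lengths(fibers_unfolded)
  l1 <- fiber_lengths(fibers_folded)
  ratio <- l1 / l0
  step <- grid$spacing / 2
  ids_all <- integer(0)
  rat_all <- numeric(0)
  for (k in seq_len(n)) {
    f <- fibers_folded$fibers[[k]]
    seg <- f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    ok <- len > 1e-12
    if (!any(ok)) next
    d <- seg[ok, , drop = FALSE] / len[ok]
    start <- f[-nrow(f), , drop = FALSE][ok, , drop = FALSE]
    nsub <- pmax(1L, ceiling(len[ok] / step))
    reps <- rep(seq_along(nsub), nsub)
    frac <- unlist(lapply(nsub, function(nn) (seq_len(nn) - 0.5) / nn))
    pts <- start[reps, , drop = FALSE] +
      d[reps, , drop = FALSE] * (frac * len[ok][reps])
    ids <- unique(voxel_id(grid, world_to_voxel(grid, pts)))
    ids <- ids[!is.na(ids)]
    ids_all <- c(ids_all, ids)
    rat_all <- c(rat_all, rep(ratio[k], length(ids)))
  }
  vals <- rep(NA_real_, n_voxels(grid))
  cnts <- numeric(n_voxels(grid))
  if (length(ids_all)) {
    m <- rowsum(cbind(rat_all, 1), ids_all)
    vox <- as.integer(rownames(m))
    vals[vox] <- m[, 1] / m[, 2] - 1
    cnts[vox] <- m[, 2]
  }
  strain_map_grid(grid, vals, cnts)
}
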
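# The volumetric deformation map: displacement-normalized trajectory time,
# barycentric point location in the reference (unfolded) mesh, and the map
# p_t = sum_i lambda_i x_i(t) carrying points between configurations.

#' Normalize trajectory time by node displacement
#'
#' Recomputes the normalized times of a trajectory so that equal spans of
#' normalized time correspond to roughly equal amounts of physical
#' deformation: each interval's duration is made proportional to the mean
#' Euclidean node displacement between its two snapshots, cumulatively
#' rescaled to `[0, 1]`. Zero-displacement intervals get zero duration.
#'
#' @param trajectory a `fold_trajectory` (or any list with `snapshots`).
#' @param stat aggregator over nodes: `"mean"` (default) or `"max"`.
#' @return the trajectory with element `normalized_times` set.
#' @export
normalize_time <- function(trajectory, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  snaps <- trajectory$snapshots
  if (length(snaps) < 2L) stop("need at least 2 snapshots to normalize time")
  d <- vapply(seq_len(length(snaps) - 1L), function(k) {
    disp <- sqrt(rowSums((snaps[[k + 1L]] - snaps[[k]])^2))
    if (stat == "mean") mean(disp) else max(disp)
  }, numeric(1))
  tot <- sum(d)
  if (tot == 0) stop("no deformation to normalize (all snapshots identical)")
  trajectory$normalized_times <- c(0, cumsum(d)) / tot
  trajectory
}

#' Build the deformation map of a folding trajectory
#'
#' Realizes the map `Phi_t(p) = sum_i lambda_i x_i(t)` where `lambda_i` are
#' the barycentric coordinates of `p` in the reference configuration `t = 0`
#' (the unfolded state) and `x_i(t)` are linearly interpolated node positions
#' at displacement-normalized time `t`; `t = 1` is the folded configuration.
#' An unfold trajectory (folded to unfolded) is reversed automatically so the
#' reference is always the unfolded state.
#'
#' @param trajectory a `fold_trajectory` from [run_simulation()].
#' @return object of class `deformation_map`.
#' @export
deformation_map <- function(trajectory) {
  snaps <- trajectory$snapshots
  if (identical(trajectory$direction, "unfold")) snaps <- rev(snaps)
  tr <- list(snapshots = snaps)
  tr <- normalize_time(tr)
  structure(list(mesh = trajectory$mesh,
                 reference = snaps[[1L]],
                 snapshots = snaps,
                 times = tr$normalized_times),
            class = "deformation_map")
}

#' @export
print.deformation_map <- function(x, ...) {
  cat(sprintf("<deformation_map> %d snapshots, t in [0, 1], %d reference tets\n",
              length(x$snapshots), nrow(x$mesh$tets)))
  invisible(x)
}

#' Locate points in the reference configuration
#'
#' Finds, for each query point, the reference tetrahedron containing it and
#' the barycentric coordinates, via a uniform-grid spatial index. Points
#' within `eps` (barycentric units) of a face are snapped onto it; points
#' farther outside get `NA`.
#'
#' @param map a [deformation_map()] (or a [tet_mesh()]).
#' @param points N x 3 matrix (a single point may be given as a length-3
#'   vector).
#' @param eps barycentric tolerance for boundary points.
#' @return list with `tet` (1-based indices, `NA` when outside) and `bary`
#'   (N x 4, rows sum to 1).
#' @export
locate_point <- function(map, points, eps = 1e-6) {
  if (inherits(map, "deformation_map")) {
    nodes <- map$reference
    tets <- map$mesh$tets
  } else {
    nodes <- map$nodes
    tets <- map$tets
  }
  points <- to_points(points)
  cpp_locate_points(nodes, tets - 1L, points, eps)
}

to_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  as.matrix(p)
}

# Interpolated node positions at normalized time t.
positions_at <- function(map, t) {
  stopifnot(t >= 0, t <= 1)
  tm <- map$times
  k <- findInterval(t, tm, rightmost.closed = TRUE)
  k <- min(max(k, 1L), length(tm) - 1L)
  t0 <- tm[k]; t1 <- tm[k + 1L]
  a <- if (t1 > t0) (t - t0) / (t1 - t0) else 0
  (1 - a) * map$snapshots[[k]] + a * map$snapshots[[k + 1L]]
}

#' Map points through the deformation
#'
#' Applies `Phi_t` to points located in the reference (t = 0) configuration:
#' the identity at `t = 0`, the folded configuration at `t = 1`, with linear
#' interpolation between bracketing snapshots in normalized time.
#'
#' @param map a [deformation_map()].
#' @param points N x 3 matrix of reference-space points.
#' @param t normalized time in `[0, 1]`.
#' @param on_outside `"error"` (default) or `"na"` for points outside the
#'   reference mesh.
#' @return N x 3 matrix of mapped points.
#' @export
map_point <- function(map, points, t, on_outside = c("error", "na")) {
  on_outside <- match.arg(on_outside)
  points <- to_points(points)
  loc <- locate_point(map, points)
  bad <- is.na(loc$tet)
  if (any(bad) && on_outside == "error")
    stop(sum(bad), " point(s) outside the reference mesh")
  xt <- positions_at(map, t)
  out <- matrix(NA_real_, nrow(points), 3)
  ok <- which(!bad)
  if (length(ok)) {
    tv <- map$mesh$tets[loc$tet[ok], , drop = FALSE]
    b <- loc$bary[ok, , drop = FALSE]
    out[ok, ] <- b[, 1] * xt[tv[, 1], , drop = FALSE] +
                 b[, 2] * xt[tv[, 2], , drop = FALSE] +
                 b[, 3] * xt[tv[, 3], , drop = FALSE] +
                 b[, 4] * xt[tv[, 4], , drop = FALSE]
  }
  out
}
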
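# Synthetic two-tissue geometries with known folding structure: a sinusoidal
# folded slab (2.5-D folds: sinusoid in x, extruded in y, so the ground-truth
# radial orientation field is analytic), a unit white-matter cube, and a wavy
# sphere. All are structured hexahedral lattices split into 6 tets per cell
# (Kuhn subdivision), giving reproducible, bit-identical connectivity.

# Kuhn 6-tet subdivision of the unit cell, orientation-corrected: each
# permutation pi of the axes yields tet (0, e_p1, e_p1+e_p2, (1,1,1)); odd
# permutations get two vertices swapped so all signed volumes are positive.
kuhn_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  parity <- c(1, -1, -1, 1, 1, -1)
  lapply(seq_along(perms), function(k) {
    p <- perms[[k]]
    v0 <- c(0, 0, 0)
    v1 <- v0; v1[p[1]] <- 1
    v2 <- v1; v2[p[2]] <- 1
    v3 <- c(1, 1, 1)
    out <- rbind(v0, v1, v2, v3)
    if (parity[k] < 0) out <- out[c(1, 3, 2, 4), ]
    out
  })
}

# Remove inverted sliver tets produced by mapping a lattice through a curved
# (but orientation-preserving) transform: nodes of inverted tets are blended
# toward the centroid of their edge-connected neighbours until all signed
# volumes are positive. Deterministic, local, and a no-op on clean meshes.
untangle_slivers <- function(nodes, tets, max_iters = 50L) {
  vol <- function(x) {
    e1 <- x[tets[, 2], ] - x[tets[, 1], ]
    e2 <- x[tets[, 3], ] - x[tets[, 1], ]
    e3 <- x[tets[, 4], ] - x[tets[, 1], ]
    (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
     e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
     e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
  }
  for (it in seq_len(max_iters)) {
    bad <- which(vol(nodes) <= 0)
    if (length(bad) == 0L) return(nodes)
    move <- sort(unique(as.vector(tets[bad, , drop = FALSE])))
    inc <- tets[rowSums(matrix(tets %in% move, nrow(tets), 4)) > 0, ,
                drop = FALSE]
    for (i in move) {
      nb <- setdiff(unique(as.vector(inc[rowSums(inc == i) > 0, ])), i)
      nodes[i, ] <- 0.5 * nodes[i, ] + 0.5 * colMeans(nodes[nb, , drop = FALSE])
    }
  }
  warning("sliver untangling did not converge")
  nodes
}

# Tets of an nx x ny x nz node lattice (1-based linear indices).
lattice_tets <- function(nx, ny, nz) {
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  blocks <- lapply(kuhn_tets(), function(tt) {
    cols <- lapply(1:4, function(v)
      nid(ci + tt[v, 1], cj + tt[v, 2], ck + tt[v, 3]))
    do.call(cbind, cols)
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  out
}

#' Specification of a synthetic folded slab
#'
#' The slab occupies `[0, extent_x] x [0, extent_y]` with a flat bottom at
#' z = 0 and a folded top surface `z = depth + A * sin(2*pi*x / W)`.
#' Nodes above `local_top - gm_thickness` are gray matter, the rest white.
#'
#' @param extent_x,extent_y,depth slab dimensions (mm).
#' @param fold_amplitude sinusoid amplitude A (mm), `0 <= A < depth`.
#' @param fold_wavelength sinusoid wavelength W (mm), > 0.
#' @param gm_thickness gray-matter shell thickness (mm), in (0, depth).
#' @param element_size target lattice spacing h (mm), `0 < h < gm_thickness`.
#' @return object of class `slab_spec`.
#' @export
slab_spec <- function(extent_x = 16, extent_y = 4, depth = 6,
                      fold_amplitude = 2, fold_wavelength = 8,
                      gm_thickness = 1.5, element_size = 0.5) {
  s <- list(extent_x = extent_x, extent_y = extent_y, depth = depth,
            A = fold_amplitude, W = fold_wavelength,
            gm_thickness = gm_thickness, h = element_size)
  stopifnot(s$A >= 0, s$W > 0, s$gm_thickness < s$depth, s$h > 0)
  if (s$h >= s$gm_thickness)
    stop("element_size must be smaller than gm_thickness")
  if (s$A >= s$depth)
    stop("geometry error: fold amplitude must be smaller than slab depth")
  structure(s, class = "slab_spec")
}

# Height of the slab's top surface above x.
slab_top <- function(spec, x) spec$depth + spec$A * sin(2 * pi * x / spec$W)

#' Generate a folded two-tissue slab mesh
#'
#' Deterministic structured mesh of a sinusoidally folded slab: identical
#' specs give bit-identical node arrays. Cortical (top) faces are recorded in
#' the metadata, together with symmetry boundary conditions (side-wall nodes
#' pinned along their outward axis, bottom nodes pinned in z) used by the
#' unfolding simulation.
#'
#' @param spec a [slab_spec()].
#' @return a [tet_mesh()] with metadata `kind = "slab"`, `envelope = "slab"`,
#'   `cortical_faces`, `freemask`, and the generating `spec`.
#' @export
make_folded_slab <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  nx <- max(2L, as.integer(round(spec$extent_x / spec$h)) + 1L)
  ny <- max(2L, as.integer(round(spec$extent_y / spec$h)) + 1L)
  nz <- max(2L, as.integer(round(spec$depth / spec$h)) + 1L)
  xs <- seq(0, spec$extent_x, length.out = nx)
  ys <- seq(0, spec$extent_y, length.out = ny)
  us <- seq(0, 1, length.out = nz)
  gx <- rep(xs, times = ny * nz)
  gy <- rep(rep(ys, each = nx), times = nz)
  gu <- rep(us, each = nx * ny)
  top <- slab_top(spec, gx)
  nodes <- cbind(gx, gy, gu * top, deparse.level = 0)
  tissue <- ifelse(nodes[, 3] > top - spec$gm_thickness, "gray", "white")
  tets <- lattice_tets(nx, ny, nz)

  freemask <- matrix(1, nrow(nodes), 3)
  tol <- 1e-9
  freemask[abs(gx) < tol | abs(gx - spec$extent_x) < tol, 1] <- 0
  freemask[abs(gy) < tol | abs(gy - spec$extent_y) < tol, 2] <- 0
  freemask[gu < tol, 3] <- 0

  mesh <- tet_mesh(nodes, tets, tissue,
                   metadata = list(kind = "slab", envelope = "slab",
                                   spec = unclass(spec), freemask = freemask))
  nz_comp <- face_normals(mesh$nodes, mesh$faces)[, 3]
  mesh$metadata$cortical_faces <- which(nz_comp > 1e-8)
  mesh
}

#' Generate a white-matter cube mesh
#'
#' Structured tet mesh of an axis-aligned cube `[0, edge]^3`, all nodes
#' labeled white matter; the Kuhn subdivision tiles the cube exactly, so the
#' summed tet volume equals `edge^3` to round-off.
#'
#' @param edge cube edge length (mm); the canonical viscoelasticity test body
#'   is the 1 mm^3 cube.
#' @param h target lattice spacing (mm), `h < edge`.
#' @return a [tet_mesh()] with metadata `kind = "cube"`.
#' @export
make_unit_cube <- function(edge = 1, h = 0.25) {
  stopifnot(h > 0, h < edge)
  n <- max(2L, as.integer(round(edge / h)) + 1L)
  s <- seq(0, edge, length.out = n)
  nodes <- cbind(rep(s, times = n * n),
                 rep(rep(s, each = n), times = n),
                 rep(s, each = n * n))
  mesh <- tet_mesh(nodes, lattice_tets(n, n, n),
                   rep("white", nrow(nodes)),
                   metadata = list(kind = "cube", envelope = "hull",
                                   edge = edge, h = h))
  mesh$metadata$cortical_faces <- seq_len(nrow(mesh$faces))
  mesh$metadata$freemask <- matrix(1, nrow(nodes), 3)
  mesh
}

#' Generate a wavy (lobed) sphere mesh
#'
#' Ball mesh whose surface is `r(theta, phi) = radius + amplitude *
#' f(theta, phi)` with the smooth lobed perturbation
#' `f = sin(theta)^n_lobes * cos(n_lobes * phi)` (a sectoral
#' spherical-harmonic-like basis, recorded in the metadata); `amplitude = 0`
#' or `n_lobes = 0` gives a sphere within meshing tolerance. Built by mapping
#' a cube lattice radially onto the lobed ball.
#'
#' @param radius base radius (mm).
#' @param n_lobes number of azimuthal lobes (0 for a plain sphere).
#' @param amplitude lobe amplitude (mm), `< radius`.
#' @param h target lattice spacing (mm).
#' @return a [tet_mesh()] with metadata `kind = "wavy_sphere"`.
#' @export
make_wavy_sphere <- function(radius = 1, n_lobes = 3, amplitude = 0.15,
                             h = 0.2) {
  stopifnot(radius > 0, h > 0, amplitude >= 0)
  if (amplitude >= radius) stop("amplitude must be smaller than radius")
  n <- max(5L, 2L * as.integer(ceiling(radius / h)) + 1L)
  s <- seq(-1, 1, length.out = n)
  p <- cbind(rep(s, times = n * n),
             rep(rep(s, each = n), times = n),
             rep(s, each = n * n))
  # smooth cube-to-ball map (orientation-preserving, no creases)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  q <- cbind(x * sqrt(pmax(1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3, 0)),
             y * sqrt(pmax(1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3, 0)),
             z * sqrt(pmax(1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3, 0)))
  r2 <- sqrt(rowSums(q^2))
  dir <- q / pmax(r2, .Machine$double.xmin)
  dir[r2 == 0, ] <- 0
  theta <- acos(pmin(pmax(dir[, 3], -1), 1))
  phi <- atan2(dir[, 2], dir[, 1])
  f <- if (n_lobes == 0L || amplitude == 0) 0 else
    sin(theta)^n_lobes * cos(n_lobes * phi)
  # radial scaling, perturbation tapered ~ r^2 so it vanishes smoothly at the
  # center (where the direction field is discontinuous) and is exact on the
  # surface (r = 1)
  nodes <- q * (radius + amplitude * f * r2^2)
  nodes <- untangle_slivers(nodes, lattice_tets(n, n, n))
  mesh <- tet_mesh(nodes, lattice_tets(n, n, n),
                   rep("white", nrow(nodes)),
                   metadata = list(kind = "wavy_sphere", envelope = "hull",
                                   radius = radius, n_lobes = n_lobes,
                                   amplitude = amplitude, h = h,
                                   basis = "sin(theta)^n * cos(n*phi)"))
  mesh$metadata$cortical_faces <- seq_len(nrow(mesh$faces))
  mesh$metadata$freemask <- matrix(1, nrow(mesh$nodes), 3)
  mesh
}

#' Analytic radial orientation field of a folded slab
#'
#' Ground truth for orientation evaluation: the inward unit normal of the
#' folded top surface propagated along straight normal lines into the slab.
#' At a query point p the foot point on the surface curve
#' `(x, depth + A sin(2 pi x / W))` is found (dense scan plus Newton
#' refinement of the squared distance in the x-z plane; folds are extruded in
#' y), and the direction is the inward normal there.
#'
#' @param spec a [slab_spec()].
#' @return object of class `analytic_field` with elements `direction`
#'   (function mapping an N x 3 matrix of points to N x 3 unit vectors) and
#'   `domain` (the slab bounding box).
#' @export
analytic_slab_orientation <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  g <- function(s) spec$depth + spec$A * sin(2 * pi * s / spec$W)
  gp <- function(s) spec$A * (2 * pi / spec$W) * cos(2 * pi * s / spec$W)
  gpp <- function(s) -spec$A * (2 * pi / spec$W)^2 * sin(2 * pi * s / spec$W)
  direction <- function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    x <- points[, 1]; z <- points[, 3]
    if (spec$A == 0) {
      out <- cbind(0, 0, -1)[rep(1, length(x)), , drop = FALSE]
      return(out)
    }
    # Foot point of the straight normal line through p: solve
    # (x - s) + (z - g(s)) g'(s) = 0 by damped Newton, starting from the
    # vertical projection s = x. Starting at the query's own abscissa picks
    # the symmetric (crest/fundus) branch beyond focal caustics, which is
    # the natural continuation of "propagated along straight normal lines".
    s <- x
    for (it in 1:40) {
      fval <- (x - s) + (z - g(s)) * gp(s)
      fder <- -1 - gp(s)^2 + (z - g(s)) * gpp(s)
      step <- fval / (sign(fder) * pmax(abs(fder), 1e-9))
      step <- pmin(pmax(step, -spec$W / 16), spec$W / 16)
      s <- s - step
    }
    nrm <- sqrt(1 + gp(s)^2)
    cbind(gp(s) / nrm, 0, -1 / nrm)
  }
  structure(list(direction = direction,
                 domain = rbind(c(0, 0, 0),
                                c(spec$extent_x, spec$extent_y,
                                  spec$depth + spec$A))),
            class = "analytic_field")
}
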
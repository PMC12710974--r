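# Tetrahedral mesh data model. Nodes are an N x 3 matrix (mm), tets an M x 4
# integer matrix of 1-based node indices with positive signed volume, and the
# boundary surface is extracted as consistently outward-oriented triangles.

#' Construct a tetrahedral mesh
#'
#' Builds the two-tissue volumetric mesh container used throughout the
#' package. Surface faces are derived from the tetrahedra (faces belonging to
#' exactly one tet), oriented outward.
#'
#' @param nodes numeric N x 3 matrix of node positions (mm).
#' @param tets integer M x 4 matrix of 1-based node indices; every tet must
#'   have positive signed volume.
#' @param tissue character or factor of length N with values `"white"` or
#'   `"gray"` (per-node tissue designation).
#' @param parcel optional integer vector of length N of parcellation labels.
#' @param node_mass optional numeric vector of length N of lumped masses (kg);
#'   usually filled in by [compute_node_masses()].
#' @param metadata named list of generator metadata (envelope type, cortical
#'   face subset, boundary-condition node sets, ...).
#' @return An object of class `tetmesh` with elements `nodes`, `tets`,
#'   `faces` (outward surface triangles), `tissue`, `parcel`, `node_mass`,
#'   `metadata`.
#' @export
tet_mesh <- function(nodes, tets, tissue, parcel = NULL, node_mass = NULL,
                     metadata = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4)
  n <- nrow(nodes)
  if (nrow(tets) == 0L) stop("no tetrahedra")
  if (min(tets) < 1L || max(tets) > n) stop("tet node index out of range")
  tissue <- as.character(tissue)
  if (length(tissue) != n) stop("tissue must be defined for all nodes")
  if (!all(tissue %in% c("white", "gray")))
    stop("tissue labels must be 'white' or 'gray'")
  m <- structure(list(nodes = nodes, tets = tets,
                      faces = surface_faces(tets),
                      tissue = tissue, parcel = parcel,
                      node_mass = node_mass, metadata = metadata),
                 class = "tetmesh")
  m
}

#' @export
print.tetmesh <- function(x, ...) {
  cat(sprintf("<tetmesh> %d nodes, %d tets, %d surface faces\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$faces)))
  tab <- table(x$tissue)
  cat("  tissue:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$metadata$kind)) cat("  kind:", x$metadata$kind, "\n")
  invisible(x)
}

# Outward-oriented boundary faces of a tet array. For a positively oriented
# tet (a,b,c,d) the outward faces are (a,c,b), (b,c,d), (a,d,c), (a,b,d).
surface_faces <- function(tets) {
  a <- tets[, 1]; b <- tets[, 2]; c <- tets[, 3]; d <- tets[, 4]
  f <- rbind(cbind(a, c, b), cbind(b, c, d), cbind(a, d, c), cbind(a, b, d))
  key <- apply(f, 1L, function(r) paste(sort.int(r), collapse = "_"))
  once <- names(which(table(key) == 1L))
  out <- f[key %in% once, , drop = FALSE]
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh a [tet_mesh()] object.
#' @param positions optional alternative N x 3 node positions (same
#'   connectivity), e.g. a trajectory snapshot.
#' @return numeric vector of signed volumes (mm^3), positive for correctly
#'   oriented tets.
#' @export
tet_volumes <- function(mesh, positions = NULL) {
  x <- if (is.null(positions)) mesh$nodes else positions
  t <- mesh$tets
  e1 <- x[t[, 2], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  e2 <- x[t[, 3], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  e3 <- x[t[, 4], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Areas of triangles at the given positions
#' @param positions node coordinate matrix.
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @return numeric vector of areas (mm^2).
#' @export
face_areas <- function(positions, faces) {
  u <- positions[faces[, 2], , drop = FALSE] - positions[faces[, 1], , drop = FALSE]
  v <- positions[faces[, 3], , drop = FALSE] - positions[faces[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Unit outward normals of faces at the given positions
#' @inheritParams face_areas
#' @return M x 3 matrix of unit normals.
#' @export
face_normals <- function(positions, faces) {
  u <- positions[faces[, 2], , drop = FALSE] - positions[faces[, 1], , drop = FALSE]
  v <- positions[faces[, 3], , drop = FALSE] - positions[faces[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Validate a tetrahedral mesh
#'
#' Report-only check of the mesh invariants: positive tet volumes, a closed
#' 2-manifold boundary surface (every surface edge shared by exactly two
#' surface faces), and absence of isolated nodes.
#'
#' @param mesh a [tet_mesh()] object.
#' @return A list of class `tetmesh_report` with `min_volume`,
#'   `n_inverted`, `n_nonmanifold_edges`, `n_isolated_nodes`, `ok`.
#' @export
validate_mesh <- function(mesh) {
  if (is.null(mesh$tets) || nrow(mesh$tets) == 0L) stop("no tetrahedra")
  vols <- tet_volumes(mesh)
  f <- mesh$faces
  ek <- c(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
          paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
          paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1])))
  ecount <- table(ek)
  iso <- sum(!seq_len(nrow(mesh$nodes)) %in% unique(as.vector(mesh$tets)))
  rep <- list(min_volume = min(vols),
              n_inverted = sum(vols <= 0),
              n_nonmanifold_edges = sum(ecount != 2L),
              n_isolated_nodes = iso)
  rep$ok <- rep$n_inverted == 0L && rep$n_nonmanifold_edges == 0L &&
    iso == 0L && all(is.finite(mesh$nodes))
  class(rep) <- "tetmesh_report"
  rep
}

#' @export
print.tetmesh_report <- function(x, ...) {
  cat(sprintf(paste0("mesh report: min volume %.3g mm^3, %d inverted tets, ",
                     "%d non-manifold edges, %d isolated nodes -> %s\n"),
              x$min_volume, x$n_inverted, x$n_nonmanifold_edges,
              x$n_isolated_nodes, if (x$ok) "OK" else "FAIL"))
  invisible(x)
}

#' Lump tissue mass onto mesh nodes
#'
#' Distributes `density * volume` of every tetrahedron equally over its four
#' nodes. Volumes are in mm^3, so masses are `density * V * 1e-9` kg.
#'
#' @param mesh a [tet_mesh()] object.
#' @param density tissue density in kg/m^3 (brain tissue is about 1040).
#' @return The mesh with `node_mass` filled in (kg).
#' @export
compute_node_masses <- function(mesh, density = 1040) {
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  vols <- tet_volumes(mesh)
  if (any(vols <= 0)) stop("mesh has non-positive tet volumes")
  share <- density * vols * 1e-9 / 4   # mm^3 -> m^3
  mass <- numeric(nrow(mesh$nodes))
  for (k in 1:4) {
    acc <- rowsum(share, mesh$tets[, k])
    idx <- as.integer(rownames(acc))
    mass[idx] <- mass[idx] + acc[, 1]
  }
  mesh$node_mass <- mass
  mesh
}

#' Gyrification index of a mesh surface
#'
#' Ratio of the actual outer-surface area to the area of a smooth reference
#' envelope. For closed surfaces the envelope is the convex hull of the
#' surface nodes; for slab-like meshes (generator metadata
#' `envelope = "slab"`) it is the flat projection of the cortical (top)
#' faces onto the xy-plane, computed as `sum(A_f * |n_z|)`, which remains
#' valid while the slab deforms. A smooth sphere or a flat slab has GI 1.
#'
#' @param mesh a [tet_mesh()] object.
#' @param positions optional alternative node positions (e.g. a snapshot).
#' @return single numeric, >= 1 up to meshing tolerance. The envelope type
#'   used is attached as attribute `"envelope"`.
#' @export
gyrification_index <- function(mesh, positions = NULL) {
  x <- if (is.null(positions)) mesh$nodes else positions
  env <- mesh$metadata$envelope
  if (is.null(env)) env <- "hull"
  if (identical(env, "slab")) {
    cf <- mesh$metadata$cortical_faces
    if (is.null(cf)) stop("slab mesh without recorded cortical faces")
    f <- mesh$faces[cf, , drop = FALSE]
    a <- face_areas(x, f)
    nz <- abs(face_normals(x, f)[, 3])
    gi <- sum(a) / sum(a * nz)
  } else {
    sn <- sort(unique(as.vector(mesh$faces)))
    hull <- cpp_convex_hull(x[sn, , drop = FALSE])
    gi <- sum(face_areas(x, mesh$faces)) / hull$area
  }
  structure(gi, envelope = env)
}

#' Total mesh volume (mm^3)
#' @param mesh a [tet_mesh()]; @param positions optional snapshot positions.
#' @return single numeric.
#' @export
total_volume <- function(mesh, positions = NULL) sum(tet_volumes(mesh, positions))

#' Total boundary surface area (mm^2)
#' @inheritParams total_volume
#' @return single numeric.
#' @export
total_surface_area <- function(mesh, positions = NULL) {
  x <- if (is.null(positions)) mesh$nodes else positions
  sum(face_areas(x, mesh$faces))
}
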
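# Standard-format I/O: surface meshes (OFF, PLY, GIFTI, FreeSurfer binary),
# VTK unstructured grids, NIfTI volumes (via RNifti), TCK/TRK streamline
# files, and JSON run manifests. Coordinates are mm; all on-disk indices are
# the formats' native 0-based convention, mapped to 1-based in R.

#' Read a triangulated surface mesh
#'
#' Supports OFF, PLY (ASCII), GIFTI (pointset + triangle arrays; ASCII,
#' Base64Binary or GZipBase64Binary encodings) and FreeSurfer binary surfaces.
#' Face orientation is made consistent across the mesh (faces flipped as
#' needed are counted in attribute `n_reoriented`).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"off"`, `"ply"`, `"gifti"`,
#'   `"freesurfer"`; `"auto"` guesses from the extension and magic bytes.
#' @return list with `vertices` (N x 3, mm) and `faces` (M x 3, 1-based),
#'   attribute `n_reoriented`.
#' @export
read_surface <- function(path, format = c("auto", "off", "ply", "gifti",
                                          "freesurfer")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_surface_format(path)
  surf <- switch(format,
                 off = read_off(path),
                 ply = read_ply(path),
                 gifti = read_gifti_surface(path),
                 freesurfer = read_fs_surface(path))
  orient_faces_consistently(surf)
}

guess_surface_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("off")) return("off")
  if (ext %in% c("ply")) return("ply")
  if (ext %in% c("gii")) return("gifti")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (length(magic) >= 3 && all(magic[1:3] == as.raw(c(255, 255, 254))))
    return("freesurfer")
  txt <- rawToChar(magic[magic != as.raw(0)])
  if (startsWith(txt, "OFF")) return("off")
  if (startsWith(txt, "ply")) return("ply")
  if (startsWith(txt, "<?xml") || startsWith(txt, "<GIFTI")) return("gifti")
  stop("cannot determine surface format of ", path)
}

parse_error <- function(path, what, offset = NA) {
  stop(sprintf("parse error in %s: %s%s", path, what,
               if (is.na(offset)) "" else sprintf(" (near byte %d)", offset)))
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!startsWith(trimws(lines[1]), "OFF")) parse_error(path, "missing OFF magic", 0)
  header <- lines[1]
  body <- if (nchar(trimws(sub("OFF", "", header))) > 0)
    c(sub("OFF", "", header), lines[-1]) else lines[-1]
  counts <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (is.na(nv) || is.na(nf)) parse_error(path, "bad count line")
  if (length(body) < 1 + nv + nf) parse_error(path, "truncated file")
  vt <- do.call(rbind, lapply(body[2:(1 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(body[(2 + nv):(1 + nv + nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) parse_error(path, "non-triangular face")
    x[2:4]
  }))
  list(vertices = vt, faces = fc + 1L)
}

#' Write a surface as ASCII OFF
#' @param vertices N x 3 matrix; @param faces M x 3 1-based triangles.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_off <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(vertices), nrow(faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) parse_error(path, "truncated header")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  if (hdr[1] != "ply") parse_error(path, "missing ply magic", 0)
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) parse_error(path, "missing vertex/face elements")
  body <- readLines(con)
  if (length(body) < nv + nf) parse_error(path, "truncated body")
  vt <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) parse_error(path, "non-triangular face")
    x[2:4]
  }))
  list(vertices = vt, faces = fc + 1L)
}

#' Write a surface as ASCII PLY
#' @inheritParams write_off
#' @return the path, invisibly.
#' @export
write_ply <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}

read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  verts <- NULL; faces <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    dtype <- xml2::xml_attr(a, "DataType")
    enc <- xml2::xml_attr(a, "Encoding")
    n <- as.integer(xml2::xml_attr(a, "Dim0"))
    datatxt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    vals <- decode_gifti_data(datatxt, enc, dtype, n * 3L, path)
    m <- matrix(vals, ncol = 3, byrow =
                  identical(xml2::xml_attr(a, "ArrayIndexingOrder"),
                            "RowMajorOrder") ||
                  is.na(xml2::xml_attr(a, "ArrayIndexingOrder")))
    if (identical(intent, "NIFTI_INTENT_POINTSET")) verts <- m
    if (identical(intent, "NIFTI_INTENT_TRIANGLE")) faces <- m + 1L
  }
  if (is.null(verts) || is.null(faces))
    parse_error(path, "missing pointset or triangle DataArray")
  list(vertices = verts, faces = faces)
}

decode_gifti_data <- function(txt, enc, dtype, n, path) {
  readvals <- function(raw) {
    what <- if (grepl("FLOAT", dtype)) "numeric" else "integer"
    size <- if (grepl("FLOAT64", dtype)) 8L else 4L
    readBin(raw, what, n = n, size = size, endian = "little")
  }
  switch(enc,
         ASCII = as.numeric(strsplit(trimws(txt), "\\s+")[[1]]),
         Base64Binary = readvals(jsonlite::base64_dec(txt)),
         GZipBase64Binary = readvals(memDecompress(jsonlite::base64_dec(txt),
                                                   type = "gzip")),
         parse_error(path, paste("unsupported GIFTI encoding", enc)))
}

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!all(magic == as.raw(c(255, 255, 254))))
    parse_error(path, "not a FreeSurfer triangle surface", 0)
  # comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) parse_error(path, "truncated comment")
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  vt <- readBin(con, "numeric", nv * 3, size = 4, endian = "big")
  fc <- readBin(con, "integer", nf * 3, size = 4, endian = "big")
  if (length(vt) < nv * 3 || length(fc) < nf * 3)
    parse_error(path, "truncated data")
  list(vertices = matrix(vt, ncol = 3, byrow = TRUE),
       faces = matrix(fc, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a FreeSurfer binary triangle surface
#' @inheritParams write_off
#' @return the path, invisibly.
#' @export
write_fs_surface <- function(vertices, faces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 254)), con)
  writeBin(charToRaw("created by cortexfold\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(faces - 1L)), con, size = 4, endian = "big")
  invisible(path)
}

# Make face windings consistent by flood fill over shared edges; returns the
# surface with attribute n_reoriented.
orient_faces_consistently <- function(surf) {
  f <- surf$faces
  nf <- nrow(f)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(f[, 1], f[, 2], seq_len(nf)),
                 cbind(f[, 2], f[, 3], seq_len(nf)),
                 cbind(f[, 3], f[, 1], seq_len(nf)))
  adj <- split(edges[, 3], ek(edges[, 1], edges[, 2]))
  nbr <- vector("list", nf)
  for (g in adj) if (length(g) == 2L) {
    nbr[[g[1]]] <- c(nbr[[g[1]]], g[2])
    nbr[[g[2]]] <- c(nbr[[g[2]]], g[1])
  }
  directed <- function(face) paste(c(face[1], face[2], face[3]),
                                   c(face[2], face[3], face[1]))
  seen <- logical(nf)
  flipped <- 0L
  for (root in seq_len(nf)) {
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      de <- directed(f[cur, ])
      for (nb in nbr[[cur]]) {
        if (seen[nb]) next
        seen[nb] <- TRUE
        # consistent orientation: shared edge traversed in opposite directions
        if (any(directed(f[nb, ]) %in% de)) {
          f[nb, ] <- f[nb, c(1, 3, 2)]
          flipped <- flipped + 1L
        }
        queue <- c(queue, nb)
      }
    }
  }
  surf$faces <- f
  attr(surf, "n_reoriented") <- flipped
  surf
}

#' Write a tetrahedral mesh (or snapshot) as legacy VTK unstructured grid
#'
#' ASCII legacy VTK with tissue labels as point data, readable by ParaView
#' and meshio.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @param positions optional alternative node positions.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, path, positions = NULL) {
  x <- if (is.null(positions)) mesh$nodes else positions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cortexfold tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(x))), con)
  writeLines(sprintf("%.17g %.17g %.17g", x[, 1], x[, 2], x[, 3]), con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(sprintf("POINT_DATA %d", nrow(x)), con)
  writeLines("SCALARS tissue int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(as.character(as.integer(mesh$tissue == "gray")), con)
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid as a tetrahedral mesh
#' @param path VTK file written by [write_vtk()] (or compatible).
#' @return a [tet_mesh()].
#' @export
read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- as.numeric(unlist(strsplit(trimws(lines[(ip + 1):(ip + np)]), "\\s+")))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- do.call(rbind, lapply(lines[(ic + 1):(ic + nc)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])[2:5]))
  tissue <- rep("white", np)
  it <- grep("^LOOKUP_TABLE", lines)
  if (length(it)) {
    lab <- as.integer(lines[(it[1] + 1):(it[1] + np)])
    tissue <- ifelse(lab == 1L, "gray", "white")
  }
  tet_mesh(nodes, cells + 1L, tissue)
}

#' Write a gridded volume as NIfTI-1
#'
#' Scalar volumes are written as 3-D images, vector fields as 4-D with the
#' last dimension of size 3. The affine maps 0-based voxel indices to mm
#' (voxel-center convention): `diag(spacing)` plus the grid origin.
#'
#' @param data numeric vector over voxels (scalar) or `n_voxels x 3` matrix.
#' @param grid a [vox_grid()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  dm <- grid$dim
  if (is.matrix(data) && ncol(data) == 3) {
    arr <- array(as.numeric(data), dim = c(dm, 3))
  } else {
    arr <- array(as.numeric(data), dim = dm)
  }
  aff <- diag(c(rep(grid$spacing, 3), 1))
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#' @param path NIfTI file.
#' @return list with `data` (array), `grid` (a [vox_grid()] reconstructed
#'   from the affine).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- aff[1, 1]
  origin <- aff[1:3, 4]
  dm <- dim(img)[1:3]
  list(data = as.array(img), grid = vox_grid(origin, spacing, dm))
}

#' Write streamlines as TCK or TRK
#'
#' TCK (MRtrix) stores Float32LE triplets with NaN streamline separators and
#' an Inf terminator; TRK (TrackVis, version 2) carries the supplied affine
#' in `vox_to_ras`. Points are written in the same world frame as the meshes
#' (mm).
#'
#' @param fibers a [fiber_set()].
#' @param path output path.
#' @param format `"tck"` or `"trk"` (default from the extension).
#' @param affine 4 x 4 voxel-to-world matrix stored in TRK headers.
#' @return the path, invisibly.
#' @export
write_fibers <- function(fibers, path, format = NULL, affine = diag(4)) {
  if (length(fibers$fibers) == 0L) stop("refusing to write an empty fiber set")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("tck", "trk"))
  if (format == "tck") write_tck(fibers, path) else
    write_trk(fibers, path, affine)
}

write_tck <- function(fibers, path) {
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(fibers$fibers)))
  # compute data offset: header text + "file: . <offset>\nEND\n"
  base <- sum(nchar(hdr)) + length(hdr)   # + newlines
  guess <- base + nchar("file: . ") + 1 + nchar("END") + 1 + 6
  off <- guess
  repeat {
    txt <- c(hdr, sprintf("file: . %d", off), "END")
    need <- sum(nchar(txt)) + length(txt)
    if (need <= off) break
    off <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(txt, collapse = "\n"), "\n")), con)
  pad <- off - (sum(nchar(txt)) + length(txt))
  if (pad > 0) writeBin(raw(pad), con)
  for (f in fibers$fibers) {
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK or TRK streamline file
#' @param path streamline file.
#' @return a [fiber_set()]; TRK affine attached as attribute `affine`.
#' @export
read_fibers <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 6)
  close(con)
  if (rawToChar(magic) == "mrtrix") read_tck(path) else read_trk(path)
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, 1)
  if (first != "mrtrix tracks") parse_error(path, "missing TCK magic", 0)
  off <- NA
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) parse_error(path, "truncated TCK header")
    if (ln == "END") break
    if (startsWith(ln, "file:"))
      off <- as.integer(trimws(sub(".*\\.", "", ln)))
  }
  if (is.na(off)) parse_error(path, "TCK header missing file offset")
  con2 <- file(path, "rb")
  on.exit(close(con2), add = TRUE)
  seek(con2, off)
  vals <- readBin(con2, "numeric", file.size(path), size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  fibers <- list()
  cur <- NULL
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (all(is.infinite(r))) break
    if (any(is.nan(r))) {
      if (!is.null(cur) && nrow(cur) >= 2) fibers[[length(fibers) + 1]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, r)
  }
  fiber_set(fibers)
}

write_trk <- function(fibers, path, affine = diag(4)) {
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(c(1, 1, 1)), con, size = 2)                 # dim
  writeBin(as.numeric(c(1, 1, 1)), con, size = 4)                 # voxel_size
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4)                 # origin
  writeBin(0L, con, size = 2)                                     # n_scalars
  writeBin(raw(200), con)                                         # scalar names
  writeBin(0L, con, size = 2)                                     # n_properties
  writeBin(raw(200), con)                                         # property names
  writeBin(as.numeric(t(affine)), con, size = 4)                  # vox_to_ras
  writeBin(raw(444), con)                                         # reserved
  wchar("LPS", 4)                                                 # voxel_order
  writeBin(raw(4), con)                                           # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)        # img orient
  writeBin(raw(2), con)                                           # pad1
  writeBin(raw(6), con)                                           # flips/swaps
  writeBin(as.integer(length(fibers$fibers)), con, size = 4)      # n_count
  writeBin(2L, con, size = 4)                                     # version
  writeBin(1000L, con, size = 4)                                  # hdr_size
  for (f in fibers$fibers) {
    writeBin(as.integer(nrow(f)), con, size = 4)
    writeBin(as.numeric(t(f)), con, size = 4)
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (rawToChar(magic[1:5]) != "TRACK") parse_error(path, "missing TRK magic", 0)
  seek(con, 6 + 6 + 12 + 12)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  seek(con, 200, origin = "current")
  n_props <- readBin(con, "integer", 1, size = 2)
  seek(con, 200, origin = "current")
  affine <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  seek(con, 444 + 4 + 4 + 24 + 2 + 6, origin = "current")
  n_count <- readBin(con, "integer", 1, size = 4)
  seek(con, 1000)
  fibers <- vector("list", n_count)
  for (k in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4)
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)
    fibers[[k]] <- m[, 1:3, drop = FALSE]
  }
  structure(fiber_set(fibers), affine = affine)
}

#' Write a JSON run manifest
#'
#' Every pipeline output is accompanied by a manifest recording the package
#' version, seed, configuration echo, and any run diagnostics (residual
#' history, GI trace), for provenance.
#'
#' @param path output path (`.json`).
#' @param ... named entries to record.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$tool <- "cortexfold"
  entries$version <- as.character(utils::packageVersion("cortexfold"))
  entries$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
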
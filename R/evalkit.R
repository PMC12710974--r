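# Orientation-field evaluation: voxel-wise absolute cosine similarity,
# aggregation by parcellation region, and white-matter depth profiles.

#' Voxel-wise absolute cosine similarity of two orientation fields
#'
#' `C(v) = |a(v) . b(v)|` wherever both fields are non-empty and the caller's
#' mask is true; empty elsewhere. Both fields hold unit vectors, so the score
#' lies in `[0, 1]` and is invariant to independent sign flips of either
#' field (axial data). Voxels flagged ambiguous in either field are excluded
#' and counted.
#'
#' @param a,b [orientation_field()]s on the same grid.
#' @param mask optional logical vector over voxels (e.g. a white-matter /
#'   non-interhemispheric mask); default all true.
#' @return object of class `similarity_map` (grid + per-voxel score);
#'   attribute `n_ambiguous` counts voxels excluded for eigen-ties.
#' @export
cosine_similarity_map <- function(a, b, mask = NULL) {
  if (!identical(a$grid$dim, b$grid$dim) ||
      !isTRUE(all.equal(a$grid$origin, b$grid$origin)) ||
      !isTRUE(all.equal(a$grid$spacing, b$grid$spacing)))
    stop("orientation fields must share grid geometry")
  nv <- n_voxels(a$grid)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  amb <- rep(FALSE, nv)
  if (!is.null(a$ambiguous)) amb <- amb | a$ambiguous
  if (!is.null(b$ambiguous)) amb <- amb | b$ambiguous
  ok <- mask & !amb & !is.na(a$vectors[, 1]) & !is.na(b$vectors[, 1])
  score <- rep(NA_real_, nv)
  score[ok] <- abs(rowSums(a$vectors[ok, , drop = FALSE] *
                           b$vectors[ok, , drop = FALSE]))
  score[ok] <- pmin(score[ok], 1)   # clip fp overshoot of unit dots
  structure(list(grid = a$grid, score = score),
            class = "similarity_map", n_ambiguous = sum(amb & mask))
}

#' @export
print.similarity_map <- function(x, ...) {
  ok <- !is.na(x$score)
  cat(sprintf("<similarity_map> %d scored voxels, mean |cos| = %.3f\n",
              sum(ok), mean(x$score[ok])))
  invisible(x)
}

#' Group similarity scores by parcellation region
#'
#' Per-label mean/min/max/count over scored voxels, plus the overall mean
#' with and without an excluded-label set (e.g. regions unsuitable for the
#' folding framework).
#'
#' @param sim a [cosine_similarity_map()].
#' @param parcels integer vector of per-voxel parcel labels (same grid).
#' @param exclude labels excluded from the secondary overall mean.
#' @return data.frame (label, count, mean, min, max); attributes
#'   `overall_mean` and `overall_mean_excluding`.
#' @export
region_scores <- function(sim, parcels, exclude = integer(0)) {
  if (length(parcels) != length(sim$score))
    stop("parcel volume must match the similarity grid")
  ok <- !is.na(sim$score) & !is.na(parcels)
  if (!any(ok)) {
    out <- data.frame(label = integer(0), count = integer(0),
                      mean = numeric(0), min = numeric(0), max = numeric(0))
    attr(out, "overall_mean") <- NaN
    attr(out, "overall_mean_excluding") <- NaN
    return(out)
  }
  s <- sim$score[ok]
  l <- parcels[ok]
  agg <- rowsum(cbind(s, 1), l)
  mins <- tapply(s, l, min)
  maxs <- tapply(s, l, max)
  out <- data.frame(label = as.integer(rownames(agg)),
                    count = as.integer(agg[, 2]),
                    mean = agg[, 1] / agg[, 2],
                    min = as.numeric(mins),
                    max = as.numeric(maxs))
  rownames(out) <- NULL
  attr(out, "overall_mean") <- mean(s)
  attr(out, "overall_mean_excluding") <- mean(s[!(l %in% exclude)])
  out
}

#' Similarity profile by depth below the surface
#'
#' Bins scored voxels by Euclidean distance from the voxel center to the
#' nearest surface sample point (bins `[0, w), [w, 2w), ...`) and reports the
#' per-bin mean similarity.
#'
#' @param sim a [cosine_similarity_map()].
#' @param surface_points matrix of surface points (mm); e.g. cortical-face
#'   vertices of the folded mesh.
#' @param bin_width bin width (mm).
#' @param max_depth maximum depth (mm).
#' @return data.frame (depth_lo, depth_hi, count, mean).
#' @export
depth_profile <- function(sim, surface_points, bin_width = 1, max_depth = 6) {
  ok <- which(!is.na(sim$score))
  if (!length(ok))
    return(data.frame(depth_lo = numeric(0), depth_hi = numeric(0),
                      count = integer(0), mean = numeric(0)))
  ctr <- voxel_centers(sim$grid, ok)
  nn <- cpp_nearest(ctr, to_points(surface_points))
  d <- sqrt(rowSums((ctr - to_points(surface_points)[nn, , drop = FALSE])^2))
  bin <- floor(d / bin_width)
  keep <- d < max_depth
  agg <- rowsum(cbind(sim$score[ok][keep], 1), bin[keep])
  b <- as.numeric(rownames(agg))
  data.frame(depth_lo = b * bin_width, depth_hi = (b + 1) * bin_width,
             count = as.integer(agg[, 2]), mean = agg[, 1] / agg[, 2])
}
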
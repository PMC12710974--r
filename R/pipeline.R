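# End-to-end synthetic-slab pipeline: unfold a folded slab, build the
# deformation map, seed radial fibers in the unfolded state, advect them back
# to the folded configuration, extract per-voxel primary peaks, and evaluate
# them against the analytic radial orientation field of the folded slab,
# together with the voxel strain map.

#' Phase classification of slab voxels
#'
#' Classifies positions by their location along the fold wave:
#' `sin(2 pi x / W) > threshold` is a gyral crown, `< -threshold` a sulcal
#' fundus/bank region, the rest transition walls.
#'
#' @param points N x 3 positions (mm) or voxel centers.
#' @param spec the [slab_spec()].
#' @param threshold sine threshold separating crowns/fundi from walls.
#' @return character vector: `"crown"`, `"sulcus"`, or `"wall"`.
#' @export
slab_phase <- function(points, spec, threshold = 0.5) {
  s <- sin(2 * pi * to_points(points)[, 1] / spec$W)
  ifelse(s > threshold, "crown", ifelse(s < -threshold, "sulcus", "wall"))
}

#' Run the folded-slab demonstration pipeline
#'
#' Generates a sinusoidally folded two-tissue slab, unfolds it quasi-statically
#' to the target gyrification index, realizes the deformation map, seeds
#' radial fibers in the unfolded configuration, advects them to the folded
#' configuration, extracts voxel-wise primary peaks, and scores them against
#' the analytic folded-slab orientation field; also computes the voxel strain
#' map of the folding deformation.
#'
#' @param spec a [slab_spec()].
#' @param mat a [material_params()].
#' @param config a [sim_config()] (direction must be `"unfold"`).
#' @param n_seeds radial fiber count.
#' @param fiber_step advection step (mm).
#' @param max_len fiber length (mm).
#' @param voxel_size evaluation grid spacing (mm).
#' @param seed RNG seed for fiber seeding.
#' @param refold also run the refolding pass (for round-trip diagnostics).
#' @param out_dir optional directory: writes VTK snapshots, TCK fibers,
#'   NIfTI maps, CSV scores, and a JSON manifest.
#' @return list with the trajectory, deformation map, fiber sets, peak and
#'   truth orientation fields, similarity map, strain map, per-phase score
#'   and strain summaries, and (optionally) the refold trajectory.
#' @export
slab_pipeline <- function(spec = slab_spec(),
                          mat = material_params(),
                          config = sim_config(n_steps = 500L,
                                              gi_target = 1.05),
                          n_seeds = 800L, fiber_step = 0.2, max_len = 3,
                          voxel_size = 0.325, seed = 1L, refold = FALSE,
                          out_dir = NULL) {
  mesh <- make_folded_slab(spec)
  traj <- run_simulation(mesh, mat, config)
  map <- deformation_map(traj)

  unfolded <- mesh
  unfolded$nodes <- map$reference

  field <- inward_normal_field(unfolded, voxel_size = voxel_size,
                               smooth_iters = 2L, depth = max_len + 1)
  fib0 <- generate_radial_fibers(unfolded, field, step = fiber_step,
                                 max_len = max_len, n_seeds = n_seeds,
                                 seed = seed)
  fib1 <- advect_fibers(map, fib0, t = 1, drop_unlocatable = TRUE)
  # keep the pairing: drop the same fibers from the unfolded set
  flagged <- attr(fib1, "flagged")
  if (length(flagged)) {
    keep <- setdiff(seq_along(fib0$fibers), flagged)
    fib0 <- fiber_set(fib0$fibers[keep],
                      seeds = fib0$seeds[keep, , drop = FALSE])
  }

  grid <- grid_from_bbox(apply(mesh$nodes, 2, min), apply(mesh$nodes, 2, max),
                         voxel_size)
  peaks <- extract_primary_peaks(fib1, grid)
  truth <- rasterize_field(analytic_slab_orientation(spec), grid)
  inside <- mesh_occupancy(mesh, grid)
  sim <- cosine_similarity_map(peaks, truth, mask = inside)
  strain <- strain_map(fib0, fib1, grid)

  scored <- which(!is.na(sim$score))
  phase <- slab_phase(voxel_centers(grid, scored), spec)
  phase_scores <- tapply(sim$score[scored], phase, mean)
  sampled <- which(!is.na(strain$values) & inside)
  sphase <- slab_phase(voxel_centers(grid, sampled), spec)
  phase_strain <- tapply(strain$values[sampled], sphase, mean)

  out <- list(spec = spec, mesh = mesh, trajectory = traj, map = map,
              field = field, fibers_unfolded = fib0, fibers_folded = fib1,
              grid = grid, peaks = peaks, truth = truth, similarity = sim,
              strain = strain,
              mean_cos = mean(sim$score[scored]),
              phase_scores = phase_scores,
              phase_strain = phase_strain)

  if (refold) {
    cfg2 <- config
    cfg2$direction <- "refold"
    out$refold <- run_simulation(mesh, mat, cfg2, resume = traj)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vtk(mesh, file.path(out_dir, "slab_folded.vtk"))
    write_vtk(mesh, file.path(out_dir, "slab_unfolded.vtk"),
              positions = map$reference)
    write_fibers(fib1, file.path(out_dir, "fibers_folded.tck"))
    write_fibers(fib0, file.path(out_dir, "fibers_unfolded.tck"))
    write_volume(ifelse(is.na(sim$score), -1, sim$score), grid,
                 file.path(out_dir, "cosine_similarity.nii.gz"))
    write_volume(ifelse(is.na(strain$values), 0, strain$values), grid,
                 file.path(out_dir, "strain.nii.gz"))
    pv <- peaks$vectors
    pv[is.na(pv)] <- 0
    write_volume(pv, grid, file.path(out_dir, "primary_peaks.nii.gz"))
    scores_df <- data.frame(phase = names(phase_scores),
                            mean_abs_cos = as.numeric(phase_scores))
    utils::write.csv(scores_df, file.path(out_dir, "phase_scores.csv"),
                     row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"),
                   spec = unclass(spec), seed = seed,
                   config = unclass(config),
                   material = unclass(mat)[c("E_white", "E_gray", "nu",
                                             "density", "visco_beta")],
                   gi = as.numeric(traj$gi),
                   mean_cos = out$mean_cos,
                   phase_scores = as.list(phase_scores),
                   phase_strain = as.list(phase_strain))
  }
  out
}
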
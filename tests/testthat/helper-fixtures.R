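# Shared fixtures. Small meshes are rebuilt per use (cheap); the slab
# unfold/refold pipeline at acceptance scale is computed lazily once and
# reused by the acceptance tests.

tiny_slab_spec <- function()
  slab_spec(extent_x = 8, extent_y = 2, depth = 4, fold_amplitude = 1,
            fold_wavelength = 4, gm_thickness = 1, element_size = 0.4)

# the study-condition slab: A/W = 0.25, ~20k tets
acceptance_slab_spec <- function()
  slab_spec(extent_x = 16, extent_y = 3, depth = 6, fold_amplitude = 2,
            fold_wavelength = 8, gm_thickness = 1.5, element_size = 0.45)

acceptance_config <- function()
  sim_config(n_steps = 1800L, gi_target = 1.05, rate_area = 0.005,
             rate_smooth = 0.005, alpha_area = 0.002, alpha_smooth = 0.002,
             settle_steps = 800L)

acceptance_material <- function() material_params(visco_beta = 3e-4)

# unit right-angle rest tet with the fourth vertex free, three pinned
single_tet_fixture <- function() {
  rest <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- tet_mesh(rest, matrix(1:4, 1), rep("white", 4),
                   metadata = list(cortical_faces = integer(0),
                                   freemask = rbind(matrix(0, 3, 3),
                                                    rep(1, 3))))
  list(rest = rest, mesh = mesh,
       Dm = t(rest[2:4, ] - matrix(rest[1, ], 3, 3, byrow = TRUE)))
}

.fixture_env <- new.env(parent = emptyenv())

# memoized acceptance-scale pipeline (unfold + refold + fibers + maps)
acceptance_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- slab_pipeline(
      acceptance_slab_spec(), acceptance_material(), acceptance_config(),
      n_seeds = 1000L, max_len = 4, seed = 1L, refold = TRUE)
  }
  .fixture_env$pipeline
}
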
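# XPBD solver: deformation gradient, neo-Hookean energy, single-constraint
# projections, viscoelastic rest-pose relaxation, quasi-static stepping.

test_that("deformation gradient recovers identity, scaling, and affine maps", {
  fx <- single_tet_fixture()
  expect_equal(deformation_gradient(fx$rest, fx$Dm), diag(3))
  expect_equal(deformation_gradient(fx$rest * 1.7, fx$Dm), 1.7 * diag(3))

  set.seed(11)
  for (k in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    while (det(A) < 0.1) A <- matrix(rnorm(9), 3, 3)
    b <- rnorm(3)
    mapped <- fx$rest %*% t(A) + matrix(b, 4, 3, byrow = TRUE)
    expect_equal(deformation_gradient(mapped, fx$Dm), A, tolerance = 1e-12)
  }
  expect_error(deformation_gradient(fx$rest, matrix(0, 3, 3)), "singular")
})

test_that("neo-Hookean energy reproduces the split formula", {
  expect_equal(neo_hookean_energy(diag(3), 10, 5),
               c(psi_h = 0, psi_d = 0))
  # F = 2I, lambda = 2, mu = 0: (2/2)(8-1)^2 = 49
  expect_equal(neo_hookean_energy(2 * diag(3), 2, 0),
               c(psi_h = 49, psi_d = 0))
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(neo_hookean_energy(R, 7, 3), c(psi_h = 0, psi_d = 0),
               tolerance = 1e-12)
})

test_that("tet projection: hydrostatic rest is exact, deviatoric rest force is O(dt^2)", {
  fx <- single_tet_fixture()
  st <- sim_state(fx$rest, rep(1, 4))
  con <- tet_constraint(1:4, fx$rest, 100, 50)
  # at rest C_H = 0: a hydrostatic-only projection moves nothing
  conH <- con
  conH$alpha_D <- 1e30
  s1 <- project_tet_constraint(st, conH, dt_sub = 0.1)
  expect_equal(s1$positions, fx$rest, tolerance = 1e-12)
  expect_equal(attr(s1, "C_H"), 0, tolerance = 1e-12)
  # the printed deviatoric constraint has value sqrt(3) at rest: a single
  # projection moves nodes by O(dt^2 / alpha_D), vanishing as dt -> 0
  d <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    s <- project_tet_constraint(st, con, dt_sub = dt)
    max(abs(s$positions - fx$rest))
  }, numeric(1))
  expect_lt(d[2], d[1] / 3)
  expect_lt(d[3], d[2] / 3)
})

test_that("uniformly scaled tet converges to det(F) = 1 under the hydrostatic constraint", {
  fx <- single_tet_fixture()
  x <- fx$rest * 1.3
  st <- sim_state(x, rep(1, 4))
  con <- tet_constraint(1:4, fx$rest, 1, 1)
  con$alpha_D <- 1e30                     # deviatoric off
  con$alpha_H <- 1e-9                     # alpha -> 0: hard projection
  lam <- 0
  for (i in 1:200) {
    st <- project_tet_constraint(st, con, dt_sub = 1, lambda_h = lam)
  }
  F <- deformation_gradient(st$positions, fx$Dm)
  expect_equal(det(F), 1, tolerance = 1e-6)
})

test_that("heavier nodes move less in exact inverse-mass ratio", {
  fx <- single_tet_fixture()
  x <- fx$rest
  x[3:4, ] <- x[3:4, ] * 1.2
  st <- sim_state(x, c(0, 0, 1, 4))   # node 3 four times heavier than node 4
  con <- tet_constraint(1:4, fx$rest, 100, 50)
  conH <- con
  conH$alpha_D <- 1e30
  s1 <- project_tet_constraint(st, conH, dt_sub = 1)
  d3 <- sqrt(sum((s1$positions[3, ] - x[3, ])^2))
  d4 <- sqrt(sum((s1$positions[4, ] - x[4, ])^2))
  g3 <- sqrt(sum((s1$positions[3, ] - x[3, ])^2))  # displacement = w * g * dl
  # with equal gradient norms the ratio would be exactly 1:4; compare
  # dl-normalized: d_i / (w_i |grad_i|) identical
  expect_gt(d4, d3)
  # pinned vertices (w = 0) never move
  expect_equal(s1$positions[1:2, ], x[1:2, ])
})

test_that("area projection is idle at the rest area and shrinks similarly", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  A0 <- face_areas(tri, matrix(1:3, 1))
  st <- sim_state(tri, rep(1, 3))
  s0 <- project_area_constraint(st, 1:3, rest_area = A0, alpha = 0, dt_sub = 1)
  expect_equal(s0$positions, tri, tolerance = 1e-12)

  # equilateral triangle, R = A0/2, alpha = 0, equal masses: iterating the
  # projection converges to half the area via a pure similarity (uniform
  # scaling about the centroid preserves the equilateral shape)
  s <- st
  for (i in 1:300) s <- project_area_constraint(s, 1:3, A0 / 2, 0, 1)
  expect_equal(as.numeric(face_areas(s$positions, matrix(1:3, 1))),
               as.numeric(A0 / 2), tolerance = 1e-9)
  ctr0 <- colMeans(tri)
  e0 <- tri - matrix(ctr0, 3, 3, byrow = TRUE)
  e1 <- s$positions - matrix(colMeans(s$positions), 3, 3, byrow = TRUE)
  expect_equal(e1 / sqrt(0.5), e0, tolerance = 1e-4)   # scaled by sqrt(1/2)

  # pinned vertices: only the free one moves
  stp <- sim_state(tri, c(0, 0, 1))
  sp <- project_area_constraint(stp, 1:3, A0 / 2, 0, 1)
  expect_equal(sp$positions[1:2, ], tri[1:2, ])
  expect_false(isTRUE(all.equal(sp$positions[3, ], tri[3, ])))
})

test_that("smoothing projection is idle at rest and flattens a roof monotonically", {
  # roof: two triangles sharing edge (s0, s1), opposite vertices a, b raised
  a <- c(-1, 0, 0.5); s0 <- c(0, -1, 0); s1 <- c(0, 1, 0); b <- c(1, 0, 0.5)
  x <- rbind(a, s0, s1, b)
  L0 <- 0.5 * sqrt(sum(((a + b) - (s0 + s1))^2))
  st <- sim_state(x, rep(1, 4))
  sidle <- project_smoothing_constraint(st, 1:4, L0, alpha = 0, dt_sub = 1)
  expect_equal(sidle$positions, x, tolerance = 1e-12, ignore_attr = TRUE)

  # L -> 0: the shared-edge midpoint approaches the midpoint of (a, b)
  gap <- function(p) 0.5 * sqrt(sum(((p[1, ] + p[4, ]) - (p[2, ] + p[3, ]))^2))
  s <- st
  gaps <- gap(x)
  for (i in 1:50) {
    s <- project_smoothing_constraint(s, 1:4, 0, alpha = 0.5, dt_sub = 1)
    gaps <- c(gaps, gap(s$positions))
  }
  expect_true(all(diff(gaps) <= 1e-12))
  expect_lt(gaps[length(gaps)], gaps[1])

  # translation invariance
  sh <- matrix(c(3, -2, 7), 4, 3, byrow = TRUE)
  st2 <- sim_state(x + sh, rep(1, 4))
  s2 <- project_smoothing_constraint(st2, 1:4, 0, alpha = 0.5, dt_sub = 1)
  s1b <- project_smoothing_constraint(st, 1:4, 0, alpha = 0.5, dt_sub = 1)
  expect_equal(s2$positions - sh, s1b$positions, tolerance = 1e-12)
})

test_that("viscoelastic rest blending is exponential and composes", {
  Dm <- diag(3)
  Ds <- matrix(rnorm(9, sd = 0.1), 3, 3) + diag(3)
  expect_identical(update_viscoelastic_rest(Dm, Ds, 0, 1), Dm)
  expect_equal(update_viscoelastic_rest(Dm, Ds, 1e9, 1), Ds, tolerance = 1e-9)
  # two half-steps equal one full step
  one <- update_viscoelastic_rest(Dm, Ds, 0.3, 2)
  half <- update_viscoelastic_rest(update_viscoelastic_rest(Dm, Ds, 0.3, 1),
                                   Ds, 0.3, 1)
  expect_equal(half, one, tolerance = 1e-12)
})

test_that("a satisfied state is exactly stationary across steps (infinite damping)", {
  m <- make_unit_cube(1, 0.25)
  m$metadata$cortical_faces <- integer(0)
  mat <- material_params(visco_beta = 0)
  cfg <- sim_config(n_steps = 10L, rate_area = 0, rate_smooth = 0,
                    snapshot_every = 10L)
  tr <- run_simulation(m, mat, cfg)
  expect_equal(tr$snapshots[[2]], m$nodes, tolerance = 1e-14)
})

test_that("slab unfolding decreases GI monotonically and conserves volume", {
  m <- make_folded_slab(tiny_slab_spec())
  mat <- material_params(visco_beta = 5e-4)
  cfg <- sim_config(n_steps = 150L, snapshot_every = 25L)
  tr <- run_simulation(m, mat, cfg)
  expect_true(all(diff(tr$gi) < 0))
  xf <- tr$snapshots[[length(tr$snapshots)]]
  expect_lt(abs(total_volume(m, xf) / total_volume(m) - 1), 0.05)
  # surface area of the cortical faces is non-increasing
  cf <- m$faces[m$metadata$cortical_faces, , drop = FALSE]
  areas <- vapply(tr$snapshots, function(x) sum(face_areas(x, cf)), numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("early GI stop yields a single snapshot for an already-unfolded slab", {
  sp <- slab_spec(extent_x = 8, extent_y = 2, depth = 4, fold_amplitude = 0,
                  fold_wavelength = 4, gm_thickness = 1, element_size = 0.4)
  m <- make_folded_slab(sp)
  tr <- run_simulation(m, material_params(),
                       sim_config(n_steps = 100L, gi_target = 1.0))
  expect_identical(length(tr$snapshots), 1L)
  expect_true(attr(tr, "stopped_early"))
})

test_that("simulation is bit-deterministic for identical config", {
  m <- make_folded_slab(tiny_slab_spec())
  mat <- material_params()
  cfg <- sim_config(n_steps = 40L, snapshot_every = 20L)
  t1 <- run_simulation(m, mat, cfg)
  t2 <- run_simulation(m, mat, cfg)
  expect_identical(t1$snapshots, t2$snapshots)
})

test_that("increasing substeps does not increase the final residual", {
  m <- make_folded_slab(tiny_slab_spec())
  mat <- material_params()
  res <- vapply(c(10L, 30L), function(sub) {
    cfg <- sim_config(n_steps = 30L, substeps = sub, snapshot_every = 30L)
    tr <- run_simulation(m, mat, cfg)
    tail(tr$residuals[, "hydro"], 1)
  }, numeric(1))
  expect_lte(res[2], res[1] + 1e-12)
})
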
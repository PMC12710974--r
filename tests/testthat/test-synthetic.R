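# Synthetic geometry generators: folded slab, unit cube, wavy sphere, and
# the analytic radial orientation field.

test_that("flat slab (A = 0) has exact top area and unit GI", {
  sp <- slab_spec(extent_x = 10, extent_y = 4, depth = 5, fold_amplitude = 0,
                  fold_wavelength = 10, gm_thickness = 1.2,
                  element_size = 0.5)
  m <- make_folded_slab(sp)
  top <- m$faces[m$metadata$cortical_faces, , drop = FALSE]
  expect_equal(sum(face_areas(m$nodes, top)), 10 * 4, tolerance = 1e-12)
  expect_equal(as.numeric(gyrification_index(m)), 1, tolerance = 1e-9)
})

test_that("folded slab has GI > 1, positive volumes, valid surface", {
  m <- make_folded_slab(tiny_slab_spec())
  expect_gt(as.numeric(gyrification_index(m)), 1)
  expect_gt(min(tet_volumes(m)), 0)
  rep <- validate_mesh(m)
  expect_true(rep$ok)
  expect_identical(rep$n_inverted, 0L)
})

test_that("slab generation is deterministic and two-tissue", {
  sp <- tiny_slab_spec()
  m1 <- make_folded_slab(sp)
  m2 <- make_folded_slab(sp)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_gt(sum(m1$tissue == "gray"), 0)
  expect_gt(sum(m1$tissue == "white"), 0)
})

test_that("degenerate slab specs are rejected", {
  expect_error(slab_spec(fold_amplitude = 7, depth = 6), "geometry error")
  expect_error(slab_spec(element_size = 2, gm_thickness = 1.5), "element_size")
})

test_that("unit cube has exact volume and scales cubically", {
  expect_equal(total_volume(make_unit_cube(1, 0.25)), 1, tolerance = 1e-9)
  expect_equal(total_volume(make_unit_cube(2, 0.5)), 8, tolerance = 1e-9)
  expect_gt(min(tet_volumes(make_unit_cube(1, 0.25))), 0)
})

test_that("wavy sphere matches analytic sphere at zero amplitude", {
  s0 <- make_wavy_sphere(1, 3, 0, 0.2)
  vol <- total_volume(s0)
  area <- total_surface_area(s0)
  r_eff <- (3 * vol / (4 * pi))^(1 / 3)
  expect_equal(area / vol, 3 / r_eff, tolerance = 0.02)
  expect_true(validate_mesh(s0)$ok)
})

test_that("lobed perturbation strictly increases surface area", {
  s0 <- make_wavy_sphere(1, 3, 0, 0.2)
  s1 <- make_wavy_sphere(1, 3, 0.15, 0.2)
  expect_true(validate_mesh(s1)$ok)
  expect_equal(total_volume(s1), total_volume(s0), tolerance = 0.05)
  expect_gt(total_surface_area(s1), total_surface_area(s0))
})

test_that("zero lobes reproduce the plain sphere", {
  expect_identical(make_wavy_sphere(1, 0, 0.3, 0.25)$nodes,
                   make_wavy_sphere(1, 5, 0, 0.25)$nodes)
})

test_that("analytic slab field is unit length, vertical when flat and at crests", {
  spf <- slab_spec(extent_x = 8, extent_y = 2, depth = 4, fold_amplitude = 0,
                   fold_wavelength = 4, gm_thickness = 1, element_size = 0.4)
  af0 <- analytic_slab_orientation(spf)
  d <- af0$direction(rbind(c(1, 1, 2), c(5, 0.3, 3.7)))
  expect_equal(d, cbind(c(0, 0), c(0, 0), c(-1, -1)), ignore_attr = TRUE)

  sp <- tiny_slab_spec()
  af <- analytic_slab_orientation(sp)
  # crest at x = W/4: vertical at any depth by symmetry
  dc <- af$direction(rbind(c(sp$W / 4, 1, 3), c(sp$W / 4, 0.2, 0.5)))
  expect_equal(dc[, 1], c(0, 0), tolerance = 1e-8)
  expect_equal(dc[, 3], c(-1, -1), tolerance = 1e-8)

  set.seed(3)
  p <- cbind(runif(100, 0, 8), runif(100, 0, 2), runif(100, 0, 4))
  dn <- af$direction(p)
  expect_equal(sqrt(rowSums(dn^2)), rep(1, 100), tolerance = 1e-9)
})

test_that("analytic field agrees with a nearest-point oracle near the surface", {
  sp <- tiny_slab_spec()
  af <- analytic_slab_orientation(sp)
  g <- function(x) sp$depth + sp$A * sin(2 * pi * x / sp$W)
  set.seed(4)
  p <- cbind(runif(2000, 0, 8), runif(2000, 0, 2), runif(2000, 0, 4))
  # keep points inside, within the caustic-free band below the surface
  keep <- p[, 3] < g(p[, 1]) & (g(p[, 1]) - p[, 3]) < 0.3
  p <- p[keep, , drop = FALSE]
  d <- af$direction(p)
  xs <- seq(-sp$W, sp$extent_x + sp$W, length.out = 40001)
  crv <- cbind(xs, g(xs))
  for (i in seq_len(nrow(p))) {
    j <- which.min((p[i, 1] - crv[, 1])^2 + (p[i, 3] - crv[, 2])^2)
    v <- c(p[i, 1] - crv[j, 1], 0, p[i, 3] - crv[j, 2])
    v <- v / sqrt(sum(v^2))           # inward: from surface into the slab
    expect_gt(sum(v * d[i, ]), 0.99)
  }
})
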
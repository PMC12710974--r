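# Mesh data model: validation, parcellation, majority-vote relabeling, mass
# lumping, gyrification index.

test_that("validate_mesh reports inverted tets and rejects empty meshes", {
  m <- make_folded_slab(tiny_slab_spec())
  expect_identical(validate_mesh(m)$n_inverted, 0L)

  m2 <- m
  m2$tets[5, ] <- m2$tets[5, c(2, 1, 3, 4)]   # swap two vertices: sign flip
  expect_identical(validate_mesh(m2)$n_inverted, 1L)

  expect_error(validate_mesh(list(tets = matrix(integer(0), 0, 4))),
               "no tetrahedra")
})

test_that("parcellation copies labels for a zero-distance atlas", {
  m <- make_folded_slab(tiny_slab_spec())
  sn <- sort(unique(as.vector(m$faces)))
  labs <- seq_along(sn)
  atl <- surface_atlas(m$nodes[sn, ], labs)
  m <- assign_parcellation(m, atl)
  expect_identical(m$parcel[sn], labs)
  # interior nodes got the sentinel
  expect_true(all(m$parcel[-sn] == 0L))
})

test_that("single-label and half-space atlases label by proximity", {
  m <- make_folded_slab(tiny_slab_spec())
  sn <- sort(unique(as.vector(m$faces)))
  atl1 <- surface_atlas(matrix(c(0, 0, 0), 1), 7L)
  expect_true(all(assign_parcellation(m, atl1)$parcel[sn] == 7L))

  set.seed(1)
  av <- cbind(runif(200, -4, 12), runif(200, 0, 2), runif(200, 0, 5))
  al <- ifelse(av[, 1] < 4, 1L, 2L)
  m2 <- assign_parcellation(m, surface_atlas(av, al))
  # brute-force nearest neighbour oracle
  for (i in sample(sn, 50)) {
    d <- colSums((t(av) - m$nodes[i, ])^2)
    expect_identical(m2$parcel[i], al[which.min(d)])
  }
  expect_error(surface_atlas(matrix(numeric(0), 0, 3), integer(0)),
               "empty atlas")
})

test_that("majority vote: uniform labels are a fixed point, a lone outlier is corrected", {
  m <- make_folded_slab(tiny_slab_spec())
  sn <- sort(unique(as.vector(m$faces)))
  m$parcel <- rep(0L, nrow(m$nodes))
  m$parcel[sn] <- 3L
  m1 <- majority_vote_relabel(m, max_iters = 1L)
  expect_identical(m1$parcel[sn], rep(3L, length(sn)))
  expect_true(attr(m1$parcel, "converged"))

  # corrupt one well-connected surface node
  deg <- table(as.vector(m$faces))
  mid <- as.integer(names(which.max(deg)))
  m$parcel[mid] <- 9L
  m2 <- majority_vote_relabel(m, max_iters = 1L)
  expect_identical(m2$parcel[mid], 3L)
})

test_that("majority vote never invents labels and converges on a checkerboard", {
  m <- make_folded_slab(tiny_slab_spec())
  sn <- sort(unique(as.vector(m$faces)))
  m$parcel <- rep(0L, nrow(m$nodes))
  # checkerboard by parity of lattice position
  m$parcel[sn] <- 1L + (round(m$nodes[sn, 1] / 0.4) +
                        round(m$nodes[sn, 2] / 0.4)) %% 2L
  m3 <- majority_vote_relabel(m, max_iters = 25L)
  expect_true(all(m3$parcel[sn] %in% c(1L, 2L)))
  expect_type(attr(m3$parcel, "converged"), "logical")
  if (attr(m3$parcel, "converged")) {
    # fixed point: one more iteration changes nothing
    m4 <- majority_vote_relabel(m3, max_iters = 1L)
    expect_identical(m4$parcel[sn], m3$parcel[sn])
  }
})

test_that("mass lumping conserves total mass and splits single tets evenly", {
  cu <- compute_node_masses(make_unit_cube(1, 0.25), 1040)
  expect_equal(sum(cu$node_mass), 1.04e-6, tolerance = 1e-9)

  tet <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(1:4, 1), rep("white", 4))
  tet <- compute_node_masses(tet, 1000)
  expect_equal(tet$node_mass, rep(1000 * (1 / 6) * 1e-9 / 4, 4))

  cu2 <- compute_node_masses(make_unit_cube(1, 0.25), 2080)
  expect_equal(cu2$node_mass, 2 * cu$node_mass)
  expect_error(compute_node_masses(cu, -1), "positive")
})

test_that("gyrification index matches the 1-D quadrature oracle on the folded slab", {
  sp <- slab_spec(extent_x = 8, extent_y = 2, depth = 4, fold_amplitude = 1,
                  fold_wavelength = 4, gm_thickness = 1, element_size = 0.25)
  m <- make_folded_slab(sp)
  k <- 2 * pi * sp$A / sp$W
  oracle <- stats::integrate(function(x) sqrt(1 + k^2 * cos(2 * pi * x / sp$W)^2),
                             0, sp$W)$value / sp$W
  expect_equal(as.numeric(gyrification_index(m)), oracle, tolerance = 0.02)
})

test_that("GI of a sphere is 1 and is rigid/scale invariant for closed surfaces", {
  s0 <- make_wavy_sphere(1, 0, 0, 0.2)
  expect_equal(as.numeric(gyrification_index(s0)), 1, tolerance = 0.02)

  ws <- make_wavy_sphere(1, 3, 0.15, 0.25)
  gi0 <- as.numeric(gyrification_index(ws))
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ws2 <- ws
  ws2$nodes <- ws$nodes %*% t(Rz) * 2.5 +
    matrix(c(10, -3, 4), nrow(ws$nodes), 3, byrow = TRUE)
  expect_equal(as.numeric(gyrification_index(ws2)), gi0, tolerance = 1e-9)
})
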
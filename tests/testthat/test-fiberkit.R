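# Fiber machinery: inward-normal fields, radial fiber generation, advection,
# Bezier bundles, primary-peak extraction.

flat_slab <- function()
  make_folded_slab(slab_spec(extent_x = 6, extent_y = 2, depth = 4,
                             fold_amplitude = 0, fold_wavelength = 6,
                             gm_thickness = 1, element_size = 0.4))

test_that("flat-slab inward normals are uniformly (0, 0, -1)", {
  m <- flat_slab()
  f <- inward_normal_field(m, voxel_size = 0.4, smooth_iters = 2L, depth = 3)
  ok <- !is.na(f$vectors[, 1])
  expect_gt(sum(ok), 100)
  expect_true(all(abs(f$vectors[ok, 1]) < 1e-6))
  expect_true(all(abs(f$vectors[ok, 2]) < 1e-6))
  expect_true(all(abs(f$vectors[ok, 3] + 1) < 1e-6))
  expect_error(inward_normal_field(m, voxel_size = -1), "positive")
})

test_that("sphere normals point to the center within 5 degrees near the surface", {
  s <- make_wavy_sphere(1, 0, 0, 0.2)
  f <- inward_normal_field(s, voxel_size = 0.15, smooth_iters = 1L,
                           depth = 0.3)
  ids <- which(!is.na(f$vectors[, 1]))
  ctr <- voxel_centers(f$grid, ids)
  r <- sqrt(rowSums(ctr^2))
  near <- which(abs(r - 1) < 0.15 & r > 0.5)
  cosang <- rowSums(f$vectors[ids[near], , drop = FALSE] *
                    (-ctr[near, , drop = FALSE] / r[near]))
  expect_gt(mean(cosang > cos(5 * pi / 180)), 0.95)
})

test_that("smoothing does not increase angular variation between neighbours", {
  m <- make_folded_slab(tiny_slab_spec())
  rough <- inward_normal_field(m, voxel_size = 0.4, smooth_iters = 0L,
                               depth = 2)
  smooth <- inward_normal_field(m, voxel_size = 0.4, smooth_iters = 3L,
                                depth = 2)
  angvar <- function(f) {
    ids <- which(!is.na(f$vectors[, 1]))
    v <- f$vectors[ids, , drop = FALSE]
    nb <- ids + 1L   # +x neighbours
    keep <- nb %in% ids
    j <- match(nb[keep], ids)
    mean(1 - abs(rowSums(v[keep, , drop = FALSE] * v[j, , drop = FALSE])))
  }
  expect_lte(angvar(smooth), angvar(rough) + 1e-12)
})

test_that("radial fibers on a flat slab are vertical with the right depth", {
  m <- flat_slab()
  f <- inward_normal_field(m, voxel_size = 0.4, smooth_iters = 2L, depth = 3.2)
  fib <- generate_radial_fibers(m, f, step = 0.2, max_len = 2.5,
                                n_seeds = 60L, seed = 7L)
  expect_gt(length(fib$fibers), 40)
  for (fl in fib$fibers) {
    # first-segment direction is the inward normal
    d1 <- fl[2, ] - fl[1, ]
    d1 <- d1 / sqrt(sum(d1^2))
    expect_gt(sum(d1 * c(0, 0, -1)), 0.99)
    # vertical: x and y nearly constant
    expect_lt(max(abs(fl[, 1] - fl[1, 1])), 1e-6)
  }
  lens <- fiber_lengths(fib)
  expect_true(all(abs(lens - 2.5) <= 0.2 + 1e-9))   # within one step
  # all points inside the mesh bounding volume
  allp <- do.call(rbind, fib$fibers)
  expect_true(all(allp[, 3] >= -1e-9 & allp[, 3] <= 4 + 1e-9))
})

test_that("fiber generation is seed-deterministic", {
  m <- flat_slab()
  f <- inward_normal_field(m, voxel_size = 0.4, smooth_iters = 1L, depth = 3)
  a <- generate_radial_fibers(m, f, n_seeds = 30L, seed = 5L)
  b <- generate_radial_fibers(m, f, n_seeds = 30L, seed = 5L)
  c <- generate_radial_fibers(m, f, n_seeds = 30L, seed = 6L)
  expect_identical(a$fibers, b$fibers)
  expect_false(identical(a$seeds, c$seeds))
})

test_that("advection at t = 0 is the identity and translations preserve lengths", {
  m <- make_folded_slab(tiny_slab_spec())
  cvec <- c(1, 2, -0.5)
  snaps <- list(m$nodes, m$nodes + matrix(cvec, nrow(m$nodes), 3, byrow = TRUE))
  traj <- structure(list(mesh = m, snapshots = snaps, times = 0:1,
                         direction = "refold"), class = "fold_trajectory")
  map <- deformation_map(traj)
  set.seed(1)
  fib <- fiber_set(lapply(1:10, function(k) {
    p <- c(runif(1, 1, 7), runif(1, 0.5, 1.5), runif(1, 2, 3))
    rbind(p, p + c(0.2, 0, -0.8), p + c(0.3, 0.1, -1.5))
  }))
  f0 <- advect_fibers(map, fib, 0)
  expect_equal(f0$fibers, fib$fibers, tolerance = 1e-9, ignore_attr = TRUE)
  f1 <- advect_fibers(map, fib, 1)
  expect_equal(fiber_lengths(f1), fiber_lengths(fib), tolerance = 1e-9)
  expect_equal(f1$fibers[[3]], fib$fibers[[3]] +
                 matrix(cvec, 3, 3, byrow = TRUE), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("Bezier bundles are deterministic and exact in the degenerate case", {
  A <- matrix(c(0, 0, 0), 1)
  B <- matrix(c(2, 0, 0), 1)
  bb <- bezier_bundle(A, B, n_fibers = 5L, sigma = 0, n_points = 64L, seed = 1L)
  # all curves identical straight segments of length d
  expect_equal(fiber_lengths(bb), rep(2, 5), tolerance = 1e-9)
  expect_equal(bb$fibers[[1]][32, ], bb$fibers[[5]][32, ])
  mid <- bb$fibers[[1]][ceiling(64 / 2), ]
  expect_equal(bb$fibers[[1]][1, ], c(0, 0, 0))
  expect_equal(bb$fibers[[1]][64, ], c(2, 0, 0))
  # jittered bundles interpolate the endpoints exactly and reproduce by seed
  set.seed(99)
  A2 <- matrix(rnorm(30), 10)
  B2 <- matrix(rnorm(30) + 5, 10)
  b1 <- bezier_bundle(A2, B2, n_fibers = 20L, seed = 3L)
  b2 <- bezier_bundle(A2, B2, n_fibers = 20L, seed = 3L)
  expect_identical(b1$fibers, b2$fibers)
  for (f in b1$fibers) {
    expect_true(any(vapply(seq_len(10), function(i)
      isTRUE(all.equal(f[1, ], A2[i, ])), logical(1))))
  }
  expect_error(bezier_bundle(matrix(numeric(0), 0, 3), B, 5), "non-empty")
})

test_that("primary peaks recover parallel directions and flag ties", {
  grid <- vox_grid(c(0, 0, 0), 1, c(3, 3, 3))
  # all segments along x crossing the center voxel
  fib <- fiber_set(lapply(1:5, function(k)
    rbind(c(0.6, 1, 1), c(1.4, 1, 1))))
  pk <- extract_primary_peaks(fib, grid)
  id <- voxel_id(grid, world_to_voxel(grid, matrix(c(1, 1, 1), 1)))
  expect_equal(abs(pk$vectors[id, 1]), 1, tolerance = 1e-9)

  # two equal orthogonal populations: ambiguous
  fib2 <- fiber_set(list(rbind(c(0.6, 1, 1), c(1.4, 1, 1)),
                         rbind(c(1, 0.6, 1), c(1, 1.4, 1))))
  pk2 <- extract_primary_peaks(fib2, grid)
  expect_true(pk2$ambiguous[id])
  expect_true(is.na(pk2$vectors[id, 1]))
})

test_that("an 80/20 direction mixture yields a peak near the dominant direction", {
  set.seed(12)
  grid <- vox_grid(c(0, 0, 0), 1, c(1, 1, 1))
  dom <- c(1, 0, 0)
  segs <- lapply(1:50, function(k) {
    d <- if (k <= 40) dom else c(0, 1, 0)
    d <- d + rnorm(3, sd = 0.05)
    d <- d / sqrt(sum(d^2)) * 0.3
    s <- runif(3, 0.2, 0.8) * 0 + c(0, 0, 0)   # stay in the single voxel
    rbind(c(0, 0, 0) + 0.35, c(0, 0, 0) + 0.35 + d)
  })
  pk <- extract_primary_peaks(fiber_set(segs), grid)
  v <- pk$vectors[1, ]
  # oracle: eigendecomposition of the accumulated orientation tensor
  dirs <- t(vapply(segs, function(s) {
    d <- s[2, ] - s[1, ]; d / sqrt(sum(d^2))
  }, numeric(3)))
  Tm <- crossprod(dirs)
  ev <- eigen(Tm, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(v * ev)), 0.9999)
  expect_gt(abs(sum(v * dom)), cos(10 * pi / 180))
})

test_that("peak extraction is antipodally symmetric", {
  set.seed(13)
  grid <- vox_grid(c(0, 0, 0), 1, c(1, 1, 1))
  segs <- lapply(1:20, function(k) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2)) * 0.3
    rbind(c(0.35, 0.35, 0.35), c(0.35, 0.35, 0.35) + d)
  })
  flipped <- lapply(seq_along(segs), function(k)
    if (k %% 2 == 0) segs[[k]][2:1, ] else segs[[k]])
  p1 <- extract_primary_peaks(fiber_set(segs), grid)$vectors[1, ]
  p2 <- extract_primary_peaks(fiber_set(flipped), grid)$vectors[1, ]
  expect_equal(abs(sum(p1 * p2)), 1, tolerance = 1e-9)
})
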
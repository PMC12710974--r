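# Deformation map: time normalization, barycentric point location, the map
# Phi_t, and the voxel strain map.

# helper: trajectory-like object from a list of snapshots
fake_traj <- function(snaps, direction = "refold") {
  mesh <- make_folded_slab(tiny_slab_spec())
  structure(list(mesh = mesh, snapshots = snaps,
                 times = seq_along(snaps) - 1, direction = direction),
            class = "fold_trajectory")
}

test_that("normalize_time makes durations proportional to displacement", {
  m <- make_folded_slab(tiny_slab_spec())
  x0 <- m$nodes
  sh <- function(d) x0 + matrix(c(d, 0, 0), nrow(x0), 3, byrow = TRUE)
  tr <- normalize_time(list(snapshots = list(x0, sh(1), sh(2))))
  expect_equal(tr$normalized_times, c(0, 0.5, 1))
  tr2 <- normalize_time(list(snapshots = list(x0, sh(1), sh(4))))
  expect_equal(tr2$normalized_times, c(0, 0.25, 1))

  # property: interval durations proportional to mean displacements
  set.seed(5)
  snaps <- list(x0)
  for (k in 1:5) snaps[[k + 1]] <- snaps[[k]] + matrix(rnorm(3, sd = 0.3),
                                                       nrow(x0), 3,
                                                       byrow = TRUE)
  tr3 <- normalize_time(list(snapshots = snaps))
  d <- vapply(1:5, function(k)
    mean(sqrt(rowSums((snaps[[k + 1]] - snaps[[k]])^2))), numeric(1))
  expect_equal(diff(tr3$normalized_times), d / sum(d), tolerance = 1e-12)

  expect_error(normalize_time(list(snapshots = list(x0, x0))),
               "no deformation")
})

test_that("locate_point returns exact barycentric coordinates", {
  m <- make_folded_slab(tiny_slab_spec())
  map <- deformation_map(fake_traj(list(m$nodes, m$nodes * 1.0 + 0.5)))
  # a node: its own coordinate is 1
  loc <- locate_point(map, m$nodes[17, ])
  b <- loc$bary[1, ]
  tv <- m$tets[loc$tet[1], ]
  expect_equal(sort(b, decreasing = TRUE)[1], 1, tolerance = 1e-9)
  expect_equal(as.numeric(b %*% m$nodes[tv, ]), m$nodes[17, ],
               tolerance = 1e-9)
  # a centroid: all quarters
  ctr <- colMeans(m$nodes[m$tets[40, ], ])
  loc2 <- locate_point(map, ctr)
  expect_equal(as.numeric(loc2$bary[1, ]), rep(0.25, 4), tolerance = 1e-9)
  # outside: NA
  expect_true(is.na(locate_point(map, c(100, 100, 100))$tet))
})

test_that("indexed lookup agrees with a brute-force scan on random interior points", {
  m <- make_folded_slab(tiny_slab_spec())
  set.seed(8)
  # random interior points: random tets, random barycentric weights
  ti <- sample.int(nrow(m$tets), 300, replace = TRUE)
  w <- matrix(stats::rexp(1200), ncol = 4)
  w <- w / rowSums(w)
  pts <- t(vapply(seq_along(ti), function(k)
    as.numeric(w[k, ] %*% m$nodes[m$tets[ti[k], ], ]), numeric(3)))
  loc <- locate_point(m, pts)
  for (k in seq_along(ti)) {
    tv <- m$tets[loc$tet[k], ]
    rec <- as.numeric(loc$bary[k, ] %*% m$nodes[tv, ])
    expect_equal(rec, pts[k, ], tolerance = 1e-9)
  }
})

test_that("Phi_0 is the identity and snapshots are recovered at their times", {
  m <- make_folded_slab(tiny_slab_spec())
  x1 <- m$nodes
  x1[, 3] <- x1[, 3] * 0.9
  map <- deformation_map(fake_traj(list(m$nodes, x1)))
  set.seed(2)
  ti <- sample.int(nrow(m$tets), 100, replace = TRUE)
  w <- matrix(stats::rexp(400), ncol = 4)
  w <- w / rowSums(w)
  pts <- t(vapply(seq_along(ti), function(k)
    as.numeric(w[k, ] %*% m$nodes[m$tets[ti[k], ], ]), numeric(3)))
  expect_equal(map_point(map, pts, 0), pts, tolerance = 1e-9)
  # node j at t = 1 lands on its snapshot position
  expect_equal(map_point(map, m$nodes[33, ], 1)[1, ], x1[33, ],
               tolerance = 1e-9)
})

test_that("rigid-translation trajectories map points linearly in t", {
  m <- make_folded_slab(tiny_slab_spec())
  cvec <- c(2, -1, 3)
  sh <- function(a) m$nodes + matrix(a * cvec, nrow(m$nodes), 3, byrow = TRUE)
  map <- deformation_map(fake_traj(list(m$nodes, sh(0.5), sh(1))))
  p <- rbind(c(1.1, 0.7, 2.2), c(6.5, 1.2, 0.9))
  for (t in c(0.25, 0.6, 1)) {
    expect_equal(map_point(map, p, t),
                 p + matrix(t * cvec, 2, 3, byrow = TRUE), tolerance = 1e-9)
  }
})

test_that("Phi is continuous across shared tet faces", {
  m <- make_folded_slab(tiny_slab_spec())
  x1 <- m$nodes * 0.93 + 0.1
  map <- deformation_map(fake_traj(list(m$nodes, x1)))
  # sample points on interior faces: face shared by two tets
  f <- rbind(m$tets[, c(1, 2, 3)], m$tets[, c(1, 2, 4)],
             m$tets[, c(1, 3, 4)], m$tets[, c(2, 3, 4)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  shared <- f[duplicated(key), , drop = FALSE][1:20, ]
  set.seed(6)
  for (k in seq_len(nrow(shared))) {
    w <- stats::rexp(3); w <- w / sum(w)
    p <- as.numeric(w %*% m$nodes[shared[k, ], ])
    # the image must be well-defined regardless of which adjacent tet hosts p
    img <- map_point(map, p, 0.7)
    expect_equal(as.numeric(img),
                 as.numeric(w %*% (0.3 * m$nodes + 0.7 * x1)[shared[k, ], ]),
                 tolerance = 1e-9)
  }
})

test_that("strain map is zero for identity deformations and exact for scaling", {
  set.seed(3)
  fibs <- fiber_set(lapply(1:20, function(k) {
    p0 <- c(runif(1, 1, 7), runif(1, 0.5, 1.5), runif(1, 1, 3))
    rbind(p0, p0 + c(0, 0, -1))
  }))
  grid <- grid_from_bbox(c(0, 0, 0), c(8, 2, 4), 0.325)
  sm0 <- strain_map(fibs, fibs, grid)
  ok <- !is.na(sm0$values)
  expect_true(any(ok))
  expect_true(all(abs(sm0$values[ok]) <= 1e-6))
  expect_true(all(sm0$values[ok] > -1))

  fibs2 <- fiber_set(lapply(fibs$fibers, function(f) {
    f[2, ] <- f[1, ] + 1.2 * (f[2, ] - f[1, ])
    f
  }))
  sm2 <- strain_map(fibs, fibs2, grid)
  ok2 <- !is.na(sm2$values)
  expect_equal(sm2$values[ok2], rep(0.2, sum(ok2)), tolerance = 1e-9)

  expect_error(strain_map(fibs, fiber_set(fibs$fibers[1:3]), grid),
               "index-paired")
})
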
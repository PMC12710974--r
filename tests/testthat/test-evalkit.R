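# Evaluation: absolute cosine similarity, region grouping, depth profiles.

unit_field <- function(grid, v) {
  m <- matrix(v, n_voxels(grid), 3, byrow = TRUE)
  orientation_field(grid, m / sqrt(sum(v^2)))
}

test_that("cosine similarity is 1 for equal fields, 0 for orthogonal, sign-invariant", {
  g <- vox_grid(c(0, 0, 0), 1, c(4, 4, 4))
  a <- unit_field(g, c(1, 0, 0))
  expect_true(all(cosine_similarity_map(a, a)$score == 1))
  b <- unit_field(g, c(0, 1, 0))
  expect_true(all(cosine_similarity_map(a, b)$score == 0))
  neg <- a; neg$vectors <- -neg$vectors
  expect_true(all(cosine_similarity_map(a, neg)$score == 1))
  # symmetry and bounds on random unit fields
  set.seed(2)
  mk <- function() {
    v <- matrix(rnorm(3 * n_voxels(g)), ncol = 3)
    orientation_field(g, v / sqrt(rowSums(v^2)))
  }
  r1 <- mk(); r2 <- mk()
  s12 <- cosine_similarity_map(r1, r2)$score
  s21 <- cosine_similarity_map(r2, r1)$score
  expect_equal(s12, s21)
  expect_true(all(s12 >= 0 & s12 <= 1))
  g2 <- vox_grid(c(0, 0, 0), 1, c(5, 4, 4))
  expect_error(cosine_similarity_map(r1, unit_field(g2, c(1, 0, 0))),
               "grid")
})

test_that("masks and empty voxels are respected", {
  g <- vox_grid(c(0, 0, 0), 1, c(3, 3, 3))
  a <- unit_field(g, c(1, 0, 0))
  b <- unit_field(g, c(1, 0, 0))
  b$vectors[5, ] <- NA
  mask <- rep(TRUE, 27); mask[7] <- FALSE
  s <- cosine_similarity_map(a, b, mask)$score
  expect_true(is.na(s[5]))
  expect_true(is.na(s[7]))
  expect_equal(sum(!is.na(s)), 25)
})

test_that("region scores aggregate exactly and support exclusions", {
  g <- vox_grid(c(0, 0, 0), 1, c(4, 1, 1))
  a <- unit_field(g, c(1, 0, 0))
  b <- a
  b$vectors <- rbind(c(1, 0, 0), c(0.6, 0.8, 0), c(0, 1, 0), c(0.8, 0.6, 0))
  sim <- cosine_similarity_map(a, b)
  parc <- c(1L, 1L, 2L, 2L)
  rs <- region_scores(sim, parc, exclude = 2L)
  expect_equal(rs$mean[rs$label == 1], mean(c(1, 0.6)))
  expect_equal(rs$mean[rs$label == 2], mean(c(0, 0.8)))
  expect_equal(rs$count, c(2L, 2L))
  expect_equal(attr(rs, "overall_mean"), mean(c(1, 0.6, 0, 0.8)))
  expect_equal(attr(rs, "overall_mean_excluding"), mean(c(1, 0.6)))
  expect_true(all(rs$mean >= rs$min & rs$mean <= rs$max))
  # labels with no scored voxels are omitted
  sim2 <- sim; sim2$score[3:4] <- NA
  rs2 <- region_scores(sim2, parc)
  expect_identical(rs2$label, 1L)
})

test_that("depth profile reproduces a constructed step", {
  g <- vox_grid(c(0.5, 0.5, 0.5), 1, c(4, 4, 6))
  # surface: the plane z = 6 (sampled densely)
  surf <- as.matrix(expand.grid(x = seq(0, 4, 0.25), y = seq(0, 4, 0.25),
                                z = 6))
  a <- unit_field(g, c(0, 0, 1))
  b <- a
  sim <- cosine_similarity_map(a, b)
  # step: score 1 for depth < 3, 0 deeper
  ctr <- voxel_centers(g)
  depth <- 6 - ctr[, 3]
  sim$score[depth >= 3] <- 0
  prof <- depth_profile(sim, surf, bin_width = 1, max_depth = 6)
  expect_equal(prof$mean, c(1, 1, 1, 0, 0, 0)[seq_len(nrow(prof))])
  # uniform score: flat profile
  sim2 <- cosine_similarity_map(a, b)
  prof2 <- depth_profile(sim2, surf, bin_width = 1, max_depth = 5)
  expect_true(all(prof2$mean == 1))
})
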
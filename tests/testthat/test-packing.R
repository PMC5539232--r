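# Force-bias ellipsoid packing: overlap estimation, contact certificates,
# periodic handling, determinism.

sphere <- function(center, r = 1)
  list(center = center, semi_axes = c(r, r, r), orientation = c(1, 0, 0, 0))

test_that("Monte-Carlo overlap volume matches closed forms", {
  # identical coincident unit spheres: the full volume
  v <- overlap_volume(sphere(c(0, 0, 0)), sphere(c(0, 0, 0)),
                      mc_samples = 50000)
  expect_equal(v, 4 * pi / 3, tolerance = 3 * 0.02)
  # unit spheres at distance 1: the lens 5 pi / 12
  v2 <- overlap_volume(sphere(c(0, 0, 0)), sphere(c(1, 0, 0)),
                       mc_samples = 200000)
  expect_lt(abs(v2 - 5 * pi / 12), 3 * 0.02)
  # beyond the summed max semi-axes: exactly zero via the contact pre-test
  expect_identical(overlap_volume(sphere(c(0, 0, 0)), sphere(c(2.5, 0, 0))),
                   0)
})

test_that("periodic minimum-image overlap matches the brute-force
           all-images oracle", {
  L <- 10
  e1 <- sphere(c(0.5, 5, 5), 1)
  e2 <- sphere(c(9.7, 5, 5), 1)     # straddles the x boundary
  v_mi <- overlap_volume(e1, e2, domain = L, mc_samples = 200000)
  # brute force: accumulate overlap with every image in free space
  v_img <- 0
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    img <- sphere(e2$center + L * c(sx, sy, sz), 1)
    v_img <- v_img + overlap_volume(e1, img, domain = 1e6,
                                    mc_samples = 200000)
  }
  expect_gt(v_mi, 0)                # they do overlap across the boundary
  expect_lt(abs(v_mi - v_img), 3 * 0.02)
})

test_that("population initialization follows the hematocrit arithmetic
           and is seed-deterministic", {
  ip <- init_population(25, 0.46, seed = 7)
  expect_identical(sum(ip$population$types == "RBC"), 101L)
  expect_identical(sum(ip$population$types == "PLT"), 10L)
  expect_true(all(abs(rowSums(ip$population$orientations^2) - 1) < 1e-12))
  expect_gte(ip$state$d_out, 1)
  ip2 <- init_population(25, 0.46, seed = 7)
  expect_identical(ip$population$centers, ip2$population$centers)
  expect_identical(ip$population$orientations, ip2$population$orientations)
  expect_error(init_population(25, 0.6), "not reachable")
})

test_that("a dilute system terminates almost immediately", {
  ip <- init_population(60, 0.005, seed = 3)
  pk <- pack_cells(ip$population, ip$state, max_iterations = 500)
  expect_true(pk$converged)
  expect_lt(pk$state$iteration, 200)
})

test_that("two overlapping spheres separate along the center line", {
  # hand-built two-particle population in a large box
  pop <- structure(list(
    centers = rbind(c(10, 10, 10), c(10.8, 10, 10)),
    orientations = rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
    types = c("RBC", "RBC"),
    semi_axes = list(RBC = c(1, 1, 1), PLT = c(1, 1, 1)),
    axes_matrix = rbind(c(1, 1, 1), c(1, 1, 1)),
    cell_volume = c(RBC = 4 * pi / 3, PLT = 4 * pi / 3),
    orientation_mode = "fixed", domain = rep(20, 3), seed = 5L),
    class = "ellipsoid_population")
  st <- structure(list(d_in = 0.4, d_out = 1.2, contraction_rate = 0.99,
                       iteration = 0L, domain = rep(20, 3)),
                  class = "packing_state")
  pk <- pack_cells(pop, st, max_iterations = 2000)
  expect_true(pk$converged)
  d <- sqrt(sum((pk$population$centers[1, ] - pk$population$centers[2, ])^2))
  expect_gte(d, 2 * (1 - 1e-9))
})

test_that("packing at 46% hematocrit converges overlap-free and is
           deterministic in the seed", {
  ip <- init_population(25, 0.46, seed = 11)
  pk <- pack_cells(ip$population, ip$state, max_iterations = 4000)
  expect_true(pk$converged)
  expect_gte(pk$state$d_in, 1)
  expect_gte(pk$hematocrit, 0.46)
  # zero overlapping pairs at scale 1, by the exact contact certificate
  din <- rbcdem:::.din_cpp(pk$population$centers,
                           pk$population$axes_matrix,
                           pk$population$orientations, ip$state$domain)
  expect_gte(din, 1)
  ip2 <- init_population(25, 0.46, seed = 11)
  pk2 <- pack_cells(ip2$population, ip2$state, max_iterations = 4000)
  expect_identical(pk$population$centers, pk2$population$centers)
})

test_that("positions round-trip through CSV and fixed orientations export
           as equal quaternions", {
  ip <- init_population(25, 0.2, seed = 9, orientation_mode = "fixed")
  path <- withr::local_tempfile(fileext = ".csv")
  export_positions(ip$population, path)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), length(ip$population$types))
  expect_true(all(df$qw == 1 & df$qx == 0))
  back <- read_positions(path, domain = 25)
  expect_equal(back$centers, unname(ip$population$centers),
               tolerance = 1e-6)
  expect_identical(back$types, ip$population$types)
})
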
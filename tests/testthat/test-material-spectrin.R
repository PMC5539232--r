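# Spectrin-link model: WLC energetics, repulsive calibration, analytic
# gradients against finite differences, dissipative forces.

test_that("WLC energy matches the closed form and its limits", {
  sp <- spectrin_params()
  # r = 0.5, l_m = 1.3 um, p = 7.5 nm: (1.3/(4*0.0075)) * 0.5/0.5 = 43.33
  expect_equal(wlc_energy(0.65, 0.5, sp), 1.3 / (4 * 0.0075) * 1,
               tolerance = 1e-9)
  expect_lt(wlc_energy(1e-8, 0.5, sp), 1e-6)      # zero-extension limit
  l <- seq(0.05, 1.29, by = 0.01)
  expect_true(all(diff(wlc_energy(l, 0.5, sp)) > 0))  # strictly increasing
  expect_error(wlc_energy(1.31, 0.5, sp), "extension limit")
})

test_that("C_q makes the equilateral lattice unit an in-plane energy
           minimum and scales as l0^3 at fixed extension ratio", {
  sp <- spectrin_params()
  # per-vertex unit cell of the triangular lattice: 3 edges + 2 faces
  E <- function(l, l0) 3 * wlc_energy(l, l0, sp) +
    2 * repulsive_coefficient(l0, sp) / (sqrt(3) / 4 * l^2)
  h <- 1e-7
  d0 <- (E(0.5 + h, 0.5) - E(0.5 - h, 0.5)) / (2 * h)
  dref <- (E(0.55, 0.5) - E(0.5, 0.5)) / 0.05   # scale of the gradient
  expect_lt(abs(d0 / dref), 1e-6)
  # positivity: 4 r0^2 - 9 r0 + 6 has no real roots
  for (x0 in c(1.5, 2.6, 4)) {
    spx <- spectrin_params(x0 = x0)
    expect_gt(repulsive_coefficient(0.5, spx), 0)
  }
  # doubling l0 at fixed r0: A_l0^2 ~ l0^4 over l_m ~ l0 -> x 8
  expect_equal(repulsive_coefficient(1.0, sp) /
                 repulsive_coefficient(0.5, sp), 8, tolerance = 1e-12)
})

test_that("reference configuration is force-free and the energy breakdown
           is consistent", {
  tmpl <- rbc_fixture()
  sp <- spectrin_params()
  f <- spectrin_forces(tmpl$mesh, tmpl$reference, params = sp)
  expect_lt(max(abs(f)), 1e-8)
  en <- spectrin_energy(tmpl$mesh, tmpl$reference, params = sp)
  expect_equal(en$total,
               en$U_inplane + en$U_bend + en$U_volume + en$U_area)
  expect_equal(en$U_bend, 0, tolerance = 1e-9)
  expect_equal(en$U_volume, 0, tolerance = 1e-9)
})

test_that("analytic forces are the exact gradient of the energy", {
  tmpl <- blob_fixture()
  pos <- tmpl$mesh$vertices *
    (1 + 0.01 * matrix(sin(seq_len(length(tmpl$mesh$vertices))), ncol = 3))
  for (variant in c("edge", "face")) {
    sp <- spectrin_params(inplane_repulsion = variant)
    f_an <- spectrin_forces(tmpl$mesh, tmpl$reference, pos, NULL, sp)
    h <- 1e-6
    U <- function(p)
      spectrin_energy(tmpl$mesh, tmpl$reference, p, sp)$total * sp$kBT
    g <- f_an * 0
    for (i in seq_len(nrow(pos))) for (j in 1:3) {
      pp <- pos; pp[i, j] <- pos[i, j] + h; up <- U(pp)
      pp[i, j] <- pos[i, j] - h
      g[i, j] <- -(up - U(pp)) / (2 * h)
    }
    expect_lt(max(abs(f_an - g)) / max(abs(g)), 1e-5)
    # compiled kernel agrees with the reference implementation
    f_cpp <- spectrin_forces(tmpl$mesh, tmpl$reference, pos, NULL, sp,
                             engine = "cpp")
    f_r <- spectrin_forces(tmpl$mesh, tmpl$reference, pos, NULL, sp,
                           engine = "r")
    expect_lt(max(abs(f_cpp - f_r)), 1e-10 * max(1, max(abs(f_r))))
  }
})

test_that("bending force response is sinusoidal: non-monotone with a peak
           near pi/2", {
  sp <- spectrin_params()
  # per-edge bending force magnitude ~ kappa_tilde * sin(theta - theta0)
  dth <- seq(0.1, pi - 0.1, by = 0.1)
  resp <- sp$kappa_tilde * sin(dth)
  expect_gt(max(resp), resp[length(resp)])      # decays past the peak
  expect_equal(dth[which.max(resp)], pi / 2, tolerance = 0.1)
})

test_that("membrane viscosity damps relative motion only", {
  tmpl <- blob_fixture()
  sp <- spectrin_params()
  pos <- tmpl$mesh$vertices
  # rigid translation velocity: no dissipative force
  v_rigid <- matrix(rep(c(0.1, -0.2, 0.05), each = nrow(pos)), ncol = 3)
  f0 <- spectrin_forces(tmpl$mesh, tmpl$reference, pos, NULL, sp)
  f1 <- spectrin_forces(tmpl$mesh, tmpl$reference, pos, v_rigid, sp)
  expect_lt(max(abs(f1 - f0)), 1e-9)
  # differential motion is damped
  set.seed(8)
  v_rand <- matrix(rnorm(length(pos), sd = 0.01), ncol = 3)
  f2 <- spectrin_forces(tmpl$mesh, tmpl$reference, pos, v_rand, sp)
  expect_lt(sum((f2 - f0) * v_rand), 0)         # dissipative power
})

test_that("bending prefactor options differ by the documented ratio", {
  a <- spectrin_params(bending_prefactor = "gompper-kroll")
  b <- spectrin_params(bending_prefactor = "two-thirds")
  expect_equal(a$kappa_tilde / b$kappa_tilde, (2 / sqrt(3)) / (2 / 3),
               tolerance = 1e-12)
})
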
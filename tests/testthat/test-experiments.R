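# Patch moduli, tweezer stretching, deformation index.

test_that("deformation index closed forms", {
  expect_equal(deformation_index(7.82, 7.82), 0)
  expect_equal(deformation_index(sqrt(3) * 5, 5), 0.5, tolerance = 1e-12)
  expect_gt(deformation_index(1e6, 1), 0.999999)
  expect_error(deformation_index(-1, 1))
})

test_that("Poisson ratio from the 2D isotropic relation", {
  expect_equal(poisson_from_moduli(27.82, 10.87), 27.82 / 21.74 - 1,
               tolerance = 1e-12)
  expect_equal(poisson_from_moduli(2, 1), 0)
  expect_equal(poisson_from_moduli(3, 1), 0.5)
})

test_that("patch moduli: linear in the stiffnesses and consistent between
           strain magnitudes", {
  p <- patch_fixture()
  pm <- patch_moduli(p)
  expect_true(all(c(pm$E_s, pm$mu, pm$K) > 0))
  expect_gt(pm$nu, -1); expect_lt(pm$nu, 1)

  # doubling every kappa doubles every modulus
  pm2 <- patch_moduli(p, new_material_params(kappa_l = 30, kappa_b = 160,
                                             kappa_a = 10, kappa_v = 40))
  expect_equal(pm2$E_s / pm$E_s, 2, tolerance = 1e-3)
  expect_equal(pm2$mu / pm$mu, 2, tolerance = 1e-3)
  expect_equal(pm2$K / pm$K, 2, tolerance = 1e-3)

  # halving the probe strain moves the estimates by < 2%
  pm_h <- patch_moduli(p, strain_magnitude = 0.005)
  expect_lt(abs(pm_h$E_s / pm$E_s - 1), 0.02)
  expect_lt(abs(pm_h$mu / pm$mu - 1), 0.02)
  expect_lt(abs(pm_h$K / pm$K - 1), 0.02)
})

test_that("patch moduli agree with the closed-form small-strain analysis
           of the hexagonal spring lattice", {
  # Independent oracle: linearizing the link force gives an edge spring
  # constant k = (kappa_l kBT / p)(1 + 1/tau_l^2)/L0; solving the 7-vertex
  # patch by hand yields E_s = 1.5 k (loaded-boundary reaction over the
  # 2 L0 width), mu = k/sqrt(3) and K = 2k/sqrt(3) + (2/sqrt(3)) c_a with
  # c_a = (kappa_a kBT / L0)(1 + 1/tau_a^2) the area-force coefficient.
  p <- patch_fixture()
  pm <- patch_moduli(p)
  k <- (15 * kBT_pN_um / 0.0075) * (1 + 1 / 9) / 0.5
  c_a <- (5 * kBT_pN_um / 0.5) * (1 + 1 / 0.09)
  expect_equal(pm$mu, k / sqrt(3), tolerance = 0.01)
  expect_equal(pm$K, 2 * k / sqrt(3) + 2 * c_a / sqrt(3), tolerance = 0.01)
  # E_s carries a small positive area-force correction above 1.5 k
  expect_gt(pm$E_s, 1.5 * k * 0.999)
  expect_lt(pm$E_s, 1.5 * k * 1.03)
})

test_that("patch moduli are invariant under rigid rotation of the patch
           about its normal", {
  p <- patch_fixture()
  ang <- 0.37
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  vr <- p$mesh$vertices %*% R
  pr <- list(mesh = tri_mesh(vr, p$mesh$faces))
  pr$reference <- reference_geometry(pr$mesh)
  pm0 <- patch_moduli(p)
  # the in-plane load axes rotate with the patch only through the lattice
  # anisotropy, which is third order; the virial moduli match closely
  pm1 <- patch_moduli(pr)
  expect_equal(pm1$mu, pm0$mu, tolerance = 0.02)
  expect_equal(pm1$K, pm0$K, tolerance = 1e-6)
})

test_that("tweezer stretch: no load reproduces the template, and the
           response is monotone in force", {
  tmpl <- rbc_fixture()
  ts <- tweezer_stretch(tmpl, forces = c(0, 50, 100, 150),
                        config = relaxation_config(force_tolerance = 0.1,
                                                   max_steps = 30000L))
  expect_true(all(ts$converged))
  expect_equal(ts$axial_diameter[1], 8, tolerance = 0.02)
  expect_equal(ts$transverse_diameter[1], 8, tolerance = 0.02)
  expect_true(all(diff(ts$axial_diameter) > 0))
  expect_true(all(diff(ts$transverse_diameter) < 0))
})

test_that("tweezer result is robust to the contact-area choice", {
  tmpl <- rbc_fixture()
  cfg <- relaxation_config(force_tolerance = 0.1, max_steps = 30000L)
  a <- tweezer_stretch(tmpl, forces = 100, contact_fraction = 0.05,
                       config = cfg)
  b <- tweezer_stretch(tmpl, forces = 100, contact_fraction = 0.10,
                       config = cfg)
  expect_lt(abs(b$axial_diameter / a$axial_diameter - 1), 0.05)
  expect_lt(abs(b$transverse_diameter / a$transverse_diameter - 1), 0.05)
})
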
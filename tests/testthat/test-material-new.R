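# Scalar response laws and force assembly of the strain-limited model.
# Expected values for the response laws were frozen from independent
# arithmetic evaluation of the printed formulas with kappa in units of
# k_B T = 4.141e-3 pN um, p = 7.5 nm, L0 = 0.5 um.

test_that("link force response matches the frozen oracle values", {
  expect_equal(link_force_magnitude(0), 0)
  expect_equal(link_force_magnitude(0.1), -0.9203246, tolerance = 1e-6)
  # odd and strictly monotone (in magnitude) up to the pole
  dL <- seq(0.05, 2.9, by = 0.05)
  expect_equal(link_force_magnitude(-dL), -link_force_magnitude(dL))
  expect_true(all(diff(-link_force_magnitude(dL)) > 0))
  expect_error(link_force_magnitude(3.0), "diverging link strain")
  expect_error(link_force_magnitude(3.2), "diverging link strain")
})

test_that("bending force response matches the frozen oracle values", {
  expect_equal(bending_force_magnitude(0, 0.5), 0)
  expect_equal(bending_force_magnitude(0.1, 0.5), -0.3170778,
               tolerance = 1e-6)
  th <- seq(0.01, pi / 6 - 0.01, by = 0.01)
  expect_equal(bending_force_magnitude(-th, 0.5),
               -bending_force_magnitude(th, 0.5))
  expect_true(all(diff(-bending_force_magnitude(th, 0.5)) > 0))
  expect_error(bending_force_magnitude(pi / 6, 0.5), "diverging bending")
})

test_that("area force response matches the frozen oracle values", {
  expect_equal(area_force_magnitude(0, 0.5), 0)
  expect_equal(area_force_magnitude(0.05, 0.5), -0.02573336,
               tolerance = 1e-6)
  dA <- seq(0.01, 0.29, by = 0.01)
  expect_true(all(diff(area_force_magnitude(dA, 0.5)) < 0))  # decreasing
  expect_error(area_force_magnitude(0.3, 0.5), "diverging area")
})

test_that("volume force response matches the frozen oracle values and has
           no unit constant in its bracket", {
  expect_equal(volume_force_magnitude(0, 0.5), 0)
  expect_equal(volume_force_magnitude(0.005, 0.5), -11.04267,
               tolerance = 1e-5)
  dV <- seq(0.0005, 0.009, by = 0.0005)
  expect_equal(volume_force_magnitude(-dV, 0.5),
               -volume_force_magnitude(dV, 0.5))
  expect_error(volume_force_magnitude(0.01, 0.5), "diverging volume")
})

test_that("undeformed template carries no force", {
  tmpl <- rbc_fixture()
  f <- accumulate_forces(tmpl$mesh, tmpl$reference)
  expect_lt(max(abs(f)), 1e-10)
  p <- patch_fixture()
  expect_lt(max(abs(accumulate_forces(p$mesh, p$reference))), 1e-10)
})

test_that("compiled and reference assemblies agree for both bending
           variants", {
  tmpl <- blob_fixture()
  pos <- perturbed(tmpl$mesh, 0.004, seed = 11)
  for (bv in c("edge", "printed")) {
    pr <- new_material_params(bending_variant = bv)
    f_r <- accumulate_forces(tmpl$mesh, tmpl$reference, pos, pr,
                             engine = "r")
    f_c <- accumulate_forces(tmpl$mesh, tmpl$reference, pos, pr,
                             engine = "cpp")
    expect_lt(max(abs(f_r - f_c)), 1e-10 * max(1, max(abs(f_r))))
  }
})

test_that("force distribution conserves linear momentum", {
  tmpl <- rbc_fixture()
  pos <- perturbed(tmpl$mesh, 0.003, seed = 2)
  br <- accumulate_forces(tmpl$mesh, tmpl$reference, pos, breakdown = TRUE,
                          engine = "r")
  # link and bending cancel per element algebraically
  expect_lt(max(abs(colSums(br$link))), 1e-10)
  expect_lt(max(abs(colSums(br$bending))), 1e-10)
  # area and volume sum over the closed surface to (numerically) zero
  expect_lt(max(abs(colSums(br$area))), 1e-6)
  expect_lt(max(abs(colSums(br$volume))), 1e-6)
})

test_that("uniform inflation produces an inward volume-force flux on
           every face", {
  tmpl <- rbc_fixture()
  pos <- tmpl$mesh$vertices * 1.002        # dV ~ 0.6%
  br <- accumulate_forces(tmpl$mesh, tmpl$reference, pos,
                          breakdown = TRUE, engine = "r")
  st <- br$strain
  # volume contribution on each face points against the outward normal
  per_face <- rowSums(st$n_k * st$n_k)     # 1 by construction
  Fv <- volume_force_magnitude(st$dV, tmpl$reference$L0_mean)
  expect_lt(Fv, 0)
  flux <- (Fv * st$S_j / st$S_avg) * per_face
  expect_true(all(flux < 0))
})

test_that("forces are rotationally equivariant", {
  tmpl <- blob_fixture()
  pos <- perturbed(tmpl$mesh, 0.004, seed = 5)
  R <- random_rotation(9)
  f1 <- accumulate_forces(tmpl$mesh, tmpl$reference, pos)
  f2 <- accumulate_forces(tmpl$mesh, tmpl$reference, pos %*% R)
  expect_lt(max(abs(f1 %*% R - f2)), 1e-9 * max(abs(f1)))
})

test_that("strain errors carry element ids and strain values", {
  tmpl <- blob_fixture()
  pos <- tmpl$mesh$vertices
  pos[1, ] <- pos[1, ] * 5                 # blows up adjacent links
  expect_error(accumulate_forces(tmpl$mesh, tmpl$reference, pos),
               "diverging link strain at element")
})

test_that("platelet parameters scale the in-plane stiffnesses tenfold", {
  plt <- plt_material_params()
  expect_equal(link_force_magnitude(0.1, plt),
               10 * link_force_magnitude(0.1), tolerance = 1e-12)
  # volume stiffness is not scaled
  expect_equal(volume_force_magnitude(0.005, 0.5, plt),
               volume_force_magnitude(0.005, 0.5), tolerance = 1e-12)
})
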
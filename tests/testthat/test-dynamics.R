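# Time integration and quasi-static relaxation.

test_that("zero forces and velocities leave the state unchanged", {
  tmpl <- blob_fixture()
  st <- cell_state(tmpl$mesh$vertices)
  cfg <- relaxation_config(dt = 1e-4, drag_coefficient = 1)
  st2 <- dem_step(st, tmpl$mesh, tmpl$reference, new_material_params(),
                  config = cfg)
  expect_equal(st2$positions, st$positions, tolerance = 1e-12)
  expect_equal(st2$velocities, st$velocities, tolerance = 1e-12)
})

test_that("a dragged vertex under constant force reaches terminal
           velocity F/c", {
  # single free vertex: a degenerate one-triangle patch with the others
  # pinned, and stiffness switched off via a zero external-only system
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   matrix(c(1L, 2L, 3L), 1))
  ref <- reference_geometry(mesh)
  eps_model <- new_material_params(kappa_l = 1e-12, kappa_b = 1e-12,
                                  kappa_a = 1e-12, kappa_v = 1e-12)
  ext <- rbind(c(2, 0, 0), c(0, 0, 0), c(0, 0, 0))
  fixed <- matrix(FALSE, 3, 3); fixed[2:3, ] <- TRUE
  cdrag <- 50; m <- 1e-4; dt <- 1e-4     # m/(c dt) = 0.02: overdamped
  cfg <- relaxation_config(dt = dt, vertex_mass = m,
                           drag_coefficient = cdrag,
                           max_displacement_per_step = 1)
  st <- cell_state(mesh$vertices)
  for (i in 1:400)
    st <- dem_step(st, mesh, ref, eps_model, ext, cfg, fixed)
  expect_equal(st$velocities[1, 1], 2 / cdrag, tolerance = 0.01)
})

test_that("relaxation recovers the reference after a uniform stretch", {
  tmpl <- rbc_fixture()
  st <- cell_state(tmpl$mesh$vertices * 1.003)
  r <- relax(st, tmpl$mesh, tmpl$reference, new_material_params(),
             config = relaxation_config(force_tolerance = 5e-3,
                                        max_steps = 20000L))
  expect_true(r$converged)
  expect_lt(max(abs(r$state$positions - tmpl$mesh$vertices)), 0.01)
  # volume restored well inside the incompressibility band
  dv <- mesh_volume(tmpl$mesh, r$state$positions) / tmpl$reference$V0 - 1
  expect_lt(abs(dv), 0.01)
})

test_that("spectrin relaxation returns to the reference and decreases the
           energy monotonically under plain damped stepping", {
  tmpl <- rbc_fixture()
  sp <- spectrin_params()
  st <- cell_state(tmpl$mesh$vertices * 1.01)
  r <- relax(st, tmpl$mesh, tmpl$reference, sp,
             config = relaxation_config(force_tolerance = 1e-3))
  expect_true(r$converged)
  expect_lt(max(abs(r$state$positions - tmpl$mesh$vertices)), 0.01)

  # the explicit damped integrator dissipates energy step by step
  blob <- blob_fixture()
  st <- cell_state(perturbed(blob$mesh, 0.005, seed = 3))
  cfg <- relaxation_config(dt = 2e-5, vertex_mass = 1e-3,
                           drag_coefficient = 2)
  en <- numeric(30)
  for (i in seq_along(en)) {
    st <- dem_step(st, blob$mesh, blob$reference, sp, config = cfg)
    en[i] <- spectrin_energy(blob$mesh, blob$reference, st$positions,
                             sp)$total
  }
  expect_true(all(diff(en) <= 1e-8))
})

test_that("relaxation starting at the reference converges immediately", {
  tmpl <- blob_fixture()
  r <- relax(cell_state(tmpl$mesh$vertices), tmpl$mesh, tmpl$reference,
             new_material_params())
  expect_true(r$converged)
  expect_identical(r$steps, 0L)
})

test_that("pinned vertices stay put to machine precision", {
  tmpl <- blob_fixture()
  fixed <- matrix(FALSE, nrow(tmpl$mesh$vertices), 3)
  fixed[1:5, ] <- TRUE
  st <- cell_state(perturbed(tmpl$mesh, 0.004, seed = 6))
  pinned0 <- st$positions[1:5, ]
  r <- relax(st, tmpl$mesh, tmpl$reference, new_material_params(),
             config = relaxation_config(force_tolerance = 0.05),
             fixed = fixed)
  expect_identical(r$state$positions[1:5, ], pinned0)
})

test_that("relaxation is deterministic", {
  tmpl <- blob_fixture()
  st <- cell_state(perturbed(tmpl$mesh, 0.004, seed = 7))
  r1 <- relax(st, tmpl$mesh, tmpl$reference, new_material_params(),
              config = relaxation_config(force_tolerance = 0.05))
  r2 <- relax(st, tmpl$mesh, tmpl$reference, new_material_params(),
              config = relaxation_config(force_tolerance = 0.05))
  expect_identical(r1$state$positions, r2$state$positions)
  expect_identical(r1$steps, r2$steps)
})
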
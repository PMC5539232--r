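# Mesh construction, topology and discrete geometry.

test_that("icosphere subdivision counts follow 10*4^n + 2", {
  for (n in 0:3) {
    m <- make_icosphere(n)
    expect_identical(nrow(m$vertices), as.integer(10 * 4^n + 2))
    expect_identical(nrow(m$edges), as.integer(30 * 4^n))
    expect_identical(nrow(m$faces), as.integer(20 * 4^n))
    # Euler characteristic of the sphere
    expect_identical(nrow(m$vertices) - nrow(m$edges) + nrow(m$faces), 2L)
    expect_true(m$closed)
    expect_gt(mesh_volume(m), 0)   # outward orientation
  }
})

test_that("icosphere volume approaches the analytic sphere", {
  m <- make_icosphere(3)
  expect_lt(abs(mesh_volume(m) / (4 * pi / 3) - 1), 0.01)
})

test_that("mesh volume is translation invariant, rotation invariant and
           orientation sensitive", {
  m <- make_icosphere(1)
  v0 <- mesh_volume(m)
  shifted <- m$vertices + matrix(c(3, -2, 7), nrow(m$vertices), 3,
                                 byrow = TRUE)
  expect_equal(mesh_volume(m, shifted), v0, tolerance = 1e-12)
  R <- random_rotation()
  expect_equal(mesh_volume(m, m$vertices %*% R), v0, tolerance = 1e-9)
  flipped <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), -v0, tolerance = 1e-12)
  # area invariance under rigid motion
  expect_equal(mesh_area(tri_mesh(shifted, m$faces)), mesh_area(m),
               tolerance = 1e-9)
})

test_that("open meshes refuse a volume", {
  p <- patch_fixture()
  expect_error(mesh_volume(p$mesh), "closed")
})

test_that("dihedral angles: flat patch zero, icosahedron closed form,
           mirror symmetric magnitudes", {
  p <- patch_fixture()
  expect_equal(unname(dihedral_angles(p$mesh)), rep(0, 6),
               tolerance = 1e-12)
  ico <- make_icosphere(0)
  th <- dihedral_angles(ico)
  # fold angle = pi - interior dihedral of the icosahedron
  expect_equal(unname(th), rep(pi - acos(-sqrt(5) / 3), 30),
               tolerance = 1e-9)
  mir <- tri_mesh(ico$vertices %*% diag(c(-1, 1, 1)),
                  ico$faces[, c(1, 3, 2)])
  expect_equal(sort(abs(dihedral_angles(mir))), sort(abs(th)),
               tolerance = 1e-9)
})

test_that("RBC template reproduces the membrane discretization", {
  tmpl <- rbc_fixture()
  m <- tmpl$mesh
  expect_identical(nrow(m$vertices), 642L)
  expect_identical(nrow(m$edges), 1920L)
  expect_identical(nrow(m$faces), 1280L)
  expect_true(m$closed)
  expect_equal(mesh_volume(m), 71, tolerance = 0.01)
  # in-plane extent set by the diameter, up to one edge length
  expect_lt(abs(diff(range(m$vertices[, 1])) - 8), tmpl$reference$L0_mean)
  # mean edge length near the working resolution
  expect_equal(tmpl$reference$L0_mean, 0.5, tolerance = 0.1)
})

test_that("template volume calibration covers the physiologic range", {
  for (tv in c(60, 100)) {
    tm <- make_rbc_template(cell_template_spec(target_volume = tv),
                            smoothing_steps = 10L)
    expect_lt(abs(mesh_volume(tm$mesh) / tv - 1), 0.01)
  }
  expect_error(
    make_rbc_template(cell_template_spec(target_volume = 1e4)),
    "unreachable")
})

test_that("hexagonal patch has the textbook geometry", {
  p <- make_patch(0.5)
  expect_identical(nrow(p$mesh$vertices), 7L)
  expect_identical(nrow(p$mesh$edges), 12L)
  expect_identical(nrow(p$mesh$faces), 6L)
  expect_false(p$mesh$closed)
  expect_equal(p$reference$A0, 6 * sqrt(3) / 4 * 0.25, tolerance = 1e-12)
  border <- is.na(p$mesh$edge_faces[, 2])
  expect_identical(sum(border), 6L)       # 6 boundary, 6 interior edges
  expect_equal(unname(p$reference$theta0[!border]), rep(0, 6))
  expect_equal(unname(p$reference$L0), rep(0.5, 12), tolerance = 1e-12)
})

test_that("reference geometry is positive and consistent", {
  tmpl <- blob_fixture()
  rg <- tmpl$reference
  expect_true(all(rg$L0 > 0))
  expect_true(all(rg$A0_k > 0))
  expect_equal(rg$A0, sum(rg$A0_k))
  expect_equal(rg$V0, mesh_volume(tmpl$mesh))
})
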
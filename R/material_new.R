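# The four-force constitutive membrane model: strain-limited link, bending,
# local-area and volume responses with poles at the tau limits.
#
# Sign convention: the scalar response functions return the signed value of
# the printed constitutive laws (negative under positive strain, i.e. the
# scalar *opposes* the strain).  The force assembler applies each scalar
# along the restoring direction of its element, so a stretched link
# contracts, an over-convex fold flattens, an expanded face shrinks and an
# inflated cell deflates.

#' Parameters of the strain-limited constitutive model
#'
#' Stiffnesses are in units of k_B T ([kBT_pN_um]); the strain limits tau
#' are the poles of the diverging force terms.  `stiffness_scale`
#' multiplies kappa_l, kappa_a and kappa_b (10 for platelets).
#'
#' @param kappa_l link stiffness, k_B T.
#' @param kappa_b bending stiffness, k_B T.
#' @param kappa_a local-area stiffness, k_B T.
#' @param kappa_v volume stiffness, k_B T.
#' @param tau_l link strain limit (dimensionless).
#' @param tau_b bending angle limit, rad.
#' @param tau_a area strain limit (dimensionless).
#' @param tau_v volume strain limit (dimensionless).
#' @param p spectrin persistence length, um.
#' @param stiffness_scale multiplier on kappa_l, kappa_a, kappa_b
#'   (1 for RBC, 10 for PLT).
#' @param bending_variant which two stencil vertices receive the per-face
#'   normal pulls in the bending distribution: `"edge"` assigns them to the
#'   two edge endpoints (symmetric), `"printed"` to one edge endpoint and
#'   the first apex (the literal index reading).
#' @return list of class `new_material_params`.
#' @export
new_material_params <- function(kappa_l = 15, kappa_b = 80, kappa_a = 5,
                                kappa_v = 20, tau_l = 3.0, tau_b = pi / 6,
                                tau_a = 0.3, tau_v = 0.01, p = 0.0075,
                                stiffness_scale = 1,
                                bending_variant = c("edge", "printed")) {
  stopifnot(kappa_l > 0, kappa_b > 0, kappa_a > 0, kappa_v > 0,
            tau_l > 0, tau_b > 0, tau_a > 0, tau_v > 0, p > 0,
            stiffness_scale > 0)
  structure(list(kappa_l = kappa_l, kappa_b = kappa_b, kappa_a = kappa_a,
                 kappa_v = kappa_v, tau_l = tau_l, tau_b = tau_b,
                 tau_a = tau_a, tau_v = tau_v, p = p,
                 stiffness_scale = stiffness_scale,
                 bending_variant = match.arg(bending_variant)),
            class = c("new_material_params", "membrane_model"))
}

#' Platelet parameter set
#'
#' Same constitutive laws with kappa_l, kappa_a, kappa_b multiplied by 10.
#' @param ... overrides passed to [new_material_params()].
#' @export
plt_material_params <- function(...) {
  new_material_params(stiffness_scale = 10, ...)
}

check_strain <- function(x, tau, what, pole_guard = 1e-6) {
  bad <- which(!is.finite(x) | abs(x) >= tau - pole_guard)
  if (length(bad))
    stop(sprintf(
      "diverging %s strain at element(s) %s: |strain| = %.6g, limit tau = %g",
      what, paste(utils::head(bad, 5L), collapse = ", "),
      max(abs(x[bad])), tau), call. = FALSE)
  invisible(x)
}

#' Link (in-plane) force response
#'
#' F = -(kappa_l dL / p) \[1 + 1/(tau_l^2 - dL^2)\]: linear for small normal
#' strain, diverging as the strain approaches the limit tau_l.
#'
#' @param dL per-edge normal strain (L - L0)/L0.
#' @param params a [new_material_params()].
#' @return signed force, pN (negative = opposing extension).
#' @export
link_force_magnitude <- function(dL, params = new_material_params()) {
  check_strain(dL, params$tau_l, "link")
  kl <- params$kappa_l * params$stiffness_scale * kBT_pN_um
  -(kl * dL / params$p) * (1 + 1 / (params$tau_l^2 - dL^2))
}

#' Bending force response
#'
#' F = -(kappa_b dtheta / L0) \[1 + 1/(tau_b^2 - dtheta^2)\] per interior
#' edge, where dtheta is the deviation of the dihedral angle from its
#' reference value.
#'
#' @param dtheta theta - theta0, rad.
#' @param L0_mean mean edge length of the template, um.
#' @inheritParams link_force_magnitude
#' @return signed force, pN.
#' @export
bending_force_magnitude <- function(dtheta, L0_mean,
                                    params = new_material_params()) {
  check_strain(dtheta, params$tau_b, "bending")
  kb <- params$kappa_b * params$stiffness_scale * kBT_pN_um
  -(kb * dtheta / L0_mean) * (1 + 1 / (params$tau_b^2 - dtheta^2))
}

#' Local-area force response
#'
#' F = -(kappa_a dA / L0) \[1 + 1/(tau_a^2 - dA^2)\] per face; the assembled
#' vertex force scales this with the centroid offset vector, so the scalar
#' has units pN/um.
#'
#' @param dA per-face area strain (A_k - A0_k)/A0_k.
#' @inheritParams bending_force_magnitude
#' @return signed coefficient, pN/um.
#' @export
area_force_magnitude <- function(dA, L0_mean,
                                 params = new_material_params()) {
  check_strain(dA, params$tau_a, "area")
  ka <- params$kappa_a * params$stiffness_scale * kBT_pN_um
  -(ka * dA / L0_mean) * (1 + 1 / (params$tau_a^2 - dA^2))
}

#' Volume force response
#'
#' F = -(kappa_v dV / L0) \[1/(tau_v^2 - dV^2)\]: the single global term,
#' without the leading unity of the other three responses, enforcing
#' quasi-incompressibility.
#'
#' @param dV global volume strain (V - V0)/V0.
#' @inheritParams bending_force_magnitude
#' @return signed force, pN.
#' @export
volume_force_magnitude <- function(dV, L0_mean,
                                   params = new_material_params()) {
  check_strain(dV, params$tau_v, "volume")
  kv <- params$kappa_v * kBT_pN_um
  -(kv * dV / L0_mean) * (1 / (params$tau_v^2 - dV^2))
}

#' Strain state of a deformed membrane
#'
#' All strain measures the constitutive model consumes, relative to the
#' reference geometry.
#'
#' @param mesh a [tri_mesh()].
#' @param reference the matching [reference_geometry()].
#' @param positions current vertex positions (defaults to the mesh's).
#' @return list of class `strain_state` with `dL` (per edge), `dtheta`
#'   (per edge, `NA` on borders), `dA` (per face), `dV` (scalar, `NA` for
#'   open meshes), `S_j` (face areas), `S_avg`, `C_k` (face centroids) and
#'   `n_k` (outward unit normals).
#' @export
strain_state <- function(mesh, reference, positions = mesh$vertices) {
  L <- row_norms(positions[mesh$edges[, 2L], , drop = FALSE] -
                 positions[mesh$edges[, 1L], , drop = FALSE])
  dL <- (L - reference$L0) / reference$L0
  fa <- face_normals_areas(positions, mesh$faces)
  dtheta <- rep(NA_real_, nrow(mesh$edges))
  interior <- which(!is.na(mesh$edge_faces[, 1L]) &
                    !is.na(mesh$edge_faces[, 2L]))
  dtheta[interior] <-
    dihedral_angles_interior(mesh, positions, interior) -
    reference$theta0[interior]
  dA <- (fa$areas - reference$A0_k) / reference$A0_k
  dV <- if (mesh$closed)
    (mesh_volume(mesh, positions) - reference$V0) / reference$V0
  else NA_real_
  structure(list(dL = dL, dtheta = dtheta, dA = dA, dV = dV,
                 S_j = fa$areas, S_avg = mean(fa$areas),
                 C_k = fa$centroids, n_k = fa$normals),
            class = "strain_state")
}

# scatter-add rows of `val` (k x 3) into rows `idx` of an n x 3 accumulator
scatter_add3 <- function(acc, idx, val) {
  s <- rowsum(val, idx)
  rows <- as.integer(rownames(s))
  acc[rows, ] <- acc[rows, , drop = FALSE] + s
  acc
}

#' Assemble per-vertex forces of the strain-limited model
#'
#' Computes the strain state and distributes the four force types onto the
#' mesh vertices: link forces along edges (equal and opposite on the two
#' endpoints); bending forces on the four-vertex stencil of each interior
#' edge (two vertices pushed along the face normals, the other two along
#' the mean normal, summing to zero per edge); area forces along the
#' un-normalized centroid offset vectors of each face; volume forces along
#' the face normals weighted by the relative face area (skipped for open
#' meshes, where no volume is defined).
#'
#' @inheritParams strain_state
#' @param params a [new_material_params()].
#' @param breakdown if `TRUE`, also return the four per-type force arrays.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (the reference
#'   implementation below; also used for `breakdown`).  Both compute the
#'   same assembly and are cross-checked in the test suite.
#' @return n x 3 matrix of forces, pN (or a list when `breakdown = TRUE`).
#' @export
accumulate_forces <- function(mesh, reference, positions = mesh$vertices,
                              params = new_material_params(),
                              breakdown = FALSE,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp" && !breakdown)
    return(.forces_new_cpp(positions, mesh$cpp, unclass(reference),
                           c(unclass(params), list(kBT = kBT_pN_um))))
  st <- strain_state(mesh, reference, positions)
  n <- nrow(positions)
  zero <- matrix(0, n, 3L)

  # --- link ---------------------------------------------------------------
  d <- positions[mesh$edges[, 2L], , drop = FALSE] -
       positions[mesh$edges[, 1L], , drop = FALSE]
  u <- d / row_norms(d)
  Fl <- link_force_magnitude(st$dL, params)
  f_link <- scatter_add3(zero, mesh$edges[, 1L], -Fl * u)
  f_link <- scatter_add3(f_link, mesh$edges[, 2L], Fl * u)

  # --- bending ------------------------------------------------------------
  interior <- which(!is.na(mesh$edge_faces[, 1L]) &
                    !is.na(mesh$edge_faces[, 2L]))
  f_bend <- zero
  if (length(interior)) {
    Fb <- bending_force_magnitude(st$dtheta[interior], reference$L0_mean,
                                  params)
    n1 <- st$n_k[mesh$edge_faces[interior, 1L], , drop = FALSE]
    n2 <- st$n_k[mesh$edge_faces[interior, 2L], , drop = FALSE]
    ap <- edge_apices(mesh)[interior, , drop = FALSE]
    # edge endpoints in face-1 traversal order (fixes which endpoint pairs
    # with which face normal)
    fwd <- mesh$edge_fwd[interior]
    ea <- ifelse(fwd, mesh$edges[interior, 1L], mesh$edges[interior, 2L])
    eb <- ifelse(fwd, mesh$edges[interior, 2L], mesh$edges[interior, 1L])
    # restoring orientation: for dtheta > 0 (over-convex, Fb < 0) the two
    # normal-pull vertices move inward, the remaining pair outward
    if (params$bending_variant == "edge") {
      v1 <- ea; v2 <- eb; v3 <- ap[, 1L]; v4 <- ap[, 2L]
    } else {                      # literal index reading of the stencil
      v1 <- ea; v2 <- ap[, 1L]; v3 <- eb; v4 <- ap[, 2L]
    }
    f_bend <- scatter_add3(f_bend, v1, Fb * n1)
    f_bend <- scatter_add3(f_bend, v2, Fb * n2)
    f_bend <- scatter_add3(f_bend, v3, -Fb * (n1 + n2) / 2)
    f_bend <- scatter_add3(f_bend, v4, -Fb * (n1 + n2) / 2)
  }

  # --- local area ---------------------------------------------------------
  Fa <- area_force_magnitude(st$dA, reference$L0_mean, params)
  f_area <- zero
  for (m in 1:3) {
    vm <- mesh$faces[, m]
    f_area <- scatter_add3(f_area, vm,
                           -Fa * (st$C_k - positions[vm, , drop = FALSE]))
  }

  # --- volume -------------------------------------------------------------
  f_vol <- zero
  if (mesh$closed) {
    Fv <- volume_force_magnitude(st$dV, reference$L0_mean, params)
    w <- Fv * st$S_j / st$S_avg
    for (m in 1:3)
      f_vol <- scatter_add3(f_vol, mesh$faces[, m], w * st$n_k)
  }

  total <- f_link + f_bend + f_area + f_vol
  if (breakdown)
    list(total = total, link = f_link, bending = f_bend,
         area = f_area, volume = f_vol, strain = st)
  else total
}
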
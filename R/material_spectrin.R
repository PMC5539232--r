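# Coarse-grained spectrin-link membrane model: worm-like-chain in-plane
# links with a per-face repulsive area term, cosine bending, global volume
# and global+local area conservation potentials, and a pairwise dissipative
# edge force standing in for membrane viscosity.  Conservative forces are
# exact analytic gradients of the free energy.

#' Parameters of the spectrin-link model
#'
#' @param kBT energy unit, pN um (default [kBT_pN_um]).
#' @param kappa bending constant, k_B T.
#' @param kV volume coefficient, k_B T/um^3.
#' @param kA global area coefficient, k_B T/um^2.
#' @param kAl local area coefficient, k_B T/um^2.
#' @param x0 maximum link extension ratio l_m/l_0.
#' @param p persistence length, um.
#' @param q repulsive-potential exponent in C_q/A^q.
#' @param eta_m membrane viscosity, Pa s.
#' @param bending_prefactor `"gompper-kroll"` uses kappa_tilde = 2 kappa /
#'   sqrt(3) (the coarse-graining of the cosine bending energy on a
#'   triangular lattice); `"two-thirds"` uses the literal 2 kappa / 3.
#' @param inplane_repulsion how the repulsive counterpart of the WLC
#'   attraction is realized.  `"edge"` (default) uses a per-edge power-law
#'   potential kp_i/l_i^2 with kp_i calibrated so every link is exactly
#'   force-free at its reference length -- the standard stress-free
#'   calibration of the coarse-grained source model, which makes any
#'   reference shape an exact equilibrium.  `"face"` uses the per-triangle
#'   potential C_q/A_k^q (see [repulsive_coefficient()]); it is an exact
#'   equilibrium only on uniform equilateral lattices and carries a small
#'   residual reference stress on irregular meshes.
#' @return list of class `spectrin_params`.
#' @export
spectrin_params <- function(kBT = kBT_pN_um, kappa = 100, kV = 6000,
                            kA = 5900, kAl = 100, x0 = 2.6, p = 0.0075,
                            q = 1, eta_m = 22e-3,
                            bending_prefactor = c("gompper-kroll",
                                                  "two-thirds"),
                            inplane_repulsion = c("edge", "face")) {
  stopifnot(kBT > 0, kappa > 0, kV >= 0, kA >= 0, kAl >= 0, x0 > 1, p > 0,
            q > 0, eta_m >= 0)
  bending_prefactor <- match.arg(bending_prefactor)
  kt <- if (bending_prefactor == "gompper-kroll") 2 / sqrt(3) else 2 / 3
  structure(list(kBT = kBT, kappa = kappa, kappa_tilde = kt * kappa,
                 kV = kV, kA = kA, kAl = kAl, x0 = x0, p = p, q = q,
                 eta_m = eta_m, bending_prefactor = bending_prefactor,
                 inplane_repulsion = match.arg(inplane_repulsion)),
            class = c("spectrin_params", "membrane_model"))
}

#' Worm-like-chain link energy
#'
#' U = (kBT l_m / 4p) (3r^2 - 2r^3)/(1 - r) with r = l/l_m, diverging at
#' the maximum link length l_m = x0 l0.
#'
#' @param l current link length, um (scalar or vector).
#' @param l0 equilibrium link length, um.
#' @param params a [spectrin_params()].
#' @return energy in units of k_B T.
#' @export
wlc_energy <- function(l, l0, params = spectrin_params()) {
  lm <- params$x0 * l0
  if (any(l <= 0) || any(l >= lm))
    stop("link length outside (0, l_m): WLC extension limit reached")
  r <- l / lm
  (lm / (4 * params$p)) * (3 * r^2 - 2 * r^3) / (1 - r)
}

# dU_WLC/dl in kBT/um: the WLC tension
wlc_tension <- function(l, l0, params) {
  lm <- params$x0 * l0
  r <- l / lm
  (1 / params$p) * (1 / (4 * (1 - r)^2) - 0.25 + r)
}

#' Repulsive per-face coefficient C_q
#'
#' The constant of the per-triangle repulsive potential C_q/A^q, chosen so
#' that the combined in-plane force vanishes at the reference geometry
#' (equilateral triangles of edge l0).
#'
#' @param l0 equilibrium link length, um.
#' @param params a [spectrin_params()].
#' @return C_q in k_B T um^(2q).
#' @export
repulsive_coefficient <- function(l0, params = spectrin_params()) {
  r0 <- 1 / params$x0
  if (r0 >= 1) stop("l0/l_m must be below 1")
  lm <- params$x0 * l0
  Al0 <- sqrt(3) * l0^2 / 4
  sqrt(3) * Al0^2 * (4 * r0^2 - 9 * r0 + 6) /
    (4 * params$p * lm * (1 - r0)^2)
}

#' Free-energy breakdown of the spectrin-link model
#'
#' @param mesh,reference mesh and reference geometry.
#' @param positions vertex positions (defaults to the mesh's).
#' @param params a [spectrin_params()].
#' @return list of class `spectrin_energy` with `U_inplane`, `U_bend`,
#'   `U_volume`, `U_area`, `total` in k_B T.  The dissipative contribution
#'   is not part of the conservative total.
#' @export
spectrin_energy <- function(mesh, reference, positions = mesh$vertices,
                            params = spectrin_params()) {
  l <- row_norms(positions[mesh$edges[, 2L], , drop = FALSE] -
                 positions[mesh$edges[, 1L], , drop = FALSE])
  U_wlc <- sum(wlc_energy(l, reference$L0, params))
  fa <- face_normals_areas(positions, mesh$faces)
  U_rep <- if (params$inplane_repulsion == "face")
    sum(face_Cq(mesh, reference, params) / fa$areas^params$q)
  else
    sum(edge_kp(reference, params) / l^2)
  interior <- which(!is.na(mesh$edge_faces[, 1L]) &
                    !is.na(mesh$edge_faces[, 2L]))
  th <- dihedral_angles_interior(mesh, positions, interior)
  U_bend <- params$kappa_tilde *
    sum(1 - cos(th - reference$theta0[interior]))
  U_volume <- if (mesh$closed) {
    V <- mesh_volume(mesh, positions)
    params$kV * (V - reference$V0)^2 / (2 * reference$V0)
  } else 0
  A <- sum(fa$areas)
  U_area <- params$kA * (A - reference$A0)^2 / (2 * reference$A0) +
    sum(params$kAl * (fa$areas - reference$A0_k)^2 / (2 * reference$A0_k))
  structure(list(U_inplane = U_wlc + U_rep, U_bend = U_bend,
                 U_volume = U_volume, U_area = U_area,
                 total = U_wlc + U_rep + U_bend + U_volume + U_area),
            class = "spectrin_energy")
}

# per-face repulsive coefficient from the face's reference area (the C_q
# formula evaluated at the equivalent equilateral edge length)
face_Cq <- function(mesh, reference, params) {
  l0_eq <- sqrt(reference$A0_k * 4 / sqrt(3))
  vapply(l0_eq, repulsive_coefficient, numeric(1), params = params)
}

# per-edge power-law coefficient (kBT um^2) making each link force-free at
# its reference length: d/dl [U_WLC + kp/l^2] = 0 at l = l0
edge_kp <- function(reference, params) {
  t0 <- wlc_tension(reference$L0, reference$L0, params)  # kBT/um, uniform
  t0 * reference$L0^3 / 2
}

# cross-product matrix action helpers (vectorized over rows)
vcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Signed-dihedral gradients for a set of interior edges.
# theta = atan2(Q, C) with C = n1.n2, Q = ((n1 x n2).e)/|e|, where n1, n2
# are the (non-unit) face normals and e the edge vector oriented as
# traversed by face 1 -- the same convention as dihedral_angles().
# Returns gradients w.r.t. the edge vertices (a, b) and the two apexes.
dihedral_gradients <- function(x1, x2, x3, x4) {
  # face1 = (x1, x2, x3) CCW, face2 = (x2, x1, x4) CCW
  e  <- x2 - x1
  n1 <- vcross(e, x3 - x1)
  n2 <- vcross(x1 - x2, x4 - x2)
  elen <- row_norms(e)
  C <- rowSums(n1 * n2)
  S <- rowSums(vcross(n1, n2) * e)
  Q <- S / elen
  denom <- C^2 + Q^2

  # Jacobian-transpose actions: n1 = u x v with u = x2-x1, v = x3-x1.
  #   d n1 = du x v + u x dv ; similarly for n2 = u2 x v2 with
  #   u2 = x1-x2, v2 = x4-x2.
  # For C = n1.n2:  grad_x C = Jn1(x)^T n2 + Jn2(x)^T n1, where
  #   (du x v)^T w = du . (v x w).
  v1 <- x3 - x1
  v2 <- x4 - x2
  gC <- function(which) {
    # contribution of dn1 in direction: du.(v1 x n2) with du = dx2 - dx1,
    # plus dv.(n2 x u) with dv = dx3 - dx1, u = e
    a_n1_u <- vcross(v1, n2)     # multiplies d(x2 - x1)
    a_n1_v <- vcross(n2, e)      # multiplies d(x3 - x1)
    a_n2_u <- vcross(v2, n1)     # multiplies d(x1 - x2)
    a_n2_v <- vcross(n1, -e)     # multiplies d(x4 - x2)
    switch(which,
      x1 = -a_n1_u - a_n1_v + a_n2_u,
      x2 =  a_n1_u - a_n2_u - a_n2_v,
      x3 =  a_n1_v,
      x4 =  a_n2_v)
  }
  m12 <- vcross(n1, n2)
  gS <- function(which) {
    b1 <- vcross(n2, e)          # dn1 . (n2 x e)
    w_n1_u <- vcross(v1, b1)
    w_n1_v <- vcross(b1, e)
    b2 <- vcross(e, n1)          # dn2 . (e x n1)
    w_n2_u <- vcross(v2, b2)
    w_n2_v <- vcross(b2, -e)
    switch(which,
      x1 = -w_n1_u - w_n1_v + w_n2_u - m12,
      x2 =  w_n1_u - w_n2_u - w_n2_v + m12,
      x3 =  w_n1_v,
      x4 =  w_n2_v)
  }
  ehat <- e / elen
  gQ <- function(which) {
    g <- gS(which) / elen
    if (which == "x1") g <- g + Q * ehat / elen
    if (which == "x2") g <- g - Q * ehat / elen
    g
  }
  grads <- lapply(c(x1 = "x1", x2 = "x2", x3 = "x3", x4 = "x4"),
                  function(w) (C * gQ(w) - Q * gC(w)) / denom)
  grads
}

#' Per-vertex forces of the spectrin-link model
#'
#' Analytic gradients of the total free energy (WLC links, per-face
#' repulsion, cosine bending, volume and area conservation) plus the
#' pairwise dissipative force -gamma_t v_mn on edge vertices that realizes
#' the membrane viscosity.
#'
#' @param mesh,reference mesh and reference geometry.
#' @param positions n x 3 vertex positions, um.
#' @param velocities n x 3 vertex velocities, um/us (zero if `NULL`).
#' @param params a [spectrin_params()].
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation); cross-checked in the test suite.
#' @return n x 3 matrix of forces, pN.
#' @export
spectrin_forces <- function(mesh, reference, positions = mesh$vertices,
                            velocities = NULL,
                            params = spectrin_params(),
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp")
    return(.forces_spectrin_cpp(positions, velocities, mesh$cpp,
                                unclass(reference), unclass(params)))
  n <- nrow(positions)
  f <- matrix(0, n, 3L)
  kBT <- params$kBT
  ea <- mesh$edges[, 1L]; eb <- mesh$edges[, 2L]

  # WLC tension along edges
  d <- positions[eb, , drop = FALSE] - positions[ea, , drop = FALSE]
  l <- row_norms(d)
  lm <- params$x0 * reference$L0
  if (any(l >= lm)) {
    bad <- which(l >= lm)
    stop(sprintf("WLC extension limit reached at edge(s) %s (l/lm = %.4g)",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 max(l[bad] / lm[bad])))
  }
  tens <- kBT * wlc_tension(l, reference$L0, params)   # pN
  if (params$inplane_repulsion == "edge")
    tens <- tens - kBT * 2 * edge_kp(reference, params) / l^3
  u <- d / l
  f <- scatter_add3(f, ea, tens * u)
  f <- scatter_add3(f, eb, -tens * u)

  # per-face repulsion C_q / A^q (when selected), local area conservation,
  # and the global area term, all through dU/dA_k
  fa <- face_normals_areas(positions, mesh$faces)
  A <- sum(fa$areas)
  dU_dAk <- kBT * (params$kAl * (fa$areas - reference$A0_k) /
                     reference$A0_k +
                   params$kA * (A - reference$A0) / reference$A0)
  if (params$inplane_repulsion == "face") {
    Cq <- face_Cq(mesh, reference, params)
    dU_dAk <- dU_dAk - kBT * params$q * Cq / fa$areas^(params$q + 1)
  }
  p1 <- positions[mesh$faces[, 1L], , drop = FALSE]
  p2 <- positions[mesh$faces[, 2L], , drop = FALSE]
  p3 <- positions[mesh$faces[, 3L], , drop = FALSE]
  # grad of face area w.r.t. each corner: 0.5 * nhat x opposite_edge
  gA1 <- 0.5 * vcross(fa$normals, p3 - p2)
  gA2 <- 0.5 * vcross(fa$normals, p1 - p3)
  gA3 <- 0.5 * vcross(fa$normals, p2 - p1)
  f <- scatter_add3(f, mesh$faces[, 1L], -dU_dAk * gA1)
  f <- scatter_add3(f, mesh$faces[, 2L], -dU_dAk * gA2)
  f <- scatter_add3(f, mesh$faces[, 3L], -dU_dAk * gA3)

  # volume conservation
  if (mesh$closed) {
    V <- mesh_volume(mesh, positions)
    dU_dV <- kBT * params$kV * (V - reference$V0) / reference$V0
    # grad_x V: for each face, d det/6 contributions
    gV1 <- vcross(p2, p3) / 6
    gV2 <- vcross(p3, p1) / 6
    gV3 <- vcross(p1, p2) / 6
    f <- scatter_add3(f, mesh$faces[, 1L], -dU_dV * gV1)
    f <- scatter_add3(f, mesh$faces[, 2L], -dU_dV * gV2)
    f <- scatter_add3(f, mesh$faces[, 3L], -dU_dV * gV3)
  }

  # bending: kappa_tilde * sum(1 - cos(theta - theta0))
  interior <- which(!is.na(mesh$edge_faces[, 1L]) &
                    !is.na(mesh$edge_faces[, 2L]))
  if (length(interior)) {
    a <- mesh$edges[interior, 1L]; b <- mesh$edges[interior, 2L]
    # orient edge as traversed by face 1 (same convention as
    # dihedral_angles) and pick apexes accordingly
    fwd <- mesh$edge_fwd[interior]
    aa <- ifelse(fwd, a, b); bb <- ifelse(fwd, b, a)
    ap <- edge_apices(mesh)[interior, , drop = FALSE]
    th <- dihedral_angles_interior(mesh, positions, interior)
    dUdth <- kBT * params$kappa_tilde *
      sin(th - reference$theta0[interior])
    g <- dihedral_gradients(positions[aa, , drop = FALSE],
                            positions[bb, , drop = FALSE],
                            positions[ap[, 1L], , drop = FALSE],
                            positions[ap[, 2L], , drop = FALSE])
    f <- scatter_add3(f, aa, -dUdth * g$x1)
    f <- scatter_add3(f, bb, -dUdth * g$x2)
    f <- scatter_add3(f, ap[, 1L], -dUdth * g$x3)
    f <- scatter_add3(f, ap[, 2L], -dUdth * g$x4)
  }

  # dissipative membrane-viscosity force on edges
  if (!is.null(velocities) && params$eta_m > 0 && any(velocities != 0)) {
    gamma_t <- sqrt(3) * params$eta_m * 1e6 * 1  # Pa s -> pN us/um^2, x 1 um
    vm <- velocities[ea, , drop = FALSE] - velocities[eb, , drop = FALSE]
    f <- scatter_add3(f, ea, -gamma_t * vm)
    f <- scatter_add3(f, eb, gamma_t * vm)
  }
  f
}
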
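# Single-cell and membrane-patch validation experiments: optical-tweezer
# stretching, hexagonal-patch moduli extraction, deformation index.

#' Optical-tweezer stretching of a cell template
#'
#' Reproduces the bead-stretching protocol: the vertex sets at the two
#' x-extremes whose area share reaches `contact_fraction` each (greedy
#' selection by descending |x|, per-vertex area = one third of the adjacent
#' face areas) receive +F/-F in equal per-vertex portions; the membrane is
#' relaxed to steady state and the axial (x) and transverse (max of y, z)
#' diameters are recorded.
#'
#' @param template list with `mesh` and `reference`
#'   (e.g. from [make_rbc_template()]).
#' @param model a membrane model parameter object.
#' @param forces numeric vector of total stretching forces, pN.
#' @param contact_fraction area fraction held by each bead (default 0.05).
#' @param config a [relaxation_config()].
#' @return data.frame with columns `force`, `axial_diameter`,
#'   `transverse_diameter`, `converged`, `residual`.
#' @export
tweezer_stretch <- function(template, model = new_material_params(),
                            forces = c(0, 50, 100, 150),
                            contact_fraction = 0.05,
                            config = relaxation_config()) {
  stopifnot(all(forces >= 0), contact_fraction > 0, contact_fraction < 0.5)
  mesh <- template$mesh; reference <- template$reference
  va <- vertex_areas(mesh)
  pick_end <- function(sgn) {
    ord <- order(sgn * mesh$vertices[, 1L], decreasing = TRUE)
    share <- cumsum(va[ord]) / sum(va)
    ord[seq_len(which(share >= contact_fraction)[1L])]
  }
  plus <- pick_end(+1); minus <- pick_end(-1)
  ord <- order(forces)            # ascending: warm-start each level from
  start <- mesh$vertices          # the previous relaxed state
  out <- vector("list", length(forces))
  for (i in ord) {
    FF <- forces[i]
    ext <- matrix(0, nrow(mesh$vertices), 3L)
    ext[plus, 1L] <- FF / length(plus)
    ext[minus, 1L] <- -FF / length(minus)
    r <- relax(cell_state(start), mesh, reference, model,
               external_forces = ext, config = config)
    start <- r$state$positions
    p <- r$state$positions
    out[[i]] <- data.frame(force = FF,
                           axial_diameter = diff(range(p[, 1L])),
                           transverse_diameter = max(diff(range(p[, 2L])),
                                                     diff(range(p[, 3L]))),
                           converged = r$converged, residual = r$residual)
  }
  do.call(rbind, out)
}

# per-vertex (barycentric lumped) area share, um^2
vertex_areas <- function(mesh) {
  ar <- face_normals_areas(mesh$vertices, mesh$faces)$areas
  va <- numeric(nrow(mesh$vertices))
  for (m in 1:3) {
    s <- rowsum(ar / 3, mesh$faces[, m])
    idx <- as.integer(rownames(s))
    va[idx] <- va[idx] + s
  }
  va
}

#' Poisson ratio from the 2D isotropic relation
#'
#' nu = E_s / (2 mu) - 1.  The alternative (K - mu)/(K + mu) is reported by
#' [patch_moduli()] for comparison.
#'
#' @param E_s surface Young modulus, uN/m.
#' @param mu surface shear modulus, uN/m.
#' @export
poisson_from_moduli <- function(E_s, mu) {
  stopifnot(E_s > 0, mu > 0)
  E_s / (2 * mu) - 1
}

#' Deformation index of a sheared cell
#'
#' DI = ((Dmax/D0)^2 - 1) / ((Dmax/D0)^2 + 1).
#'
#' @param D_max maximal diameter during deformation, um.
#' @param D0 undeformed diameter, um.
#' @export
deformation_index <- function(D_max, D0) {
  stopifnot(all(D_max > 0), all(D0 > 0))
  q <- (D_max / D0)^2
  (q - 1) / (q + 1)
}

# relax the patch under per-coordinate constraints and return the model
# forces at equilibrium (reaction at a fixed coordinate = -force)
patch_solve <- function(mesh, reference, model, positions, fixed, config) {
  r <- relax(cell_state(positions), mesh, reference, model,
             config = config, fixed = fixed)
  if (!r$converged)
    stop(sprintf("patch relaxation did not converge (residual %.3g pN)",
                 r$residual))
  list(positions = r$state$positions,
       forces = model_forces(mesh, reference, r$state$positions,
                             r$state$velocities * 0, model))
}

#' Elastic moduli of the hexagonal membrane patch
#'
#' Three quasi-static boundary-driven tests on the 7-vertex hexagonal patch
#' with the interior vertex relaxed, evaluated by central differences at
#' +/- `strain_magnitude`:
#'
#' * uniaxial stretching (boundary x imposed, boundary y and the interior
#'   free): E_s is the summed x-reaction of the loaded (x > 0) boundary
#'   vertices per unit patch width (the corner-to-corner width 2 L0),
#'   divided by the strain; the lateral contraction of the free boundary
#'   vertices gives the kinematic Poisson ratio.
#' * simple shear (boundary displaced by u_x = gamma y): mu is the
#'   tangential boundary traction per unit length, evaluated as the areal
#'   moment of the boundary reactions sum(R_x y)/A (exact for a uniform
#'   stress state), divided by gamma.
#' * isotropic dilation (boundary scaled radially): K is the radial
#'   boundary tension per unit length, evaluated as the mean in-plane
#'   normal stress sum(R . x)/(2 A), divided by the relative area change.
#'
#' The reported Poisson ratio is `poisson_from_moduli(E_s, mu)`.
#'
#' @param patch list with `mesh` and `reference` from [make_patch()].
#' @param model a membrane model parameter object.
#' @param strain_magnitude half-width of the central difference (default
#'   0.01, i.e. +/-1% strain).
#' @param config a [relaxation_config()].
#' @return list of class `patch_moduli` with `E_s`, `mu`, `K`, `nu`
#'   (uN/m and dimensionless), plus `nu_kinematic` and `nu_from_K` for the
#'   isotropy cross-checks.
#' @export
patch_moduli <- function(patch, model = new_material_params(),
                         strain_magnitude = 0.01,
                         config = relaxation_config(force_tolerance = 1e-6)) {
  stopifnot(strain_magnitude > 0, strain_magnitude < 0.1)
  mesh <- patch$mesh; reference <- patch$reference
  v0 <- mesh$vertices
  ring <- which(sqrt(rowSums(v0[, 1:2, drop = FALSE]^2)) > 1e-12)
  L0 <- reference$L0_mean
  A0 <- reference$A0
  width <- diff(range(v0[, 1L]))          # corner-to-corner width, 2 L0

  # --- uniaxial: boundary x imposed, boundary y free, z pinned ------------
  uni <- function(eps) {
    pos <- v0
    pos[ring, 1L] <- v0[ring, 1L] * (1 + eps)
    fixed <- matrix(FALSE, nrow(v0), 3L)
    fixed[ring, 1L] <- TRUE
    fixed[, 3L] <- TRUE                   # in-plane test
    sol <- patch_solve(mesh, reference, model, pos, fixed, config)
    loaded <- ring[v0[ring, 1L] > 1e-12]
    Tx <- -sum(sol$forces[loaded, 1L])    # reaction = -model force
    lat0 <- max(v0[ring, 2L]); lat <- max(sol$positions[ring, 2L])
    c(Tx = Tx, eps_y = (lat - lat0) / lat0)
  }
  up <- uni(strain_magnitude); dn <- uni(-strain_magnitude)
  E_s <- (up[["Tx"]] - dn[["Tx"]]) / (2 * strain_magnitude) / width
  nu_kin <- -(up[["eps_y"]] - dn[["eps_y"]]) / (2 * strain_magnitude)

  # --- simple shear: boundary pinned to u_x = gamma y ---------------------
  shear <- function(gam) {
    pos <- v0
    pos[ring, 1L] <- v0[ring, 1L] + gam * v0[ring, 2L]
    fixed <- matrix(FALSE, nrow(v0), 3L)
    fixed[ring, 1:2] <- TRUE
    fixed[, 3L] <- TRUE
    sol <- patch_solve(mesh, reference, model, pos, fixed, config)
    R <- -sol$forces[ring, , drop = FALSE]
    sum(R[, 1L] * sol$positions[ring, 2L]) / A0
  }
  mu <- (shear(strain_magnitude) - shear(-strain_magnitude)) /
    (2 * strain_magnitude)

  # --- isotropic dilation: boundary scaled radially -----------------------
  dila <- function(eps) {
    pos <- v0
    pos[ring, 1:2] <- v0[ring, 1:2] * (1 + eps)
    fixed <- matrix(FALSE, nrow(v0), 3L)
    fixed[ring, 1:2] <- TRUE
    fixed[, 3L] <- TRUE
    sol <- patch_solve(mesh, reference, model, pos, fixed, config)
    R <- -sol$forces[ring, , drop = FALSE]
    A <- sum(face_normals_areas(sol$positions, mesh$faces)$areas)
    c(sm = sum(R[, 1L] * sol$positions[ring, 1L] +
               R[, 2L] * sol$positions[ring, 2L]) / (2 * A0),
      dA = (A - A0) / A0)
  }
  up <- dila(strain_magnitude); dn <- dila(-strain_magnitude)
  K <- (up[["sm"]] - dn[["sm"]]) / (up[["dA"]] - dn[["dA"]])

  structure(list(E_s = unname(E_s), mu = unname(mu), K = unname(K),
                 nu = poisson_from_moduli(E_s, mu),
                 nu_kinematic = unname(nu_kin),
                 nu_from_K = unname((K - mu) / (K + mu))),
            class = "patch_moduli")
}

#' @export
print.patch_moduli <- function(x, ...) {
  cat(sprintf(
    "patch moduli: E_s = %.3f uN/m, mu = %.3f uN/m, K = %.3f uN/m, nu = %.3f\n",
    x$E_s, x$mu, x$K, x$nu))
  cat(sprintf("  (kinematic nu = %.3f, (K-mu)/(K+mu) = %.3f)\n",
              x$nu_kinematic, x$nu_from_K))
  invisible(x)
}
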
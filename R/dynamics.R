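# Damped explicit time integration and quasi-static relaxation of membrane
# vertices.  Steady states are force-balance states and therefore
# independent of the (artificial) mass, drag and time step used to reach
# them; the defaults put the integrator deep in the overdamped regime.

#' Kinematic state of a cell membrane
#'
#' @param positions n x 3 vertex positions, um.
#' @param velocities n x 3 velocities, um/us (default zero).
#' @param time elapsed time, us.
#' @return list of class `cell_state` with `positions`, `velocities`,
#'   `forces` (last accumulated, pN) and `time`.
#' @export
cell_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3L)
  stopifnot(all(dim(velocities) == dim(positions)))
  structure(list(positions = positions, velocities = velocities,
                 forces = matrix(0, nrow(positions), 3L), time = time),
            class = "cell_state")
}

#' Integrator settings for quasi-static relaxation
#'
#' @param dt time step, us.  If `NULL`, estimated from the stiffest link of
#'   the model as dt = 0.2 sqrt(m / k_max).
#' @param vertex_mass artificial vertex mass, pg.
#' @param drag_coefficient per-vertex drag c, pN us/um.  If `NULL`, chosen
#'   as 2 sqrt(m k_max) (near-critical damping of the stiffest mode).
#' @param force_tolerance convergence threshold on the max vertex force, pN.
#' @param max_steps iteration cap.
#' @param max_displacement_per_step displacement cap, um; guards the
#'   diverging force poles.
#' @return list of class `relaxation_config`.
#' @export
relaxation_config <- function(dt = NULL, vertex_mass = 1e-3,
                              drag_coefficient = NULL,
                              force_tolerance = 1e-3, max_steps = 50000L,
                              max_displacement_per_step = 1e-3) {
  stopifnot(is.null(dt) || dt > 0, vertex_mass > 0, force_tolerance > 0,
            max_steps >= 1, max_displacement_per_step > 0)
  structure(list(dt = dt, vertex_mass = vertex_mass,
                 drag_coefficient = drag_coefficient,
                 force_tolerance = force_tolerance,
                 max_steps = as.integer(max_steps),
                 max_displacement_per_step = max_displacement_per_step),
            class = "relaxation_config")
}

# Numerical probe of the stiffest per-vertex response (pN/um) at the given
# configuration: displace all vertices by a small deterministic unit-row
# pattern and measure the largest force change per displacement.  Used only
# to auto-scale dt and drag; a conservative overestimate is harmless.
stiffness_probe <- function(mesh, reference, model, positions) {
  n <- nrow(positions)
  raw <- cbind(sin(1.7 * seq_len(n) + 0.3), cos(2.3 * seq_len(n) + 1.1),
               sin(3.1 * seq_len(n) + 2.2))
  probes <- list(raw / sqrt(rowSums(raw^2)))
  if (mesh$closed) {
    # uniform outward-normal pattern excites the (stiff) volume mode that a
    # divergence-free random pattern misses
    fn <- face_normals_areas(positions, mesh$faces)$normals
    vn <- matrix(0, n, 3L)
    for (m in 1:3) vn <- scatter_add3(vn, mesh$faces[, m], fn)
    probes <- c(probes, list(vn / sqrt(rowSums(vn^2))))
  }
  h <- 1e-5 * reference$L0_mean
  f0 <- model_forces(mesh, reference, positions, NULL, model)
  one <- function(delta, h) {
    f1 <- tryCatch(
      model_forces(mesh, reference, positions + h * delta, NULL, model),
      error = function(e) NULL)   # probe crossed a force pole: retry closer
    if (is.null(f1)) {
      if (h < 1e-12) return(NA_real_)
      return(one(delta, h / 10))
    }
    max(sqrt(rowSums((f1 - f0)^2))) / h
  }
  k <- max(vapply(probes, one, numeric(1), h = h), na.rm = TRUE)
  5 * k   # safety margin: the probes lower-bound the stiffest mode
}

# Conservative model forces.  The quasi-static integrator never feeds
# vertex velocities to the models: the dissipative membrane-viscosity term
# of the spectrin model vanishes at steady state and belongs to the
# fluid-coupled dynamics, while the integrator's own drag -c v supplies the
# dissipation here.
model_forces <- function(mesh, reference, positions, velocities, model) {
  if (inherits(model, "new_material_params"))
    accumulate_forces(mesh, reference, positions, model)
  else
    spectrin_forces(mesh, reference, positions, velocities, model)
}

#' One damped velocity-Verlet step
#'
#' Advances the state by one explicit step under the model forces plus
#' optional external forces and per-vertex drag `-c v`.  Per-step vertex
#' displacements are capped to keep strains away from the force poles.
#' Coordinates flagged in `fixed` are immobile (velocity and displacement
#' zeroed), which implements pinned vertices and prescribed displacements;
#' the model force accumulated at a fixed coordinate is the negative of the
#' constraint reaction.
#'
#' @param state a [cell_state()].
#' @param mesh,reference mesh and reference geometry.
#' @param model a [new_material_params()] or [spectrin_params()].
#' @param external_forces n x 3 matrix of applied loads, pN (or `NULL`).
#' @param config a [relaxation_config()] with `dt` and `drag_coefficient`
#'   resolved (see [relax()]).
#' @param fixed n x 3 logical matrix of constrained coordinates (or `NULL`).
#' @return the advanced `cell_state` (with `forces` set to the model+
#'   external forces at the *start* of the step).
#' @export
dem_step <- function(state, mesh, reference, model, external_forces = NULL,
                     config = relaxation_config(), fixed = NULL) {
  dt <- config$dt; m <- config$vertex_mass; cdrag <- config$drag_coefficient
  if (is.null(dt) || is.null(cdrag))
    stop("dem_step() needs a fully resolved config; use relax() or set dt and drag_coefficient")
  x <- state$positions; v <- state$velocities
  f <- model_forces(mesh, reference, x, NULL, model)
  if (!is.null(external_forces)) f <- f + external_forces
  if (!is.null(fixed)) { f[fixed] <- 0; v[fixed] <- 0 }
  a <- (f - cdrag * v) / m
  dx <- v * dt + 0.5 * a * dt^2
  # displacement cap
  dn <- sqrt(rowSums(dx^2))
  over <- dn > config$max_displacement_per_step
  if (any(over)) {
    dx[over, ] <- dx[over, , drop = FALSE] *
      (config$max_displacement_per_step / dn[over])
    v[over, ] <- 0
  }
  if (!is.null(fixed)) dx[fixed] <- 0
  x_new <- x + dx
  if (!all(is.finite(x_new))) {
    bad <- which(!is.finite(rowSums(x_new)))[1L]
    stop(sprintf("integration diverged at t = %g us (vertex %d)",
                 state$time, bad))
  }
  f_new <- model_forces(mesh, reference, x_new, NULL, model)
  if (!is.null(external_forces)) f_new <- f_new + external_forces
  if (!is.null(fixed)) f_new[fixed] <- 0
  v_new <- (v + 0.5 * (a + f_new / m) * dt) / (1 + 0.5 * cdrag * dt / m)
  if (!is.null(fixed)) v_new[fixed] <- 0
  structure(list(positions = x_new, velocities = v_new, forces = f_new,
                 time = state$time + dt), class = "cell_state")
}

#' Relax a membrane to static equilibrium
#'
#' Iterates [dem_step()] until the largest unconstrained vertex force drops
#' below `force_tolerance` or `max_steps` is reached.
#'
#' @inheritParams dem_step
#' @return list with `state` (final [cell_state()]), `converged` (logical),
#'   `residual` (final max vertex force, pN) and `steps`.
#' @export
relax <- function(state, mesh, reference, model, external_forces = NULL,
                  config = relaxation_config(), fixed = NULL) {
  resid_of <- function(st) {
    f <- st$forces
    if (!is.null(fixed)) f[fixed] <- 0
    if (nrow(f) == 0) 0 else max(sqrt(rowSums(f^2)))
  }
  f0 <- model_forces(mesh, reference, state$positions, NULL, model)
  if (!is.null(external_forces)) f0 <- f0 + external_forces
  if (!is.null(fixed)) f0[fixed] <- 0
  state$forces <- f0
  res <- resid_of(state)
  steps <- 0L

  if (!is.null(config$dt) && !is.null(config$drag_coefficient)) {
    # fully specified integrator: plain damped velocity-Verlet iteration
    while (res >= config$force_tolerance && steps < config$max_steps) {
      state <- dem_step(state, mesh, reference, model, external_forces,
                        config, fixed)
      steps <- steps + 1L
      if (steps %% 10L == 0L) res <- resid_of(state)
    }
    res <- resid_of(state)
    return(list(state = state, converged = res < config$force_tolerance,
                residual = res, steps = steps))
  }

  if (inherits(model, "spectrin_params")) {
    # conservative model with an exact energy: quasi-Newton minimization
    # converges orders of magnitude faster than damped dynamics and reaches
    # the same steady state (which is integrator independent)
    out <- relax_lbfgs(state, mesh, reference, model, external_forces,
                       config, fixed)
    return(out)
  }

  # Auto-tuned path: FIRE-accelerated damped dynamics.  The strain-limited
  # force poles make the stiffness strongly state dependent (orders of
  # magnitude stiffer near a pole than at equilibrium), so the step size is
  # re-probed periodically and adapted between probes by the FIRE rules:
  # grow dt and align velocities with the force while the power F.v stays
  # positive, freeze and shrink dt when it turns negative.
  reprobe_every <- 250L
  probe_cfg <- function(cfg) {
    k <- max(stiffness_probe(mesh, reference, model, state$positions), 1e-6)
    cfg$dt0 <- 0.5 * sqrt(config$vertex_mass / k)
    cfg$dt_max <- 25 * cfg$dt0
    cfg
  }
  fire <- probe_cfg(list())
  dt <- fire$dt0
  alpha <- 0.1; ngood <- 0L
  step_cfg <- config
  step_cfg$drag_coefficient <- 0
  while (res >= config$force_tolerance && steps < config$max_steps) {
    step_cfg$dt <- dt
    trial <- tryCatch(
      dem_step(state, mesh, reference, model, external_forces,
               step_cfg, fixed),
      error = function(e) e)
    if (inherits(trial, "error")) {
      # a trial step crossed a force pole: backtrack instead of clamping
      state$velocities[] <- 0
      dt <- dt * 0.3
      alpha <- 0.1; ngood <- 0L
      if (dt < 1e-9 * fire$dt0) stop(trial)
      steps <- steps + 1L
      next
    }
    state <- trial
    steps <- steps + 1L
    f <- state$forces; v <- state$velocities
    if (!is.null(fixed)) { f[fixed] <- 0; v[fixed] <- 0 }
    P <- sum(f * v)
    if (P > 0) {
      ngood <- ngood + 1L
      if (ngood > 5L) {
        dt <- min(dt * 1.1, fire$dt_max)
        alpha <- alpha * 0.99
      }
      fn <- sqrt(sum(f^2)); vn <- sqrt(sum(v^2))
      if (fn > 0)
        state$velocities <- (1 - alpha) * v + alpha * (vn / fn) * f
    } else {
      state$velocities[] <- 0
      dt <- max(dt * 0.5, 0.02 * fire$dt0)
      alpha <- 0.1; ngood <- 0L
    }
    if (steps %% 10L == 0L) res <- resid_of(state)
    if (steps %% reprobe_every == 0L) {
      fire <- probe_cfg(fire)
      dt <- min(max(dt, fire$dt0), fire$dt_max)
    }
  }
  res <- resid_of(state)
  list(state = state, converged = res < config$force_tolerance,
       residual = res, steps = steps)
}

# L-BFGS-B minimization of the spectrin free energy (pN um), with external
# loads as a linear potential and fixed coordinates excluded from the
# optimization vector.
relax_lbfgs <- function(state, mesh, reference, model, external_forces,
                        config, fixed) {
  x0 <- state$positions
  free <- if (is.null(fixed)) matrix(TRUE, nrow(x0), 3L) else !fixed
  pack <- function(x) x[free]
  unpack <- function(p) { x <- x0; x[free] <- p; x }
  fn <- function(p) {
    x <- unpack(p)
    u <- tryCatch(
      spectrin_energy(mesh, reference, x, model)$total * model$kBT,
      error = function(e) NA_real_)
    if (!is.finite(u)) return(1e12)   # beyond the WLC extension limit
    if (!is.null(external_forces)) u <- u - sum(external_forces * x)
    u
  }
  gr <- function(p) {
    x <- unpack(p)
    f <- tryCatch(spectrin_forces(mesh, reference, x, NULL, model),
                  error = function(e) matrix(0, nrow(x0), 3L))
    if (!is.null(external_forces)) f <- f + external_forces
    -pack(f)
  }
  opt <- stats::optim(pack(x0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_steps,
                                     factr = 10,
                                     pgtol = config$force_tolerance / 10))
  xf <- unpack(opt$par)
  f <- spectrin_forces(mesh, reference, xf, NULL, model)
  if (!is.null(external_forces)) f <- f + external_forces
  if (!is.null(fixed)) f[fixed] <- 0
  res <- if (nrow(f)) max(sqrt(rowSums(f^2))) else 0
  st <- cell_state(xf, time = state$time)
  st$forces <- f
  list(state = st, converged = res < config$force_tolerance,
       residual = res, steps = opt$counts[["function"]])
}
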
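# Force-bias packing of ellipsoid cell proxies: dense randomized,
# overlap-free initial conditions for RBC/PLT mixtures in a periodic box.
# Cells are represented by their enclosing ellipsoids during packing; the
# hematocrit is accounted with the true (mesh) cell volumes.

#' Default enclosing-ellipsoid semi-axes, um
#'
#' RBC: half the 8 um diameter in-plane and half the biconcave template
#' thickness; PLT: a rigid oblate ellipsoid.
#' @name packing_defaults
#' @export
rbc_semi_axes <- function() c(4.0, 4.0, 1.0)

#' @rdname packing_defaults
#' @export
plt_semi_axes <- function() c(1.8, 1.8, 0.55)

#' Initialize an ellipsoid population for packing
#'
#' Draws random cell centers (and optionally orientations) in a periodic
#' box, with cell counts chosen so that the true cell volumes reach the
#' requested hematocrit: `n_RBC = floor(H V_box / V_RBC)` and
#' `n_PLT = floor(plt_ratio n_RBC)`.  The initial outer scale `d_out` is
#' set so that the merged (union) volume of the scaled ellipsoids equals
#' the total enclosing-ellipsoid volume of the population.
#'
#' @param domain periodic box edge lengths, um (length 1 or 3).
#' @param hematocrit target RBC+PLT volume fraction from true cell volumes,
#'   in (0, 0.5].
#' @param plt_ratio platelets per RBC (default 0.1, i.e. 1 PLT : 10 RBC).
#' @param orientation_mode `"random"` or `"fixed"` (all cells aligned,
#'   symmetry axis along z).
#' @param seed integer RNG seed; identical seeds give identical populations.
#' @param rbc_volume,plt_volume true cell volumes, um^3 (defaults: the
#'   71 um^3 template and the PLT ellipsoid volume).
#' @param rbc_axes,plt_axes enclosing-ellipsoid semi-axes, um.
#' @param contraction_rate per-iteration contraction factor of `d_out`.
#' @return list with `population` (class `ellipsoid_population`: `centers`,
#'   `semi_axes`, `orientations`, `types`, `cell_volume`) and `state`
#'   (class `packing_state`: `d_in`, `d_out`, `contraction_rate`,
#'   `iteration`, `domain`).
#' @export
init_population <- function(domain, hematocrit, plt_ratio = 0.1,
                            orientation_mode = c("random", "fixed"),
                            seed = 1L,
                            rbc_volume = 71,
                            plt_volume = 4 / 3 * pi * prod(plt_semi_axes()),
                            rbc_axes = rbc_semi_axes(),
                            plt_axes = plt_semi_axes(),
                            contraction_rate = 0.999) {
  orientation_mode <- match.arg(orientation_mode)
  if (length(domain) == 1L) domain <- rep(domain, 3L)
  stopifnot(length(domain) == 3, all(domain > 0),
            hematocrit > 0, plt_ratio >= 0, contraction_rate > 0,
            contraction_rate < 1)
  if (hematocrit > 0.5)
    stop("hematocrit above 0.5 is not reachable by ellipsoid packing")
  Vbox <- prod(domain)
  n_rbc <- floor(hematocrit * Vbox / rbc_volume)
  n_plt <- floor(plt_ratio * n_rbc)
  if (n_rbc < 1) stop("domain too small for a single RBC")
  n <- n_rbc + n_plt
  types <- c(rep("RBC", n_rbc), rep("PLT", n_plt))

  set.seed(seed)
  centers <- cbind(runif(n, 0, domain[1L]), runif(n, 0, domain[2L]),
                   runif(n, 0, domain[3L]))
  if (orientation_mode == "random") {
    q <- matrix(stats::rnorm(4L * n), n, 4L)
    q <- q / sqrt(rowSums(q^2))
  } else {
    q <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4L)
  }
  axes <- rbind(matrix(rbc_axes, n_rbc, 3L, byrow = TRUE),
                matrix(plt_axes, max(n_plt, 0L), 3L, byrow = TRUE))

  pop <- structure(list(
    centers = centers, orientations = q, types = types,
    semi_axes = list(RBC = rbc_axes, PLT = plt_axes),
    axes_matrix = axes,
    cell_volume = c(RBC = rbc_volume, PLT = plt_volume),
    orientation_mode = orientation_mode,
    domain = domain, seed = as.integer(seed)),
    class = "ellipsoid_population")

  # d_out0: union volume of d_out-scaled ellipsoids = total unscaled
  # ellipsoid volume (bisection on the monotone union fraction)
  Vell <- sum(4 / 3 * pi * apply(axes, 1L, prod))
  target_frac <- min(Vell / Vbox, 0.99)
  f_of <- function(s)
    .union_fraction_cpp(centers, axes, q, s, domain, 40000L,
                        as.integer(seed) + 17L)
  lo <- 1; hi <- 2
  while (f_of(hi) < target_frac && hi < 8) hi <- hi * 1.3
  for (it in 1:20) {
    mid <- (lo + hi) / 2
    if (f_of(mid) < target_frac) lo <- mid else hi <- mid
  }
  d_out0 <- max((lo + hi) / 2, 1)
  d_in0 <- .din_cpp(centers, axes, q, domain)
  state <- structure(list(
    d_in = d_in0, d_out = d_out0,
    contraction_rate = contraction_rate, iteration = 0L,
    domain = domain),
    class = "packing_state")
  list(population = pop, state = state)
}

#' Monte-Carlo overlap volume of two ellipsoids
#'
#' Samples inside the smaller ellipsoid and counts the fraction falling
#' inside the other, under minimum-image periodicity.  A Perram-Wertheim
#' contact pre-test returns an exact zero for disjoint pairs.
#'
#' @param e_i,e_j lists with `center` (length 3), `semi_axes` (length 3)
#'   and `orientation` (unit quaternion, w-first).
#' @param scale common scaling factor applied to both ellipsoids.
#' @param domain periodic box edge lengths (length 1 or 3); use a box much
#'   larger than the pair for free-space overlaps.
#' @param mc_samples number of Monte-Carlo samples.
#' @param seed RNG seed.
#' @return overlap volume, um^3.
#' @export
overlap_volume <- function(e_i, e_j, scale = 1, domain = 1e6,
                           mc_samples = 20000L, seed = 1L) {
  if (length(domain) == 1L) domain <- rep(domain, 3L)
  centers <- rbind(e_i$center, e_j$center)
  axes <- rbind(e_i$semi_axes, e_j$semi_axes)
  quats <- rbind(e_i$orientation, e_j$orientation)
  .mc_overlap_cpp(centers, axes, quats, scale, domain,
                  as.integer(mc_samples), as.integer(seed))
}

#' Run the force-bias packing loop
#'
#' Iteratively pushes overlapping ellipsoids apart with displacements
#' proportional to their pairwise overlap volume at the outer scale `d_out`
#' (heavier, larger cells move less), contracts `d_out` each iteration, and
#' recomputes the no-overlap certificate scale `d_in` (Perram-Wertheim).
#' Terminates when `d_out <= d_in`; `d_out` never contracts below 1, so a
#' converged result is overlap-free at the true cell size.
#'
#' For randomly oriented populations the cells also rotate toward larger
#' pair clearance; freezing the orientations (`rotate = FALSE`, the default
#' for `orientation_mode = "fixed"`) restricts the dynamics to center-of-
#' mass translation, which jams well below the densities reachable with
#' rotational freedom.
#'
#' @param population,state from [init_population()].
#' @param max_iterations iteration cap.
#' @param mc_samples Monte-Carlo samples per overlapping pair and iteration.
#' @param step_length displacement per unit normalized overlap, um.
#' @param jitter annealing kick amplitude, in units of the particle scaling
#'   radius, applied to particles under contact force (0 disables).
#' @param rotate allow rotational relaxation; defaults to `TRUE` for
#'   randomly oriented populations and `FALSE` for fixed alignment.
#' @param rot_step rotation per unit contact-scale gradient, rad.
#' @return list with updated `population`, `state` (including the per-
#'   iteration `d_in`/`d_out` logs), `converged`, and `hematocrit` (the
#'   achieved true-volume fraction; meaningful when converged).
#' @export
pack_cells <- function(population, state, max_iterations = 5000L,
                       mc_samples = 128L, step_length = 0.8,
                       jitter = 0, rotate = NULL, rot_step = 0.5) {
  if (is.null(rotate))
    rotate <- isTRUE(population$orientation_mode == "random")
  res <- .pack_cpp(population$centers, population$axes_matrix,
                   population$orientations, state$domain,
                   state$d_out, state$contraction_rate,
                   as.integer(max_iterations), as.integer(mc_samples),
                   step_length, jitter, isTRUE(rotate), rot_step,
                   population$seed + 1000003L)
  population$centers <- res$centers
  population$orientations <- res$orientations
  state$d_in <- res$d_in
  state$d_out <- res$d_out
  state$iteration <- state$iteration + res$iterations
  state$din_log <- res$din_log
  state$dout_log <- res$dout_log
  hm <- sum(population$cell_volume[population$types]) / prod(state$domain)
  if (!res$converged)
    warning(sprintf(
      "packing not converged after %d iterations (d_in %.4f < d_out %.4f)",
      res$iterations, res$d_in, res$d_out))
  list(population = population, state = state,
       converged = res$converged, hematocrit = unname(hm))
}

#' Export a packed population to CSV (and optionally VTK points)
#'
#' @param population an `ellipsoid_population`.
#' @param path CSV output path (columns: type, x, y, z, qw, qx, qy, qz).
#' @param vtk_path optional legacy-VTK glyph (points + orientation vectors)
#'   for visual inspection.
#' @return `path`, invisibly.
#' @export
export_positions <- function(population, path, vtk_path = NULL) {
  df <- data.frame(type = population$types,
                   x = population$centers[, 1L],
                   y = population$centers[, 2L],
                   z = population$centers[, 3L],
                   qw = population$orientations[, 1L],
                   qx = population$orientations[, 2L],
                   qy = population$orientations[, 3L],
                   qz = population$orientations[, 4L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(vtk_path)) {
    n <- nrow(df)
    lines <- c("# vtk DataFile Version 3.0", "ellipsoid centers", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n),
               sprintf("%.9g %.9g %.9g", df$x, df$y, df$z))
    writeLines(lines, vtk_path)
  }
  invisible(path)
}

#' Read a population back from the CSV written by [export_positions()]
#'
#' Geometry metadata (semi-axes, cell volumes, domain) is not stored in the
#' CSV and is supplied by the caller.
#'
#' @param path CSV path.
#' @inheritParams init_population
#' @return an `ellipsoid_population`.
#' @export
read_positions <- function(path, domain,
                           rbc_axes = rbc_semi_axes(),
                           plt_axes = plt_semi_axes(),
                           rbc_volume = 71,
                           plt_volume = 4 / 3 * pi * prod(plt_semi_axes())) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (length(domain) == 1L) domain <- rep(domain, 3L)
  axes <- t(vapply(df$type, function(tt)
    if (tt == "RBC") rbc_axes else plt_axes, numeric(3)))
  structure(list(
    centers = unname(as.matrix(df[, c("x", "y", "z")])),
    orientations = unname(as.matrix(df[, c("qw", "qx", "qy", "qz")])),
    types = df$type,
    semi_axes = list(RBC = rbc_axes, PLT = plt_axes),
    axes_matrix = unname(axes),
    cell_volume = c(RBC = rbc_volume, PLT = plt_volume),
    domain = domain, seed = NA_integer_),
    class = "ellipsoid_population")
}
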
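# Triangulated membrane meshes: construction, topology, discrete geometry.
# Coordinates are in micrometers throughout the package; forces in pN;
# energies in units of k_B T with k_B T = 4.141e-3 pN um (T = 300 K).

#' Thermal energy unit used throughout the package
#'
#' `kBT_pN_um` is k_B T at T = 300 K expressed in pN um.  All stiffness
#' parameters quoted "in k_B T" are converted with this constant.
#' @export
kBT_pN_um <- 4.141e-3

#' Construct a triangle mesh
#'
#' Builds the package's triangle-mesh container from a vertex matrix and a
#' face index matrix, deriving the unique edge list and the edge-to-face
#' adjacency.  Faces must be consistently oriented (counter-clockwise seen
#' from outside for closed surfaces).
#'
#' @param vertices numeric matrix, n x 3, vertex positions in um.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return An object of class `tri_mesh`: a list with elements `vertices`,
#'   `faces`, `edges` (e x 2, each row sorted), `edge_faces` (e x 2 face
#'   indices, `NA` for the missing side of a border edge), and `closed`
#'   (logical; `TRUE` when every edge has two adjacent faces).
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")

  # half-edges of every face, canonicalized by sorting the endpoint pair
  he <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  fid <- rep.int(seq_len(nrow(faces)), 3L)
  key_a <- pmin(he[, 1L], he[, 2L])
  key_b <- pmax(he[, 1L], he[, 2L])
  ord <- order(key_a, key_b)
  ka <- key_a[ord]; kb <- key_b[ord]; fo <- fid[ord]
  new_edge <- c(TRUE, ka[-1L] != ka[-length(ka)] | kb[-1L] != kb[-length(kb)])
  eid <- cumsum(new_edge)
  ne <- eid[length(eid)]
  cnt <- tabulate(eid, ne)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two faces")
  edges <- cbind(ka[new_edge], kb[new_edge])
  edge_faces <- matrix(NA_integer_, ne, 2L)
  first <- which(new_edge)
  edge_faces[, 1L] <- fo[first]
  second <- which(!new_edge)
  edge_faces[eid[second], 2L] <- fo[second]
  closed <- all(cnt == 2L)

  # bending stencil of each interior edge: the apex vertex of each adjacent
  # face, and the edge orientation as traversed by face 1 (fixes the sign
  # convention of the dihedral angle)
  a <- edges[, 1L]; b <- edges[, 2L]
  apices <- matrix(NA_integer_, ne, 2L)
  for (s in 1:2) {
    ok <- !is.na(edge_faces[, s])
    fv <- faces[edge_faces[ok, s], , drop = FALSE]
    apices[ok, s] <- fv[, 1L] + fv[, 2L] + fv[, 3L] - a[ok] - b[ok]
  }
  fwd <- rep(NA, ne)
  ok <- !is.na(edge_faces[, 1L])
  f1 <- faces[edge_faces[ok, 1L], , drop = FALSE]
  fwd[ok] <- (f1[, 1L] == a[ok] & f1[, 2L] == b[ok]) |
             (f1[, 2L] == a[ok] & f1[, 3L] == b[ok]) |
             (f1[, 3L] == a[ok] & f1[, 1L] == b[ok])

  mesh <- list(vertices = vertices, faces = faces, edges = edges,
               edge_faces = edge_faces, apices = apices,
               edge_fwd = fwd, closed = closed)
  # 0-based topology bundle consumed by the compiled kernels; interior
  # edges are re-oriented so face 1 traverses a -> b
  interior <- which(!is.na(edge_faces[, 1L]) & !is.na(edge_faces[, 2L]))
  ea <- a; eb <- b
  swp <- interior[!fwd[interior]]
  ea[swp] <- b[swp]; eb[swp] <- a[swp]
  mesh$cpp <- list(
    ea = ea - 1L, eb = eb - 1L, interior = interior - 1L,
    if1 = edge_faces[interior, 1L] - 1L,
    if2 = edge_faces[interior, 2L] - 1L,
    ap1 = apices[interior, 1L] - 1L, ap2 = apices[interior, 2L] - 1L,
    faces = faces - 1L, closed = closed)
  structure(mesh, class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d edges, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$edges), nrow(x$faces),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# Backwards-compatible accessor for the per-edge apex pair.
edge_apices <- function(mesh) mesh$apices

row_norms <- function(m) sqrt(rowSums(m * m))

face_normals_areas <- function(vertices, faces) {
  p0 <- vertices[faces[, 1L], , drop = FALSE]
  p1 <- vertices[faces[, 2L], , drop = FALSE]
  p2 <- vertices[faces[, 3L], , drop = FALSE]
  u <- p1 - p0
  v <- p2 - p0
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  a2 <- row_norms(cr)
  list(normals = cr / a2, areas = a2 / 2,
       centroids = (p0 + p1 + p2) / 3)
}

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()].
#' @return total area of all faces, um^2.
#' @export
mesh_area <- function(mesh) {
  sum(face_normals_areas(mesh$vertices, mesh$faces)$areas)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem, positive when all face normals
#' point outward.
#'
#' @param mesh a closed [tri_mesh()].
#' @param vertices optional replacement vertex matrix (same topology).
#' @return enclosed volume, um^3.
#' @export
mesh_volume <- function(mesh, vertices = mesh$vertices) {
  if (!mesh$closed)
    stop("mesh_volume() requires a closed mesh")
  p0 <- vertices[mesh$faces[, 1L], , drop = FALSE]
  p1 <- vertices[mesh$faces[, 2L], , drop = FALSE]
  p2 <- vertices[mesh$faces[, 3L], , drop = FALSE]
  sum(p0[, 1L] * (p1[, 2L] * p2[, 3L] - p1[, 3L] * p2[, 2L]) -
      p0[, 2L] * (p1[, 1L] * p2[, 3L] - p1[, 3L] * p2[, 1L]) +
      p0[, 3L] * (p1[, 1L] * p2[, 2L] - p1[, 2L] * p2[, 1L])) / 6
}

#' Signed dihedral angles of the interior edges
#'
#' The fold angle between the two faces adjacent to each interior edge.
#' Coplanar faces give 0; the angle is positive for a convex (outward
#' bulging) fold, i.e. when the face normals diverge, and negative for a
#' concave crease.  Border edges of open meshes are excluded.
#'
#' @param mesh a [tri_mesh()].
#' @param vertices optional replacement vertex matrix (same topology).
#' @return named numeric vector of angles in radians; names are the interior
#'   edge indices into `mesh$edges`.
#' @export
dihedral_angles <- function(mesh, vertices = mesh$vertices) {
  interior <- which(!is.na(mesh$edge_faces[, 1L]) &
                    !is.na(mesh$edge_faces[, 2L]))
  th <- dihedral_angles_interior(mesh, vertices, interior)
  names(th) <- interior
  th
}

# dihedral angles for the given interior edge indices (no names, no checks)
dihedral_angles_interior <- function(mesh, vertices, interior) {
  fn <- face_normals_areas(vertices, mesh$faces)$normals
  n1 <- fn[mesh$edge_faces[interior, 1L], , drop = FALSE]
  n2 <- fn[mesh$edge_faces[interior, 2L], , drop = FALSE]
  a <- mesh$edges[interior, 1L]
  b <- mesh$edges[interior, 2L]
  ev <- vertices[b, , drop = FALSE] - vertices[a, , drop = FALSE]
  # the edge is oriented as traversed by face 1 (see tri_mesh()), which
  # fixes the sign: positive for convex (outward-bulging) folds
  sgn <- ifelse(mesh$edge_fwd[interior], 1, -1)
  cr <- cbind(n1[, 2L] * n2[, 3L] - n1[, 3L] * n2[, 2L],
              n1[, 3L] * n2[, 1L] - n1[, 1L] * n2[, 3L],
              n1[, 1L] * n2[, 2L] - n1[, 2L] * n2[, 1L])
  s <- sgn * rowSums(cr * ev) / row_norms(ev)
  c_ <- rowSums(n1 * n2)
  atan2(s, c_)
}

#' Reference (equilibrium) geometry of a mesh
#'
#' Captures the undeformed template geometry that the constitutive models
#' measure strains against.  Computed once from the template and treated as
#' immutable.
#'
#' @param mesh a [tri_mesh()] in its equilibrium configuration.
#' @return An object of class `ref_geometry`: list with `L0` (per-edge
#'   lengths, um), `A0_k` (per-face areas, um^2), `theta0` (per interior
#'   edge dihedral, rad; `NA` on border edges), `V0` (enclosed volume, um^3;
#'   `NA` for open meshes), `A0` (total area, um^2) and `L0_mean` (mean
#'   edge length, um).
#' @export
reference_geometry <- function(mesh) {
  L0 <- row_norms(mesh$vertices[mesh$edges[, 2L], , drop = FALSE] -
                  mesh$vertices[mesh$edges[, 1L], , drop = FALSE])
  fa <- face_normals_areas(mesh$vertices, mesh$faces)
  theta0 <- rep(NA_real_, nrow(mesh$edges))
  interior <- which(!is.na(mesh$edge_faces[, 1L]) &
                    !is.na(mesh$edge_faces[, 2L]))
  theta0[interior] <- dihedral_angles_interior(mesh, mesh$vertices, interior)
  structure(list(
    L0 = L0,
    A0_k = fa$areas,
    theta0 = theta0,
    V0 = if (mesh$closed) mesh_volume(mesh) else NA_real_,
    A0 = sum(fa$areas),
    L0_mean = mean(L0)
  ), class = "ref_geometry")
}

#' Geodesic icosphere
#'
#' Repeated 4-to-1 subdivision of a regular icosahedron with projection onto
#' the unit sphere.  Level `n` yields 10*4^n + 2 vertices, 30*4^n edges and
#' 20*4^n triangles; level 2 gives the 642/1920/1280 membrane resolution
#' used for the RBC template.
#'
#' @param subdivision_level non-negative integer.
#' @return a closed [tri_mesh()] with unit circumradius and outward faces.
#' @export
make_icosphere <- function(subdivision_level) {
  stopifnot(length(subdivision_level) == 1L, subdivision_level >= 0)
  n <- as.integer(subdivision_level)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(n)) {
    nv <- nrow(v)
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- key(f[, 1L], f[, 2L]); e2 <- key(f[, 2L], f[, 3L])
    e3 <- key(f[, 3L], f[, 1L])
    allk <- c(e1, e2, e3)
    uk <- unique(allk)
    midx <- match(allk, uk) + nv      # index of each midpoint vertex
    a <- uk %/% (nv + 1); b <- uk %% (nv + 1)
    mid <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    mid <- mid / row_norms(mid)
    v <- rbind(v, mid)
    m <- nrow(f)
    m1 <- midx[seq_len(m)]; m2 <- midx[m + seq_len(m)]
    m3 <- midx[2 * m + seq_len(m)]
    f <- rbind(cbind(f[, 1L], m1, m3),
               cbind(m1, f[, 2L], m2),
               cbind(m3, m2, f[, 3L]),
               cbind(m1, m2, m3))
  }
  mesh <- tri_mesh(v, f)
  if (mesh_volume(mesh) < 0)
    mesh <- tri_mesh(v, f[, c(1L, 3L, 2L)])
  mesh
}

#' Cell template specification
#'
#' @param cell_type `"RBC"` or `"PLT"`.
#' @param diameter cell diameter, um.  The RBC literature uses both 8 um
#'   (typical diameter) and 7.82 um (the optical-tweezer reference value);
#'   both are accepted here and each experiment uses the value appropriate
#'   to it.
#' @param target_volume enclosed volume, um^3 (RBC default 71).
#' @param subdivision_level icosphere subdivision level (3 gives the
#'   642-vertex membrane used throughout).
#' @return a list of class `cell_template_spec`.
#' @export
cell_template_spec <- function(cell_type = c("RBC", "PLT"), diameter = 8,
                               target_volume = 71, subdivision_level = 3L) {
  cell_type <- match.arg(cell_type)
  stopifnot(diameter > 0, target_volume > 0, subdivision_level >= 0)
  structure(list(cell_type = cell_type, diameter = diameter,
                 target_volume = target_volume,
                 subdivision_level = as.integer(subdivision_level)),
            class = "cell_template_spec")
}

# Biconcave discocyte profile: half-thickness z(r) for cylindrical radius r,
# using the classical Evans-Fung parameterization with a uniform thickness
# scale applied to the coefficients so the mesh volume can be calibrated.
biconcave_halfz <- function(r, diameter, thickness_scale = 1) {
  c0 <- 0.1035805; c1 <- 1.001279; c2 <- -0.5614381
  rho2 <- pmin((2 * r / diameter)^2, 1)
  thickness_scale * (diameter / 2) * sqrt(1 - rho2) *
    (c0 + c1 * rho2 + c2 * rho2^2)
}

#' Biconcave RBC template mesh
#'
#' Maps an icosphere onto the biconcave discocyte surface (Evans-Fung
#' profile), smooths the triangulation tangentially to avoid sliver
#' triangles, and scales the profile thickness so the enclosed mesh volume
#' matches `target_volume` exactly.  The reference geometry is captured
#' from the calibrated shape.
#'
#' @param spec a [cell_template_spec()] with `cell_type = "RBC"`.
#' @param smoothing_steps tangential Laplacian smoothing iterations.
#' @return list with elements `mesh` ([tri_mesh()]) and `reference`
#'   ([reference_geometry()]).
#' @export
make_rbc_template <- function(spec = cell_template_spec(),
                              smoothing_steps = 50L) {
  if (spec$cell_type != "RBC")
    stop("make_rbc_template() requires cell_type = 'RBC'")
  D <- spec$diameter
  ico <- make_icosphere(spec$subdivision_level)
  u <- ico$vertices
  # cylindrical-radius projection: keep the azimuth, map latitude bands of
  # the sphere onto the disc radius, hemisphere sign selects the sheet
  r <- (D / 2) * sqrt(pmin(u[, 1L]^2 + u[, 2L]^2, 1))
  az <- atan2(u[, 2L], u[, 1L])
  sgn <- sign(u[, 3L])
  v <- cbind(r * cos(az), r * sin(az),
             sgn * biconcave_halfz(r, D))
  mesh <- tri_mesh(v, ico$faces)

  # tangential smoothing: umbrella average in the disc plane, re-projected
  # onto the profile each step (keeps the surface, equalizes triangles)
  adj <- lapply(seq_len(nrow(v)), function(i) integer(0))
  for (k in seq_len(nrow(mesh$edges))) {
    a <- mesh$edges[k, 1L]; b <- mesh$edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lambda <- 0.5
  rim <- sgn == 0            # equatorial vertices stay on the rim circle
  for (it in seq_len(smoothing_steps)) {
    avg <- t(vapply(adj, function(nb) colMeans(v[nb, , drop = FALSE]),
                    numeric(3)))
    v <- v + lambda * (avg - v)
    r <- pmin(sqrt(v[, 1L]^2 + v[, 2L]^2), D / 2 * (1 - 1e-12))
    r[rim] <- D / 2
    az <- atan2(v[, 2L], v[, 1L])
    v <- cbind(r * cos(az), r * sin(az),
               sgn * biconcave_halfz(r, D))
  }

  vol1 <- mesh_volume(mesh, v)
  s <- spec$target_volume / vol1   # z-scaling changes the volume linearly
  if (!is.finite(s) || s <= 0.05 || s > 3)
    stop(sprintf(
      "target volume %.3g um^3 unreachable by thickness scaling (scale %.3g)",
      spec$target_volume, s))
  v[, 3L] <- v[, 3L] * s
  mesh <- tri_mesh(v, mesh$faces)
  list(mesh = mesh, reference = reference_geometry(mesh))
}

#' Ellipsoidal platelet template mesh
#'
#' Platelets are modeled as near-rigid oblate ellipsoids; the same membrane
#' machinery applies with a 10x stiffness scale.
#'
#' @param semi_axes numeric length 3, um (default `c(1.8, 1.8, 0.55)`).
#' @param subdivision_level icosphere subdivision level.
#' @return list with `mesh` and `reference` as in [make_rbc_template()].
#' @export
make_plt_template <- function(semi_axes = c(1.8, 1.8, 0.55),
                              subdivision_level = 1L) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  ico <- make_icosphere(subdivision_level)
  v <- sweep(ico$vertices, 2L, semi_axes, `*`)
  mesh <- tri_mesh(v, ico$faces)
  list(mesh = mesh, reference = reference_geometry(mesh))
}

#' Flat hexagonal membrane patch
#'
#' The elementary 7-vertex patch (1 center + 6 ring vertices, 6 equilateral
#' faces, 12 edges) used for the quasi-static moduli extraction tests.  All
#' interior dihedral reference angles are 0.
#'
#' @param L0 edge length, um.
#' @return list with `mesh` (open [tri_mesh()]) and `reference`.
#' @export
make_patch <- function(L0 = 0.5) {
  stopifnot(L0 > 0)
  ang <- (0:5) * pi / 3
  v <- rbind(c(0, 0, 0), cbind(L0 * cos(ang), L0 * sin(ang), 0))
  f <- cbind(1L, 2L:7L, c(3L:7L, 2L))   # CCW seen from +z
  mesh <- tri_mesh(v, f)
  list(mesh = mesh, reference = reference_geometry(mesh))
}
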
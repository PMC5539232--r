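---
title: "Discrete-element red blood cell membranes: models, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-element red blood cell membranes: models, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcdem)
```

## Scope

`rbcdem` models red blood cell (RBC) and platelet membranes as
discrete-element triangulated surfaces carrying constitutive force laws,
together with the single-cell experiments used to calibrate such models
(optical-tweezer stretching, hexagonal membrane-patch moduli), a force-bias
packing generator for dense randomized suspensions, and a minimal D3Q19
lattice-Boltzmann (LBM) solver with immersed-boundary (IBM) coupling for one
suspended cell. Everything runs at desk scale on one CPU; the module
boundaries are chosen so that the same membrane kernels could drive
large multi-cell suspensions, which are outside this package's scope.

Units are micrometers, microseconds, picograms and piconewtons throughout.
Energies are quoted in units of thermal energy with
`kBT_pN_um` = 4.141e-3 pN um, i.e. T = 300 K; stiffness constants quoted
"in kBT" are converted with this constant.

## The membrane discretization

A cell is a closed triangulated surface: vertices, edges and faces with
consistent outward orientation. The biconcave RBC template is built by
projecting a subdivided icosahedron (level 3: 642 vertices, 1,920 edges,
1,280 faces) onto the classical Evans–Fung discocyte profile

$$z(r) = \pm\frac{D}{2}\sqrt{1-\left(\tfrac{2r}{D}\right)^2}
  \left(c_0 + c_1\left(\tfrac{2r}{D}\right)^2 +
  c_2\left(\tfrac{2r}{D}\right)^4\right),$$

with the standard dimensionless coefficients
$(c_0, c_1, c_2) = (0.1035805,\ 1.001279,\ -0.5614381)$,
followed by 50 tangential Laplacian smoothing passes (vertices re-projected
onto the profile each pass, the equatorial ring pinned to the rim) to avoid
sliver triangles, and a final uniform scaling of the thickness so the
*discrete* mesh volume matches the target exactly — z-scaling changes the
enclosed volume linearly, so the calibration is closed-form rather than
iterative. The default target volume is 71 um^3 at 8 um diameter; the
resulting mean edge length is about 0.47 um, the working resolution `L0` of
all force laws. The reference geometry (per-edge lengths, per-face areas,
per-edge dihedral angles, total area and volume) is captured once from this
template and never mutated.

Two diameters appear in the RBC literature and both are supported: 8 um as
the typical cell diameter (the template default) and 7.82 um as the
reference diameter of the optical-tweezer and ektacytometry experiments;
each experiment uses the value appropriate to it.

Signed dihedral angles follow a fixed convention: 0 for coplanar faces,
positive when the two outward face normals diverge (a convex, outward
bulging fold). The sign is anchored by orienting each interior edge as it
is traversed by its first adjacent face; a regular icosahedron gives
+0.7297 rad on every edge, which the test suite checks against the closed
form $\pi - \arccos(-\sqrt5/3)$.

## The strain-limited constitutive model

The primary material model expresses the membrane response as four force
types, each with a linear small-strain regime and a pole that diverges at a
material limit $\tau$:

* **Link** (per edge): $F = -\frac{\kappa_l\,dL}{p}\bigl[1 +
  \frac{1}{\tau_l^2 - dL^2}\bigr]$ with normal strain $dL = (L-L_0)/L_0$,
  persistence length $p$ = 7.5 nm and $\tau_l = 3$.
* **Bending** (per interior edge): $F = -\frac{\kappa_b\,d\theta}{L_0}
  \bigl[1 + \frac{1}{\tau_b^2 - d\theta^2}\bigr]$ with
  $d\theta = \theta - \theta_0$ and $\tau_b = \pi/6$.
* **Local area** (per face): $F = -\frac{\kappa_a\,dA}{L_0}\bigl[1 +
  \frac{1}{\tau_a^2 - dA^2}\bigr]$ with $dA = (A_k - A_{0,k})/A_{0,k}$ and
  $\tau_a = 0.3$ (membranes are damaged beyond ~30–40% area strain).
* **Volume** (global): $F = -\frac{\kappa_v\,dV}{L_0}\,
  \frac{1}{\tau_v^2 - dV^2}$ with $dV = (V-V_0)/V_0$ and $\tau_v = 0.01$;
  note the missing leading unity — this term is pure constraint, with no
  independent linear regime.

Defaults are $\kappa_l = 15$, $\kappa_a = 5$, $\kappa_b = 80$ and
$\kappa_v = 20$ kBT; platelets use the same laws with $\kappa_l$,
$\kappa_a$, $\kappa_b$ multiplied by 10 (`plt_material_params()`).

The scalar response functions return the signed constitutive laws as
written above (negative under positive strain). The assembler applies them
in the restoring orientation of each element: a stretched link contracts
(equal and opposite forces on its two vertices), an expanded face pulls its
three vertices toward the centroid along the *un-normalized* offset
$C - v_m$ (so the force scales with triangle size — a deliberate fidelity
choice), an inflated cell pushes every face inward along its normal
weighted by $S_j/S_{avg}$ (each of the three face vertices receives the
full vector; the global $\kappa_v$ calibration absorbs the constant), and
an over-convex fold flattens through a four-vertex stencil: the two
vertices receiving the individual face-normal pulls and the remaining pair
receiving the opposite mean-normal push, which cancels exactly per edge.
Which two stencil vertices take the individual normals is configurable
(`bending_variant`): the default `"edge"` assigns them to the edge
endpoints, which is symmetric and restoring; the literal index reading of
the source description (`"printed"`) assigns one endpoint and one apex and
is retained for comparison. Both conserve linear momentum exactly; the sum
of all four force types over a closed mesh is zero to rounding error.

Near a pole the forces diverge by design — that stiffening *is* the model —
so nothing is clamped: strains within 1e-6 of a limit raise an error
naming the element, and the integrators bound the per-step displacement
instead.

## The spectrin-link comparison model

The coarse-grained spectrin-link model describes the cell by a free energy:
worm-like-chain (WLC) links, $U = \frac{k_BT\,l_m}{4p}\,
\frac{3r^2-2r^3}{1-r}$ with $r = l/l_m$ and maximum extension
$l_m = x_0 l_0$ ($x_0$ = 2.6); a repulsive per-triangle term $C_q/A^q$
(exponent $q = 1$) whose coefficient is chosen in closed form so the
equilateral lattice unit is an in-plane energy minimum; cosine bending
$\tilde\kappa\sum_i(1 - \cos(\theta_i - \theta_{0,i}))$ with
$\tilde\kappa = 2\kappa/\sqrt3$ (the triangular-lattice coarse-graining
constant; the literal $2\kappa/3$ variant is available as
`bending_prefactor = "two-thirds"`); and quadratic global volume, global
area and local area penalties ($k_V$ = 6000, $k_A$ = 5900,
$k_{Al}$ = 100, read as kBT/um^3 and kBT/um^2 — the sources do not state
units, which is flagged here as an interpretation). Forces are exact
analytic gradients, verified against central finite differences of the
energy to better than 1e-5 relative in the test suite; the dihedral-angle
gradient is differentiated exactly through its `atan2` form rather than
through small-angle shortcuts.

Two points deserve emphasis:

* The printed maximum-extension ratio "$r_0 = l_0/l_{max} = 2.6$" is
  impossible, since $r_0 < 1$ by definition; the only consistent reading,
  used here, is $l_m/l_0 = 2.6$.
* The per-face repulsion makes a reference shape an exact equilibrium only
  on uniform equilateral lattices. On the irregular biconcave template it
  leaves residual vertex forces of a few tenths of a pN. The default
  `inplane_repulsion = "edge"` therefore uses the source model's standard
  stress-free calibration — a per-edge power-law $k_{p,i}/l^2$ with
  $k_{p,i}$ fixed so each link is force-free at its own reference length —
  which makes *any* reference shape an exact critical point. The printed
  per-face variant remains available and its lattice equilibrium property
  is tested.

The cosine bending response is deliberately kept with its documented
weakness: the restoring force is sinusoidal in the angle deviation, peaking
near $\pi/2$ and decaying beyond, which is why this model loses stability
under strong folds where the strain-limited model stiffens.

Membrane viscosity is realized as a pairwise dissipative edge force
$-\gamma_t v_{mn}$ on relative vertex velocities ($\gamma_t$ mapped from
the quoted 22 mPa s through the lattice geometry; the mapping is
approximate and documented as such). It vanishes for rigid motion, is
active only in the fluid-coupled dynamics, and is excluded from
quasi-static relaxation, where it would only slow convergence: steady
states are force-balance states and independent of dissipation.

## Quasi-static dynamics

`dem_step()` is a damped explicit velocity-Verlet step with per-vertex drag
and a per-step displacement cap guarding the force poles; pinned vertices
and prescribed displacements are per-coordinate constraints whose reaction
is minus the accumulated model force.

`relax()` drives a state to equilibrium. The naive critically-damped
iteration turns out to be impractical for the strain-limited model: the
stiffness is strongly state dependent (the volume term near its pole is
four orders of magnitude stiffer than the soft bending modes), and a time
step tuned to the stiffest mode advances the soft ones by ~1e-4 of their
relaxation per step. Two standard remedies are used, chosen by model:

* the strain-limited model (no global energy exists — the bending stencil
  is not a gradient) uses FIRE-accelerated damped dynamics: the same
  Verlet step with adaptive step size, velocity–force alignment while the
  power $F\cdot v$ is positive, freezing when it turns negative, plus
  periodic numerical re-probing of the stiffest mode and backtracking when
  a trial step crosses a force pole;
* the spectrin model minimizes its free energy directly with L-BFGS-B
  (exact analytic gradients; external loads enter as a linear potential),
  which converges in a few hundred evaluations.

Both paths report the final maximum vertex force as the residual;
convergence is deterministic given identical inputs. The plain damped
iteration remains available (and tested, including its step-by-step energy
decrease) by specifying `dt` and `drag_coefficient` explicitly.

## Patch moduli: protocol and closed-form oracle

The elastic constants quoted for the model are extracted from the
elementary 7-vertex hexagonal patch (`make_patch(0.5)`) by three
quasi-static tests at ±1% strain (central differences), interior relaxed:

* **Uniaxial** — boundary x-coordinates imposed, boundary y free:
  $E_s$ = summed x-reaction of the loaded (x > 0) boundary vertices per
  unit patch width, taken as the corner-to-corner width $2L_0$, per unit
  strain. The lateral contraction of the free boundary gives a kinematic
  Poisson ratio as a cross-check.
* **Simple shear** — boundary pinned to $u_x = \gamma y$: $\mu$ =
  tangential boundary traction per unit length, evaluated through the
  areal reaction moment $\sum R_x y / A$ (the discrete virial stress,
  exact for a uniform stress state), per unit $\gamma$.
* **Isotropic dilation** — boundary scaled radially: $K$ = mean in-plane
  normal stress $\sum R\cdot x / (2A)$ per unit relative area change.

Because the patch is six equilateral triangles of springs, the small-strain
response has a closed form, which the tests use as an independent oracle.
Linearizing the link law gives an edge spring constant
$k = \frac{\kappa_l k_BT}{p}(1 + 1/\tau_l^2)/L_0 \approx 18.40$ pN/um, and
the area law a coefficient
$c_a = \frac{\kappa_a k_BT}{L_0}(1 + 1/\tau_a^2) \approx 0.50$ pN/um.
Solving the seven-vertex equilibria by hand yields
$\mu = k/\sqrt3$, $K = 2k/\sqrt3 + 2c_a/\sqrt3$ and
$E_s = 1.5k$ plus a small positive area-force correction. Numerically
(defaults): $E_s \approx 27.85$, $\mu \approx 10.63$,
$K \approx 21.83$ uN/m and $\nu = E_s/2\mu - 1 \approx 0.31$, against the
independently reported calibration values 27.82, 10.87, 21.88 and 0.29 for
this parameter set. The kinematic Poisson ratio is 1/3 — the classical
value of a central-force triangular lattice — and $(K-\mu)/(K+\mu)$ gives
0.35; the spread between the three estimates reflects the mild anisotropy
and finite size of a single hexagon, which is also why the moduli are
quoted with a generous tolerance rather than as sharp constants. Halving
the probe strain moves every modulus by far less than 1%, confirming the
linear regime.

## Optical-tweezer stretching

`tweezer_stretch()` selects the vertex sets at the two x-extremes whose
lumped (one-third face area) share reaches 5% of the membrane area each —
the silica-bead attachment patches — distributes ±F uniformly over them,
and relaxes to steady state, reporting axial and transverse diameters.
Force levels are solved in ascending order, each warm-started from the
previous solution, which keeps the transient strains away from the force
poles. With defaults the axial diameter grows 8 → 12.9 um and the
transverse shrinks 8 → 6.2 um over 0–150 pN, strictly monotone in both
directions, and doubling the contact area at fixed force moves the
diameters by under 5%.

## Force-bias packing

Dense randomized initial conditions use the enclosing ellipsoids of the
cells (RBC semi-axes 4, 4, 1 um — half the diameter and half the template
thickness; platelets 1.8, 1.8, 0.55 um) in a periodic box. Counts follow
the true-cell-volume hematocrit: at 46% in a 25 um cube,
$\lfloor 0.46\cdot 25^3/71\rfloor = 101$ RBCs and one platelet per ten
RBCs. Two scalars drive the process: $d_{in}$, the largest uniform scaling
with zero overlaps, computed exactly from the Perram–Wertheim contact
function (pairwise touching scale $\sqrt F$, minimized over all pairs with
minimum-image displacements); and $d_{out}$, initialized so the *union*
volume of the $d_{out}$-scaled ellipsoids (Monte-Carlo estimate, bisected)
equals the total enclosing-ellipsoid volume, then contracted by the rate
$\tau$ = 0.999 per iteration with a floor at 1 so that termination
($d_{out} \le d_{in}$) certifies an overlap-free configuration at true
size. Overlapping pairs at the $d_{out}$ scale are pushed apart along
their center line by the overlap-volume potential (Monte-Carlo, normalized
by the mean particle volume) plus a geometric de-overlap term — half the
center-line separation deficit — which keeps overlaps shallower than the
Monte-Carlo resolution active; larger cells move less (mass proportional
to the scaling radius), so RBCs displace platelets rather than the other
way around.

Orientation handling follows the two initialization modes. With fixed
alignments the dynamics are translation-only, and the packing converges in
under a hundred iterations (aligned ellipsoids pack like affinely scaled
spheres). With random orientations, translation-only dynamics *jam* near
$d_{in} \approx 0.94$ — well below the target — under every step-size,
force-law and annealing variant we tried; frozen crossed oblates lock.
Randomly oriented cells therefore also rotate toward larger pair
clearance (gradient ascent on the Perram–Wertheim contact scale), the
natural completion of a mode whose whole point is randomized alignments,
and convergence returns to ~100–130 iterations at 46% hematocrit on every
seed. All randomness is drawn from one named seed; identical seeds give
identical configurations.

## Fluid coupling

The plasma is a D3Q19 BGK lattice-Boltzmann fluid with Guo forcing and
halfway bounce-back at solid nodes (moving walls carry the standard
momentum correction); default spacing dx = 0.5 um matches the membrane
resolution, and the time step follows from the relaxation time through
$\nu = (\tau - \tfrac12)\,dx^2/(3\,dt)$. Plasma viscosity defaults to
1.2 mPa s at density 1.025 pg/um^3, the same fluid inside and outside the
membrane. Couette flow between opposing moving walls is reproduced to
machine precision and body-force-driven Poiseuille flow to better than
0.1% on 20 nodes; both checks pin down the viscosity mapping.

Membrane and fluid exchange information through the Peskin 4-point kernel:
velocity interpolation (exact for uniform flows, by the partition of
unity) advects the vertices, and force spreading conserves the total force
exactly. Two numerical safeguards matter:

* *Transmembrane-flux projection.* A kernel-smeared membrane is weakly
  permeable. With a quasi-incompressibility force as stiff as this model's
  ($\tau_v$ = 0.01), the feedback loop "interior pressurizes → fluid seeps
  through the surface → vertices advect outward → volume error grows" is
  unconditionally unstable — reducing the time step twentyfold does not
  cure it, only delays it. The coupled stepper therefore projects the net
  volumetric flux out of the interpolated vertex velocities each step (a
  uniform normal correction, leaving all tangential and deformation
  components untouched), the standard divergence-correction remedy for
  immersed closed membranes. Volume drift over a full shear run is then at
  rounding level, and the volume force handles genuine deformation-induced
  changes only.
* A density guard aborts a run when the local deviation exceeds 5%
  (compressibility error), and any membrane strain reaching a pole aborts
  with the shear rate in the message.

`shear_cell()` places the cell at the center of a wall-driven shear
(symmetry axis along the velocity gradient, in the shear plane and normal
to the flow) and records the maximal diameter and deformation index
$DI = ((D_{max}/D_0)^2-1)/((D_{max}/D_0)^2+1)$ with $D_0$ = 7.82 um.
Desk-scale honesty: at plasma viscosity the experimental steady
deformation at 17–200 1/s lies seconds of physical time away (the
ektacytometric steady state involves many membrane relaxation times and
tank-treading periods), which is far beyond a single-CPU LBM budget at
dt ~ 1e-8 s. The runs here (default 32 x 20 x 26 nodes, 0.25–0.5 ms
simulated) capture the early deformation response; its *ordering* in shear
rate — the property asserted by the tests — is strict and deterministic
across 17, 50, 100, 200 and 1500 1/s, while the DI magnitudes remain far
below the experimental plateau values and are not compared against them.
At 1500 1/s the strain-limited model completes the run with no face
inversion and volume drift at rounding level, the regime where the
sinusoidal bending response of the spectrin model is known to fail.
`channel_cell()` drives the cell through a cylindrical (staircase
bounce-back) channel of 12 um diameter toward the parachute regime; at
desk scale the tests assert shape axisymmetry, volume conservation and the
unperturbed limit in a wide slow channel rather than the full parachute
development.

## Interfaces and reproducibility

Meshes read and write OFF, ASCII PLY and legacy VTK POLYDATA (0-based
indices on disk, 1-based in memory); packed populations export to CSV
(type, center, quaternion) with an optional VTK point cloud.
`run_experiment()` dispatches any experiment from a serializable
configuration and writes a manifest (resolved settings, seed, package
version) beside the outputs; `inst/cli/rbcdem` is a thin shell front-end
over it with subcommands `make-cell`, `patch-moduli`, `tweezer`,
`shear-cell`, `channel-cell` and `pack`. Every stochastic path consumes
exactly one named seed.

## Known limitations

* Thermal fluctuations, inter-cell adhesion and aggregation, cytoplasmic
  viscosity contrast and adaptive remeshing are out of scope.
* The bending-stencil vertex assignment and the per-face repulsion of the
  spectrin model are genuinely ambiguous in their sources; both readings
  are implemented and the defaults documented above.
* The smallest-curvature bookkeeping of the bending limit
  ($r_{min} = L_0/(2\sin(\tau_b/2))$ gives 0.97 um at the working
  resolution, not the 0.18 um sometimes quoted with it); $\tau_b = \pi/6$
  is used as stated.
* Collective transport observables (apparent viscosity versus vessel
  diameter, cell-free layers, cluster break-up) require thousands of cells
  and are deliberately not reproduced; the packing and coupling layers are
  designed so they would not need to change.
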
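# rbcdem

Discrete-element mechanics of red blood cell (RBC) membranes, with the
calibration experiments, a dense-suspension initializer and a minimal
fluid coupling. The package is aimed at computational biomechanics work on
cellular blood rheology: building and validating membrane constitutive
models at the single-cell level, and generating artifact-free initial
conditions for dense RBC/platelet suspensions.

## What it implements

A cell membrane is a closed triangulated surface (the RBC template has
N_v = 642 vertices, N_e = 1,920 edges, N_t = 1,280 faces on a biconcave
Evans–Fung shape calibrated to 71 µm³). Two constitutive models act on
this mesh:

**Strain-limited model** (the primary model): four force types, each
linear at small strain and diverging at a material limit τ,

    F_link   = −(κ_l dL/p)  [1 + 1/(τ_l² − dL²)]      per edge
    F_bend   = −(κ_b dθ/L0) [1 + 1/(τ_b² − dθ²)]      per interior edge
    F_area   = −(κ_a dA/L0) [1 + 1/(τ_a² − dA²)]      per face
    F_volume = −(κ_v dV/L0) [1/(τ_v² − dV²)]          global

with defaults κ_l = 15, κ_a = 5, κ_b = 80, κ_v = 20 k_BT and
τ_l = 3, τ_b = π/6, τ_a = 0.3, τ_v = 0.01 (platelets: κ_l, κ_a, κ_b ×10).

**Spectrin-link model** (the comparison model): a free energy of
worm-like-chain links, a repulsive per-triangle term with closed-form
coefficient C_q, cosine bending 2κ/√3 Σ(1 − cos(θ−θ₀)), and volume/area
penalties, with exact analytic vertex forces.

Around the models: quasi-static relaxation (`relax`), optical-tweezer
stretching (`tweezer_stretch`), membrane-patch moduli extraction
(`patch_moduli`), force-bias packing of ellipsoid cell proxies
(`init_population`, `pack_cells`), and a D3Q19 lattice-Boltzmann solver
with Peskin 4-point immersed-boundary coupling for a single sheared or
channel-driven cell (`shear_cell`, `channel_cell`). Meshes are exchanged
as OFF / ASCII PLY / legacy VTK.

See the methods vignette (`vignettes/membrane-models.Rmd`) for the models,
their assumptions, the numerical choices and the known limitations.

## Worked example

Membrane-patch calibration of the strain-limited model — the elastic
moduli of the elementary hexagonal patch at the working resolution
L0 = 0.5 µm:

```r
library(rbcdem)
patch <- make_patch(0.5)
patch_moduli(patch)
#> patch moduli: E_s = 27.853 uN/m, mu = 10.626 uN/m, K = 21.833 uN/m, nu = 0.311
#>   (kinematic nu = 0.345, (K-mu)/(K+mu) = 0.345)
```

E_s is the surface Young modulus from uniaxial stretching, mu the shear
modulus, K the area-compression modulus and nu = E_s/(2 mu) − 1; healthy
RBC membranes measure E_s ≈ 25–50 µN/m, mu ≈ 6–10 µN/m and
K ≈ 18–20 µN/m, so the default stiffnesses sit at the physiological
calibration point.

Optical-tweezer stretching of the full template:

```r
tmpl <- make_rbc_template(cell_template_spec())   # 642 vertices, 71 um^3
tweezer_stretch(tmpl, forces = c(0, 50, 100, 150))
#>   force axial_diameter transverse_diameter converged   residual
#> 1     0        8.00000            8.000000      TRUE 5.2e-12
#> 2    50       10.15486            7.397396      TRUE 4.9e-02
#> 3   100       11.62472            6.779558      TRUE 4.8e-02
#> 4   150       12.85649            6.178526      TRUE 4.5e-02
```

The axial diameter grows and the transverse diameter shrinks monotonically
with the stretching force, as in the bead-stretching experiments.

Dense randomized initial conditions at physiological hematocrit:

```r
ip <- init_population(domain = 25, hematocrit = 0.46, seed = 1)
pk <- pack_cells(ip$population, ip$state)
#> (converges in ~120 iterations)
pk$converged    # TRUE : d_in >= 1, zero overlaps at true cell size
pk$hematocrit   # 0.4637 -- 101 RBCs + 10 platelets in a 25 um box
```

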
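---
title: "A multiscale, multi-resolution agent-based model of glioblastoma growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale, multi-resolution agent-based model of glioblastoma growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(glioscale)
```

## The model

glioscale simulates glioblastoma (GBM) expansion as a hybrid
discrete-continuum system with three coupled scales:

* **Intracellular.** Each cell carries an 11-species EGFR signalling
  state: glucose `X0` (inert), free TGF$\alpha$ `X1`, free EGFR `X2`, the
  ligand-receptor complex `X3`, its dimer `X4`, the phosphorylated dimer
  `X5`, free PLC$\gamma$ `X6`, the receptor-PLC$\gamma$ complexes `X7` and
  `X8`, phosphorylated PLC$\gamma$ `X9` and its inactivated form `X10`.
  Dynamics are mass-action for the nine reversible steps and
  Michaelis--Menten for the two phosphatase reactions,
  $v_4 = V_4 X_5/(K_4+X_5)$ and $v_8 = V_8 X_9/(K_8+X_9)$. (One published
  form of the second phosphatase rate reads as a product
  $V_8 X_9 (K_8+X_9)$; we implement the quotient, by symmetry with $v_4$
  and because $V_8$ has units nM/s — the product form would have units
  nM$^3$/s.) The scheme conserves three moieties exactly — total receptor
  $X_2+X_3+2(X_4+X_5+X_7+X_8)$, total PLC$\gamma$
  $X_6+X_7+X_8+X_9+X_{10}$, and total ligand $X_1+X_3+2(X_4+X_5+X_7+X_8)$
  — which is the main correctness audit of the integrator. Dimer-bearing
  complexes are weighted by two receptors and two ligands; this assumes
  `X5` (and the downstream complexes formed from it) retain the dimer
  stoichiometry, which the dimerisation-then-phosphorylation ordering of
  the scheme implies.

* **Intercellular.** A cell is migratory, proliferative or quiescent.
  The phenotype decision compares the cell's percentage rate of change of
  phosphorylated PLC$\gamma$ (`X9`) per simulated hour against the mean
  rate `Avg` of all cells deciding at that step: strictly above the mean
  means migrate, at or below means proliferate (a transient PLC$\gamma$
  signal drives motility; a smooth one drives division). A cell never
  migrates and divides in the same step (the migration--proliferation
  dichotomy). Movement and daughter placement use the attraction rule
  $T = \psi E + (1-\psi)\,\varepsilon$, $\varepsilon \sim N(\mu,\sigma^2)$,
  over free Moore-neighbour nodes, with search precision $\psi = 0.7$.

* **Tissue.** TGF$\alpha$ diffuses on the fine lattice following
  $\partial Y/\partial t = D \nabla^2 Y - U + S$, with per-node uptake and
  secretion maps rebuilt from the cell population each step. The solver is
  a Peaceman--Rachford ADI scheme whose implicit sweeps are Thomas solves
  batched across grid lines, optionally decomposed into overlapping tiles
  advanced by alternating-Schwarz iteration.

The scales meet at three interfaces: the pathway fixes the phenotype, the
phenotype reshapes the occupancy and the source maps, and the field feeds
back into each cell's free-ligand pool `X1` before every hour of
intracellular integration (ligand is *transferred*, not copied: what the
cells absorb is removed from the field).

## The dual-resolution lattice

Cells live on a fine lattice (10 µm spacing, one node per cell diameter)
nested in a coarse lattice of $r\times r$ blocks. A coarse site whose
block is fully occupied is *dense*; a dense site whose eight neighbours
are all dense is *homogeneous* and its cells are frozen — no pathway
integration, no decisions — contributing only aggregated uptake/secretion
as one big "cell". Everything else occupied is *heterogeneous*: the
active rim where all intracellular computation is spent. Freezing is
reversible: cells re-activate the moment their site is reclassified.

The reference coarse spacing of 62.5 µm (the smallest hemocytometer unit)
implies a non-integer nesting ratio of 6.25 against the 10 µm fine grid;
sub-node alignment is undefined on a lattice, so the package requires an
integer ratio and defaults to $r = 6$ (a 60 µm coarse cell), configurable.
"Topographic neighbourhood" is read as the 8-connected Moore
neighbourhood, with a 4-connected mode behind a flag.

## Parameters and defaults

Kinetics and initial concentrations default to the standard literature
values carried by `egfr_kinetics()` and `pathway_state()` (free ligand
9010.55 nM, receptor 100 nM, PLC$\gamma$ 10 nM, complexes zero; glucose
25 mM appears in no kinetic equation and is carried inert). The tissue
parameters are *not* fixed by the source model and are documented
placeholders, all config-exposed:

| parameter | default | why |
|---|---|---|
| `diffusion$D` | 1e-7 cm²/s | typical small-protein diffusivity in tissue |
| `diffusion$secretion` | 0.05 nM/s per cell | autocrine source strong enough to shape gradients within hours |
| `diffusion$uptake_rate` | 0.001 /s | first-order uptake proportional to local concentration |
| `diffusion$substeps`, `sub_dt` | 6 × 600 s per hour | keeps source terms resolved below the cell-decision timescale |
| `attraction$psi` | 0.7 | established search-precision value |
| `attraction$sigma` | 0.1 × local mean concentration | scale-aware sensing noise; an absolute σ is also accepted |
| `cycle$interval` | 12 h | "several time steps" per cycle; one decision per interval |
| `coupling$conversion` | 1 | field and pathway both in nM |
| `init` | disc of radius 5, Gaussian field peaked off-centre (fraction 0.75, 0.75) | seeding geometry is unreported; a radially symmetric source off the tumour gives a directional gradient |

`Avg` as printed is circular (the switching cohort is only known after
comparing to `Avg`); it is resolved as: the cohort is *all cells whose
cycle clock expires this step*, and `Avg` is their mean `X9` rate, so each
decision is relative to the cohort mean. A lone decider therefore always
proliferates. An empty cohort yields `Avg = 0` and no decisions.

Other open points, decided once and exposed: daughters inherit a copy of
the parent's pathway state (reset-to-initial mode behind
`daughter$inherit = FALSE`); cells never die (the homogeneous core is
quiescent, not necrotic); migratory cells move one node per step (≈10
µm/h); cell update order is re-randomised each step from a seeded stream
to avoid raster artefacts; percentage rates are per hour (one step).

## Numerical choices

* **Pathway integrator.** Fixed-step classical RK4 (compiled), default
  micro-step 0.01 s against a 3600 s horizon per simulated hour. RK4
  preserves linear invariants exactly, so the moiety totals drift only at
  roundoff (≈1e-13 relative over an hour; the package asserts 1e-6).
  Tiny negative overshoot (≤1e-9 nM) is clamped to zero and counted;
  larger undershoot or non-finite values abort with advice to reduce `dt`
  — the full initial condition has a fast binding transient
  (λ ≈ k₁X₁ ≈ 27/s), which bounds the stable step near 0.1 s.
  Inside the engine the default micro-step is 0.1 s: coupled cells take
  their `X1` from the tissue field (tens of nM, not 9010), the stiffest
  remaining rate is the dimer phosphatase (V₄/K₄ = 9/s), and λ·dt ≈ 0.9
  sits well inside the RK4 stability region while keeping a 100-hour,
  ~10³-cell run in minutes. Duration must be a multiple of `dt`, which
  makes results independent of how a horizon is partitioned across calls.
* **Diffusion.** Peaceman--Rachford ADI; each half step adds
  $(S-U)\,dt/2$ (diffuse-then-react within the half step; alternatives
  differ at $O(dt^2)$). Zero-flux edges use the reflected, symmetric
  Laplacian, so the implicit solves conserve mass to roundoff; a
  Dirichlet-zero mode is available. Uptake can overdraw a nearly-empty
  node within one sub-step; negative nodes are clamped to zero and
  counted (`n_clamped`, also reported per step by the engine). The
  shipped solver test configurations produce no clamping; a full tumour
  run clamps occasionally at freshly colonised nodes, by construction of
  the explicit source term.
* **Schwarz tiling.** Tiles extended by `overlap` nodes solve the same
  half-step equations with Dirichlet data taken from the current global
  iterate (old-time values for explicit parts, latest intermediate/new
  estimates for implicit sweeps), swept in row-major order `iterations`
  times. Its fixed point is exactly the monolithic ADI solution, and the
  strictly diagonally dominant sweeps make the iteration contract, so the
  deviation falls monotonically with overlap and iterations; a 1×1 layout
  is bitwise identical to `adi_step()`. Convergence per sweep slows as
  the diffusion number $D\,dt/dx^2$ grows — the equivalence tests run at
  $D\,dt/dx^2 = 10$, where overlap 2 and 3 sweeps reach 1e-4.
* **Ties and ordering.** Target selection breaks attraction ties by the
  lowest (row, column); sensing-noise draws follow that same fixed
  neighbour order; one base seed derives the `init` and `actions` streams
  by fixed offsets, so runs are bitwise reproducible and checkpoint
  cloning (`gbm_clone()`) resumes exactly.

## What the synthetic conditions do and do not show

No external data enter the model: kinetics come from the literature
table, and the fixture generator supplies the initial tumour (a filled
disc of proliferative cells), the chemoattractant profile (Gaussian), and
the solver test fields (eigenmodes, bumps, random occupancies). Default
run conditions follow the reported protocol — 100 steps of one hour,
default 10 replicates with derived seeds, a 20×20-site coarse lattice
(120×120 fine for the integer ratio 6) as used in the package's own
checks.

Passing tests therefore demonstrate internal correctness — conservation,
convergence order, solver equivalence, classification against brute
force, behavioural invariants, determinism — and the qualitative
morphology (a heterogeneous rim around any homogeneous interior; two
phenotype curves whose crossings the analysis layer detects). They do not
validate against real tumours: the tissue parameters $D$, $U$, $S$, the
seeding geometry and the cycle length are unreported in the source
material, so quantitative trajectories (e.g. specific crossing times near
$t = 27$ and $36$, or heatmap magnitudes) are not reproducible targets and
are deliberately not asserted. Hardware speed-up factors are likewise out
of scope; the Schwarz solver is validated for equivalence, not wall-clock
gain.

## A short run

```{r, eval = FALSE}
cfg <- gbm_config(steps = 24, replicates = 2,
                  lattice = list(shape_high = c(60L, 60L)),
                  init = list(tumor_radius = 3))
run <- gbm_run(cfg)
glance(run)
autoplot(run)                       # population curves
find_crossings(population_series(run))
switch_profiles(run$replicates[[1]]$switch_events)
render_figures(run, "figures/")    # PNG + CSV pairs
```

Problem sizes in the shipped tests are chosen to exercise every contract
at desk scale: 15–26-step engine runs on 36–60-node lattices for the
behavioural invariants, one 100-step run at the default 120×120 lattice
for the tumour-morphology check, 128×128 grids for the PDE benchmarks,
and 3600 s at `dt` 0.01 s for the conservation audit.

## Known limitations

* 2D only; one chemoattractant species; no cell death, mechanics,
  adhesion or compression.
* Explicit RK4 is deliberately simple; a pathway variant much stiffer
  than the shipped kinetics would need smaller `dt` rather than an
  implicit solver.
* The homogeneous-core speed-up changes the computed biology by design:
  frozen cells skip pathway time entirely (their clocks do not advance
  while frozen).
* The Schwarz solver is sequential here; the tile contract (tiles may be
  advanced concurrently within one sweep) is what a parallel backend
  would exploit.
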
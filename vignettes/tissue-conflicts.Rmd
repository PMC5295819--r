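---
title: "Tissue conflict resolution on a growing canvas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue conflict resolution on a growing canvas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuecanvas)
```

# The model and its assumptions

`tissuecanvas` treats a growing tissue as a continuous triangulated sheet
(*canvas*) with two surfaces, A (adaxial, +z at construction) and B
(abaxial), and a per-vertex thickness. Three ingredients drive a
simulation:

1. **Specified growth.** A growth-regulatory network (KRN) maps regional
   factor levels to growth rates `Kpar`, `Kper` (in-plane, relative to the
   local polarity, per surface) and `Knor` (thickness). Rates are
   fractional rates per hour and compound exponentially: over a step `dt`
   each element's *rest metric* is stretched by `exp(K dt)` along and
   across its polarity. Rates may be negative (contraction). The KRN
   grammar supports constants, factor references, `+ - * /`, the
   regulatory primitives `pro(x, f) = 1 + x f` and
   `inh(x, f) = 1/(1 + x f)`, threshold indicators `(f > c)` (0/1 valued),
   `&`, and `pos()` clipping. Expressions are stored as parsed R language
   objects evaluated in a sealed environment, so evaluation is pure and
   serialisation is exact (`deparse`/`parse` round-trips).

2. **Polarity.** A diffusible polariser (POL) is produced and degraded at
   organiser regions; each element's polarity is the unit tangent along
   the down-gradient direction (from "+" toward "−" organisers). The
   polariser is solved as a steady screened-diffusion profile on the mesh
   (cotangent stiffness matrix, lumped mass, Dirichlet organisers).
   Polarity may be *frozen* per surface, in which case the element keeps
   its material direction (stored in edge-basis coordinates, hence
   advected exactly). Elements whose POL gradient falls below 1e-9 of the
   canvas mean are flagged and grown isotropically at the same areal rate
   for that step.

3. **Mechanics.** Quasi-static elastic relaxation after each growth
   increment. The energy is a two-layer discrete shell:

   * per triangle and per surface, a plane-stress St-Venant–Kirchhoff
     membrane density on `E = (C - G_s)/2` (realised vs rest edge Gram
     tensor), weighted by rest area and half the thickness, with Poisson
     coupling ν = 0.3 and unit Young modulus (only ratios matter for
     quasi-static shapes);
   * per interior edge, hinge bending `k_b (θ − θ0)²` with
     `k_b ∝ h³/12` and a spontaneous dihedral `θ0` computed from the A/B
     rest-length differential across the hinge, so differential surface
     growth produces spontaneous curvature with the faster surface on the
     convex side.

   This is the standard equivalent of a literal two-offset-layer membrane
   (the design sketched in the original framework): the mean A/B metric
   drives the membrane, the differential drives bending. It is far more
   robust to discretise and its gradients are local. Gradients are
   assembled from per-element central finite differences of the exact
   energy (step 1e-5 of the mean element scale; error O(eps²) ≈ 1e-10
   relative), so the energy expression is the single source of truth.
   The minimiser is Polak–Ribière conjugate gradients with Armijo
   backtracking: monotone in energy, no injected randomness — buckling
   direction is selected only by the initial curvature or the seeded
   height noise of the canvas, and flat-start runs flip buckling direction
   across seeds.

**Conflict diagnosis.** The growth tensor of an element over a step is the
in-plane deformation gradient `F` (the deformed element is first
parallel-transported back by the minimal rotation aligning normals, so the
in-plane rotation is measured rather than absorbed into a frame choice),
polar-decomposed `F = R U`: strain rate `log(U)/dt`, rotation rate from
`R` plus the normal tilt. Specified growth has no rotational part;
*residual strain* is resultant minus specified strain. A conflict-free run
(uniform specified growth, free sheet) gives residual strain and rotation
at solver tolerance (~1e-7), which is the baseline against which conflict
models generate rotations at 1e-2–1e-1 rad/h.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| square canvas side | 100 | µm | scale of the published square models (figures show sheets a few hundred µm across carrying ~20 clones) |
| initial thickness (squares) | 2 | µm | thin plate, h/L = 2%: the depicted sheets are thin, and the buckling threshold strain ~(h/L)² must lie below the printed rate differentials |
| strip canvas | 1060 × 120 | µm | printed wedge dimensions |
| initial cap sagitta | 1% of short side | µm | "slight curvature"; biases buckling direction |
| flat-start z-noise | 0.1% of side | µm | seeded, uniform; symmetry breaking for flat starts |
| target edge length | short side / 30 (production), coarser in tests | µm | remeshing by longest-edge bisection when any edge exceeds 2× target |
| Poisson coupling ν | 0.3 | — | convention (not printed) |
| relax tolerance | 1e-6 relative energy change | — | with FD-gradient noise ~1e-10 this converges reliably |
| dt | 1 | h | rates ≤ 0.1/h, so per-step stretches ≤ 10% |
| JUN/RIM stripe width | 10% of side | — | domains shown only graphically |
| signal diffusion lengths | sjun/srim 5% of side; sRAD 100 µm; sRIM 12 µm; vein signals 40 µm | µm | chosen so the printed qualitative extents hold (e.g. sRIM > 0.01 a few cell widths around RIM; sRAD grading across the hinge) |
| division threshold | 2× initial mean cell area | µm² | not printed; keeps cell sizes within a factor 2 |
| wall shortening | 10% length reduction, endpoint travel ≤ 12% of wall length | — | "shortened slightly"; the cap keeps daughter areas in [0.35, 0.65] |
| PinPoint band radius / window | 5 px / 30 px | px | printed values |

Run lengths: the published square models carry no durations. Growing
models default to 15 h (linear size roughly doubles at Karea = 0.1/h,
matching the depicted growth). The size-preserving (contraction) family
defaults to 10 h: its dome is established by ~2 h and, with Karea = 0,
nothing further develops, while residual elastic compression accumulates
slowly without bound as the directional incompatibility grows
exponentially; at 10 h all four models hold |area change| < 2% with domes
over 5% of the side.

Two printed values are kept verbatim although mutually inconsistent: the
square models state `Knor = 0.044` while the wedge models state thickness
growth "0.44 %/h" (0.0044/h). The catalogue stores each model's own value
and does not reconcile them.

# The synthetic-data generators

`gen_pin_stack()` emulates two-channel whole-mount images: Voronoi
polygons of a jittered grid are the cells; the wall channel marks
boundary bands; the PIN channel concentrates a fraction `edge_frac` of
each cell's signal on the boundary arc facing that cell's true angle,
distributing it per angular bin symmetrically about the target direction
(so the noise-free vector sum points at the specified angle regardless of
cell shape), plus Poisson shot noise and Gaussian read noise
(SNR = arc intensity / read-noise σ). What it does **not** emulate:
out-of-focus light, a point-spread function (no PSF convolution),
signal bleed between neighbouring membranes, segmentation error, or
z-stack ambiguity — so a green recovery test establishes correctness of
the vector-sum estimator and its noise robustness, not performance on
real confocal data.

`gen_cell_grid()` provides the four initial cell geometries of the
cell-file simulations (near-square, elongated, oblique, irregular).
Shapes 1–3 carry 5% seeded vertex jitter — real initial cells are never
exact polygons, and exact squares make the shortest-wall rule degenerate
(all orientations tie); shape 4 carries 25%. Cell-file growth is applied
as the exact affine map per step, since uniform specified growth is
conflict-free; cells are passive markers with no mechanical feedback.

`gen_perturbed_sheet()` is the seeded flat-start canvas used by the
buckling-direction seed sweeps.

# Numerical choices and degenerate inputs

* **Tie-breaks.** Equal-minimal division chords: smallest angle to the
  x-axis wins (the angle scan starts at 0 and accepts only strict
  improvements). Karea = 0 under areal normalisation: the constant is
  split equally between Kpar and Kper and the element is flagged.
* **Wall shortening** slides each endpoint along its parent wall in the
  length-reducing direction (bounded Newton steps); when the new wall
  meets its parents near-perpendicularly, sliding cannot shorten it and
  the wall is left as found.
* **Remeshing** is longest-edge bisection with exact rest-metric
  inheritance (`G_child = Bᵀ G B` for the child-to-parent edge map), so
  refinement introduces no spurious elastic energy; vertex fields are
  interpolated linearly, clone ids and frozen polarity are inherited.
* **Degenerate elements** (zero area) abort tensor decomposition with an
  error; empty diffusion sources warn and return a zero field; erosion
  that empties a mask returns the whole mask as band, with a warning.
* **Region recipes** extend membership half an edge length beyond nominal
  bands so thin stripes (RIM, vein lines) stay non-empty at coarse test
  resolutions.

# Design choices where the source was open

* The elastic model, moduli, solver, and all mesh-level numerics are this
  package's own (the source framework defers them to its cited
  implementation); the discrete-shell decomposition above is the main
  such choice.
* The size-preserving areal model prints rates 0.019/0.032 and states the
  parameters were chosen to keep canvas size constant; the `icentre`
  profile radius is therefore calibrated at set-up so the area-weighted
  mean of `iedge` equals 0.019/0.032 (the profile shape, not the printed
  rates, is the free parameter).
* The orthogonal-conflict ablations of the wedge models remove the
  phase-II interactions that build the orthogonal pattern (the sRIM/sLAT
  promotions and inhibitions); the exact membership of that set is read
  from the network summaries and recorded in the catalogue source.
* The windowed PIN field *sums* vectors per tile (as the procedure is
  described); a `mode = "mean"` option exists.

# Known limitations

* The shell is elastic and quasi-static: no plasticity, no inertial
  dynamics, no explicit cellular mechanics (turgor, wall anisotropy).
  Post-buckled configurations under sustained incompatibility accumulate
  residual compression (StVK softens under compression), which is why the
  size-preserving models are specified-area-preserving but only
  approximately resultant-area-preserving over long runs.
* Signals and the polariser are solved at steady state and then fixed
  (as in the modelled system after set-up); there is no transient
  signalling dynamics.
* Full-corolla geometry and its inherited factor domains are out of
  scope; the corolla growth equations are covered only as DSL parser
  fixtures.
* Mesh-level convergence: the catalogue defaults and tests run at coarse
  resolution for speed; quantitative outputs (dome heights, clone
  statistics) at those resolutions carry discretisation error of a few
  percent, and the convergent polarity field on a square deviates from
  radial by up to ~9° near the corners, a real boundary effect.

Every quantitative claim above is recomputed by the test suite
(`tests/testthat/`, with `test-acceptance.R` holding the acceptance
criteria) or by `scripts/acceptance.R`; the vignette states no result they
do not compute.
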
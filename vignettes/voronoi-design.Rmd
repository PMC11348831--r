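---
title: "Cube-bounded Voronoi scaffolds: model, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cube-bounded Voronoi scaffolds: model, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(voroscaffold)
```

## The model

voroscaffold generates and analyses porous scaffold designs built as
three-dimensional Voronoi tessellations bounded by a cube. A design is
specified by a single integer parameter `G`: the number of generating points
placed independently and uniformly at random inside a cube of side `L`
(100 model units by default). Each point owns the region of the cube closer
to it than to any other point; the resulting convex cells tile the cube
exactly. The wireframe of the tessellation — the union of all cell edges —
is the scaffold: a strut network suitable for 3D printing in tissue
engineering applications.

Four structural parameters summarise a wireframe:

* `V` — number of distinct vertices,
* `E` — number of distinct edges (struts),
* `epsilon` — mean strut length,
* `chi = V - E + F` — the Euler characteristic of the cell complex.

For non-degenerate uniform seedings these follow tight laws in `G`:

* `V ≈ 5.45 G − 8.53` and `E ≈ 10.89 G − 21.10` (linear),
* `epsilon ≈ L · G^−0.45` (power law; a calibrated prefactor of
  `101.41 · L / 100` is also provided),
* `chi = 1 + G` exactly, a combinatorial identity of cube-bounded
  tessellations in general position, along with `E = 2V − 4` and a vertex
  degree histogram of exactly eight degree-3 vertices (the cube corners)
  and `V − 8` degree-4 vertices.

Inverting these gives the package's design equations: given a target
vertex count, strut count, mean strut length or Euler characteristic taken
from real tissue (lymph node conduits, trabecular bone, tumour
microvasculature), `g_from_vertices()`, `g_from_edges()`,
`g_from_edge_length()` and `g_from_euler()` return the `G` to print.
Predictions are rounded half-up; the first three routes carry expected
mean absolute deviations of about 1, 1 and 3 respectively over the tested
ranges, while the Euler route is exact on clean structures.

## The pipeline

```{r, eval = FALSE}
pose <- sample_pose(13, seed = 42)        # 13 uniform points in the cube
trace <- relax(pose, lambda_max = 25)     # Lloyd iterations toward a CVT
metrics <- measure(trace$final_complex)   # V, E, F, epsilon, chi
write_wireframe(extract_wireframe(trace$final_complex),
                "scaffold.stl", format = "stl")
```

`relax()` applies Lloyd's algorithm: each point moves to the centroid of
its cell and the tessellation is rebuilt. This drives the seeding toward a
centroidal Voronoi tessellation (CVT), evening out cell volumes and strut
lengths — desirable for printability — while typically shedding a few
vertices and edges. Across any transition where neither endpoint has
degenerate short edges, the drop obeys `ΔE = 2ΔV`
(`lloyd_delta_audit()` verifies this on recorded traces).

## Numerical methods

**Tessellation.** Each cell is computed by clipping the cube, represented
as a convex polyhedron, by the perpendicular-bisector half-space of every
neighbouring point, in order of increasing distance. A security-radius
criterion stops early: once the next neighbour is farther than twice the
radius of the ball containing the current cell, no further plane can cut
it. This makes the cost per cell nearly independent of `G` and keeps the
clipping exact with respect to the cube boundary (no mirror-point
approximation). The core is implemented in C++.

**Clipping tolerance.** A vertex is classified as on-plane when its signed
distance is within `1e-10 · L`; intersection points are computed once per
cut polyhedron edge and shared between faces so that adjacent cells
reproduce bit-identical vertices.

**Wireframe deduplication.** Cell-local vertices are merged by a
union-find sweep with tolerance `1e-9 · L` (comfortably above clipping
noise, far below any genuine strut length), edges by their merged vertex
pair, and faces by their canonical merged-vertex loop so interior walls
are counted once. Under this counting the identities `chi = 1 + G` and
`E = 2V − 4` hold exactly for structures in general position.

**Degeneracy diagnostics.** Nearly coincident Voronoi vertices produce
struts too short to print and break the counting identities. `measure()`
flags edges shorter than `1.5e-4 · L` (0.015 units at `L = 100`, an order
of magnitude below the shortest genuine struts seen at `G = 300`);
structures with `short_edge_count > 0` are reported but excluded from
identity checks. `check_topology()` reports the three invariants
explicitly.

**Relaxation energy.** The CVT (quantisation) energy
`sum over cells of the integral of |x − p_i|^2` is evaluated in closed
form by tetrahedral decomposition of each cell (exact second moments of
convex polyhedra), so its monotone decrease under Lloyd iteration can be
asserted to round-off (`1e-10` relative) rather than to Monte-Carlo
noise. A seeded Monte-Carlo estimator (`cvt_energy_mc()`) is retained as
an independent cross-check.

**Convergence.** `relax()` declares a CVT when the largest point
displacement falls below `displacement_tolerance · L` (`1e-6` by
default). Because fixed-iteration ensembles must be comparable across
poses, all `lambda_max` iterations are performed unless
`early_stop = TRUE`.

## Statistical choices

* **Ensembles** (`run_ensemble()`) derive one sub-seed per structure from
  a single master seed via a multiplicative congruential mix, keeping
  every seed below 2^31 and the whole ensemble reproducible from one
  integer.
* **Refitting** (`fit_linear()`, `fit_powerlaw()`) aggregates to per-`G`
  means before ordinary least squares (log–log for the power law), so
  heavily replicated small-`G` cells do not dominate the fit;
  `aggregation = "per_structure"` is available for comparison. Fits carry
  `tidy()` and `glance()` methods.
* **Deviation reports** (`deviation_report()`) are computed
  per-structure by default — each structure's rounded prediction compared
  to its true `G` — with a per-`G` aggregated alternative.
* **Case studies** (`case_study()`) rebuild the three worked examples:
  lymph-node conduits (`V = 65`), trabecular bone (`E = 1388`) and tumour
  microvasculature (`epsilon = 35` at `L = 150`). Each predicts `G`,
  generates an ensemble at the predicted value (100 structures and 25
  Lloyd iterations by default) and, optionally, at neighbouring values to
  show the prediction separates from its neighbours.

## What the generator emulates, and what it does not

The package generates *designs*, not tissues: uniform random seeding plus
Lloyd relaxation is a model of how scaffold candidates are produced for
printing, and the design equations map measured tissue parameters onto
that model. Mechanical properties, printing constraints beyond strut
length, anisotropy and spatially graded porosity are out of scope. The
linear and power laws are empirical over the tested ranges
(`V` in 25–1700, `E` in 45–3400, `epsilon/L` in 0.07–0.55, `chi` in
6–301 at `L = 100`); the predictors warn when extrapolating.

## Interface conventions

Tabular results are tibbles; `measure()` output has a `tidy()` method;
traces, ensembles and case studies have `autoplot()` methods. A command
line interface (`cli_main()`, wrapped by `exec/voroscaffold`) exposes
`generate`, `relax`, `measure`, `predict`, `ensemble`, `fit`,
`case-study` and `export` subcommands over the same functions. Structures
round-trip losslessly through a native JSON format; wireframes export to
OBJ, PLY and watertight beam-solid binary STL (units recorded in a JSON
sidecar, since STL carries none).
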
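---
title: "Modeling whole-tumor microvascular hemodynamics, oxygen transport and heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling whole-tumor microvascular hemodynamics, oxygen transport and heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculr)
```

vasculr treats a tumor's microvasculature as a geometric graph — nodes with
3D positions, segments with a diameter and a centerline length — and asks
three questions of it: how does blood flow through it, how much oxygen does
that flow deliver, and how heterogeneous is the resulting functional
landscape. This vignette documents the models, their assumptions, the
tunable parameters, and the numerical and design choices behind the
implementation.

## The blood flow model

Each segment obeys the generalized one-dimensional Poiseuille law

$$Q_{ij} = \frac{\pi D_{ij}^4 \, (P_i - P_j)}{128\, \mu_{ij} L_{ij}},$$

with mass conservation $\sum_j Q_{ij} = 0$ imposed at every junction. The
working units are µm (length), mmHg (pressure), µl/s (flow) and cP
(viscosity); the single conversion constant is documented in the source.
Assembling the junction balances gives a sparse symmetric linear system in
the nodal pressures, solved directly; pressure boundary conditions enter as
Dirichlet rows, measured flow conditions as right-hand-side injections
(inflow positive, with at least one pressure anchor per connected
component).

Blood is not Newtonian at these scales. Three empirical laws close the
model, with all coefficients stored in `rheology_params()` so alternative
calibrations can be swapped:

* **Apparent in-vivo viscosity** (Fahraeus–Lindqvist effect plus the
  endothelial surface layer): a diameter- and hematocrit-dependent
  relative viscosity with the characteristic steep rise below ~10 µm from
  the $(D/(D-1.1))^2$ layer term. At zero hematocrit it reduces to
  plasma viscosity times that geometric factor.
* **Fahraeus law**: tube (resident) hematocrit $H_T$ falls below discharge
  (flow-weighted) hematocrit $H_D$ in narrow tubes; the ratio tends to 1
  in large vessels.
* **Phase separation (plasma skimming)**: at a diverging bifurcation the
  red-cell flux fraction entering a daughter is a logit-linear function of
  its fractional blood flow, skewed by the daughter/sibling diameter ratio
  and steepened by low feed hematocrit, with pure-plasma thresholds at
  fractional flows below $0.4/D_f$ (µm).

The coupled steady state is computed as a fixed point: viscosities from
the current hematocrit field, pressures and flows from the linear system,
hematocrit re-routed through the new flow field, under-relaxed (factor
0.5) until the pressure and hematocrit fields change by less than $10^{-4}$
(at most 200 outer iterations). Hematocrit routing processes nodes in
descending-pressure order — a topological order of the flow digraph, since
flow strictly follows the pressure gradient — so red-cell flux is
propagated in one sweep per outer iteration, exactly conserved at every
junction.

Derived per-segment quantities follow algebraically: velocity
$u = 4Q/(\pi D^2)$ (mm/s), wall shear stress $\tau = 32\mu Q/(\pi D^3)$
(dyn/cm²), transit time $vstt = \pi D^2 L/(4Q)$ (s), and per network the
flow-weighted mean path length $MPL = \sum Q L / \sum Q$ (µm).

### Boundary pressures

Whole-tumor networks reconstructed from imaging carry no measured boundary
data. `optimize_boundary_pressures()` classifies boundary (degree-1) nodes
by the diameter of their attached vessel, initializes pressures by linear
interpolation in log-diameter between a venous and an arterial anchor
(defaults 10 and 30 mmHg), and applies damped global corrections until the
relative inflow–outflow imbalance is below $10^{-3}$. With pure pressure
boundary conditions the global balance is structural — the nodal solve
already conserves mass — so in practice the loop terminates at its
initialization; the machinery matters when the imbalance definition or
boundary types change. Networks with complete measured boundary data (such
as a microvascular network with measured inlet flows and hematocrits)
bypass the optimization entirely.

## The intravascular oxygen model

Oxygen is carried dissolved in blood and bound to hemoglobin. Along each
perfused segment the drop in advected oxygen content equals the transmural
flux:

$$Q_b \left( \alpha_b \,\Delta P + H_D\, C_{bind}\, \Delta S_{Hb} \right)
  = J_{wall},$$

with the blood solubility a tube-hematocrit blend
$\alpha_b = H_T \alpha_{RBC} + (1 - H_T)\alpha_{pl}$ and the saturation
given by the Hill curve $S_{Hb}(P) = P^n/(P^n + P_{50}^n)$ ($n = 2.7$,
$P_{50} = 37$ mmHg, $\alpha_{pl} = 2.82\times 10^{-5}$ ml O₂/ml/mmHg).
The model deliberately excludes extravascular diffusion: the tissue is
partitioned into domains proportional to segment length, and each segment's
wall flux is a fixed share of the total tissue demand,

$$J_{wall,ij} = M_c\, m_{tissue}\, \frac{L_{ij}}{\sum L_{ij}},$$

applied only to segments that transport significant oxygen ($H_D > 0.01$
and $vstt < 25$ s). The normalization $\sum L$ runs over eligible segments
by default, so the delivered total equals $M_c\, m_{tissue}$ exactly; a
switch (`normalize_eligible_only = FALSE`) selects the all-segments
alternative. The consumption rate $M_c$ (ml O₂·g⁻¹·s⁻¹) has no defensible
universal default and must always be supplied; $m_{tissue}$ defaults to
tissue density (1 g/ml) times the network's tumor volume. The red-cell
solubility ($3.38\times10^{-5}$) and binding capacity (0.5 ml O₂/ml RBC)
defaults are standard textbook values, not tied to a particular
calibration.

### Numerical formulation

Node tensions are the unknowns. Each junction balance takes the upstream
node's composition for every incoming segment (upwind advection) and the
node's own tension for outgoing segments; at outlet (inflow-only) nodes
the exiting composition is carried by the inflow segments themselves, so
the per-segment content-drop identity is exact on single-inflow
topologies and holds in flux-weighted aggregate at converging junctions.
Summing all balances telescopes into the global identity (advected in −
advected out = total wall flux), which the test suite verifies to
$10^{-8}$ relative.

The hemoglobin term dominates the dissolved term by roughly three orders
of magnitude, so a naive iteration that lags $S_{Hb}$ outside the matrix
diverges. The solver instead quasi-linearizes the Hill term through its
secant slope $\sigma = S_{Hb}(P)/P$, placing both dissolved and bound
transport coefficients inside the system matrix and refreshing $\sigma$
each sweep (with under-relaxation 0.5 on the tension update) until the
tension change falls below the tolerance ($10^{-10}$ by default). Because
advective weights span many orders of magnitude across a tumor network,
rows are equilibrated by their diagonal before each solve; the live flow
graph is acyclic (flow follows pressure), so the system is structurally
triangular and well-behaved after scaling. Tensions that would go negative
— oxygen demand exceeding what the local supply can deliver, a real
feature of tumor cores — are clamped to zero with a warning; the
undelivered share then appears in the global balance residual, which is
reported rather than hidden. Segments below the perfusion floor
($10^{-10}$ µl/s) advect nothing and are excluded; vascular pockets not
fed by any inlet are reported as `NA`.

## Morphometry maps

Three voxel-grid maps summarize vascular geometry the way volumetric
imaging studies report it, on a lattice centered on the network bounding
box (voxel-center world coordinates, µm):

* **$D_v$** — exact 3D Euclidean distance from each voxel center to the
  nearest vessel voxel center, on the fine grid (8 µm default). A voxel is
  a vessel voxel iff its center lies within $D/2$ of a segment centerline.
  The distance transform is the exact two-parabola-envelope algorithm,
  implemented in compiled code and verified against brute-force search.
  The distance is voxel-center to vessel-voxel-center (not to the analytic
  centerline), matching the stated map resolution.
* **$L_v$, $S_v$** — vascular length (mm/mm³) and lateral surface area
  (mm²/mm³) densities: each segment's length and $\pi D L$ surface are
  distributed over the fine voxels its centerline traverses (supersampled
  at a quarter of the voxel pitch, so totals are conserved exactly), then
  aggregated over 20×20×20-voxel box windows (160 µm regions at the
  default pitch), normalized by the in-bounds window volume to avoid rim
  artifacts. Summing density times window volume recovers the network
  totals to $10^{-6}$ relative — a test invariant.

The scalar `morphology_summary()` adds the vascular volume density
$\sum \pi D^2 L / 4$ over the tumor volume.

## Vessel niches and heterogeneity

Perfused vessels ($Q \ge 10^{-10}$ µl/s) are classified into four niches.
Shunts are tested first because their criteria can co-occur with the
hyperperfused class: velocity at least twice the median, diameter at least
twice the median, and length at most half the median (medians over the
same network's perfused vessels). Otherwise Class 1 is hypoperfused and
hypoxic ($u < 50$ µm/s and $PO_2 < 10$ mmHg), Class 2 hyperperfused and
normoxic ($u \ge 50$ µm/s and $PO_2 \ge 10$ mmHg), and Class 3 the two
mixed quadrants. Descriptions of Classes 2 and 3 are swapped in parts of
the literature; this package follows the convention carrying the explicit
inequalities (Class 2 = hyperperfused + normoxic) throughout.

Heterogeneity is quantified by the coefficient of variation (sample
standard deviation over mean — the sample convention is a deliberate,
documented choice for small ensembles) per parameter per network,
Pearson-correlated across networks with two-sided p-values. Ensembles are
clustered with UPGMA (unweighted pair-group averaging) on Euclidean
distances between z-scored per-network median features — z-scoring is
essential because the features mix units — and the cophenetic correlation
between tree-implied and original distances is flagged when at or below
0.8. Group comparisons use the two-tailed Mann–Whitney U test at
$\alpha = 0.05$. The flat-cluster threshold (count `k` or height `h`) is a
free parameter.

## The synthetic network generator

`make_tumor_like()` exists so that every solver and statistic is testable
without imaging data. It emulates the features of tumor vasculature that
the downstream analyses are sensitive to:

* a dense vascularized **rim** over a sparse **core** (node density boosted
  threefold, by default, in the outer 25% shell of the sphere);
* **positively skewed diameters** (log-normal, median 10 µm, sigma 0.5,
  smoothed along vessels by averaging node-level sizes);
* **loopy topology**: a minimum spanning tree over the sampled nodes,
  every interior tree leaf closed by an edge to its nearest non-neighbor
  (tumor networks do not end blindly at the resolution modeled here), plus
  short random loop edges up to the exact requested segment count;
* **pendant boundary vessels** on the surface, with pressures interpolated
  in log-diameter between the anchors (or no boundary data at all, to
  exercise the optimizer).

Identical seeds give byte-identical networks. What the generator does
*not* emulate: angiogenic growth dynamics, curved centerlines (lengths are
chords times a tortuosity factor, 1.1 by default), image noise,
segmentation artifacts, and the specific morphometry of any real tumor.
Passing tests on these networks therefore demonstrates correctness of the
solvers and statistics under controlled conditions — not that a particular
biological tumor is reproduced.

## Parameters that matter

| Parameter | Unit | Default | Source |
|---|---|---|---|
| `n_hill` | — | 2.7 | literature standard |
| `p50` | mmHg | 37 | literature standard |
| `alpha_pl` | ml O₂/ml/mmHg | 2.82e-5 | literature standard |
| `alpha_rbc` | ml O₂/ml/mmHg | 3.38e-5 | textbook value, configurable |
| `c_bind` | ml O₂/ml RBC | 0.5 | textbook value, configurable |
| `m_c` | ml O₂/g/s | **required** | experiment-specific |
| `hd_min`, `vstt_max` | —, s | 0.01, 25 | transport-significance filters |
| `inlet_hematocrit` | — | 0.45 | systemic hematocrit |
| arterial/venous anchors | mmHg | 30 / 10 | free parameters (no measured data) |
| velocity / PO₂ class cuts | µm/s, mmHg | 50, 10 | literature definitions |
| perfusion floor | µl/s | 1e-10 | perfused-vessel filter |
| fine grid / window | µm | 8 / 160 | map resolutions |

The analyses in the test suite and acceptance script use 100–400-segment
synthetic networks, 20 randomized ≤50-segment networks for the dense-solve
oracle, grids up to ~32³ for exact distance-map checks, and 10-network
ensembles over 100 seeds for the clustering property — sizes chosen to
exercise every code path at interactive runtimes.

## Known limitations

* No extravascular oxygen diffusion: tissue $PO_2$ fields cannot be
  derived, only intravascular oxygenation indices.
* Constant wall flux per unit length per segment; a transport-matched
  local flux would require the extravascular problem.
* Steady state only; no pulsatility, vessel adaptation or remodeling.
* The phase-separation law is empirical for bifurcations; higher-degree
  divergences are handled by recursive flow-ranked pairwise application,
  which preserves red-cell flux exactly but inherits the law's
  bifurcation-scale calibration.
* Rasterization treats segments as straight capped cylinders; vessels
  thinner than the voxel pitch can miss all voxel centers and vanish from
  the mask (the density maps, which conserve totals by construction, do
  not suffer this).
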
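---
title: "Vertex-model mechanics of disordered epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-model mechanics of disordered epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivertex)
```

## The model

epivertex implements a planar vertex model of a confluent epithelial
monolayer. The tissue is a network of straight-edged polygonal cells whose
degrees of freedom are the junction (vertex) positions; in the interior
every junction is a trijunction. Each cell $\alpha$ with area $A_\alpha$ and
perimeter $L_\alpha$ carries the dimensionless mechanical energy

$$U_\alpha = \tfrac12 (A_\alpha - 1)^2 + \tfrac12\,\Gamma\,(L_\alpha - L_0)^2,$$

after scaling lengths on the square root of the preferred cell area. The
first term is bulk (cytoplasmic) area elasticity; the second is the cortical
perimeter spring, with contractility $\Gamma > 0$ and preferred perimeter
$L_0 = -\Lambda/2\Gamma$ set by the line tension $\Lambda$ (adhesion versus
cortical contraction). An additive constant $\Lambda^2/4\Gamma^2$ per cell is
dropped; it does not move any force. Two caveats about $L_0$ are worth
stating explicitly because printed values in the source literature are not
mutually consistent on this point: this package uses $L_0 = -\Lambda/2\Gamma$
*everywhere* (energy, forces, stress, moduli, cubic roots), which is the
value implied by differentiating the energy above; a convention with twice
this preferred perimeter (equivalently, a per-edge rather than per-cell line
tension) changes every density-dependent prediction, notably the zero-load
cell density discussed below.

Vertices feel minus the gradient of the total energy. For a vertex $i$ of
cell $\alpha$ the restoring force is

$$\mathbf f^i_\alpha = -P_\alpha\,\mathbf p^i_\alpha + T_\alpha\,\mathbf q^i_\alpha,
\qquad P_\alpha = A_\alpha - 1,\quad T_\alpha = \Gamma\,(L_\alpha - L_0),$$

with $\mathbf p^i = \tfrac12(\mathbf R^{i+1}-\mathbf R^{i-1})\times\hat{\mathbf z}$
and $\mathbf q^i = \hat{\mathbf t}^i - \hat{\mathbf t}^{i-1}$ built from the
anticlockwise edge tangents. Net vertex forces sum these contributions over
the (three) incident cells. Out of equilibrium, vertices move against a
substrate drag proportional to the areas of the incident cells
(`step_overdamped()`); at equilibrium all net vertex forces vanish.

The stress tensor attributed to a cell is

$$\boldsymbol\sigma_\alpha = -P^{\rm eff}_\alpha\,\mathsf I
  + T_\alpha\,\mathsf J_\alpha - \tfrac12 \dot{\mathsf S}_\alpha,
\qquad
P^{\rm eff}_\alpha = P_\alpha + \frac{T_\alpha L_\alpha}{2A_\alpha},$$

where $\mathsf J_\alpha = A_\alpha^{-1}\bigl(\tfrac12 L_\alpha \mathsf I -
\sum_i l^i\,\hat{\mathbf t}^i\otimes\hat{\mathbf t}^i\bigr)$ is traceless and
the rate-of-shape term $-\tfrac12\dot{\mathsf S}$ is included only when
vertex velocities are supplied — it vanishes at the equilibria the package
mostly works with, which is why the equilibrium pipeline treats it as zero.
The implementation satisfies, to $10^{-10}$ or better and verified in the
test suite: symmetry of $\boldsymbol\sigma$,
$\mathrm{Tr}\,\boldsymbol\sigma = -2P^{\rm eff}$,
$\mathrm{Tr}\,\mathsf J = 0$, the geometric identities
$\sum_i \mathbf R^i\otimes\mathbf p^i = A\,\mathsf I$ and
$\sum_i \mathbf R^i\otimes\mathbf q^i = -\sum_i \hat{\mathbf t}^i\otimes\mathbf t^i$,
and agreement of $\boldsymbol\sigma$ with the virial form
$A^{-1}\sum_i \mathbf R^i \otimes \mathbf f^i$.

### Stress-shape alignment: what holds and what does not

A cell's shape tensor $\mathsf S = Z^{-1}\sum_i \mathbf R^i\otimes\mathbf R^i$
(centred vertices, arithmetic-mean centroid — the convention under which
$\sum_i \mathbf R^i = 0$ exactly) is often stated to share its principal
axes with $\boldsymbol\sigma$ at equilibrium. In this implementation that
coaxiality is *exact* for mirror-symmetric cells (rectangles, kites,
trapezoids, regular polygons) and *statistical* for generic equilibrium
cells: on relaxed disordered monolayers the median axis deviation is of
order $10^{-2}$ rad, with a tail up to roughly $10^{-1}$ rad, and it does
not shrink as the force residual is driven from $10^{-6}$ down to
$10^{-13}$. We therefore treat exact coaxiality as a symmetry property, not
an equilibrium identity, and report the axis deviation per cell
(`stress_shape_alignment()`, `cell_table()$alignment`). Because which stress
eigenvalue lies along the shape major axis flips with the sign of
$P^{\rm eff}$ (a compressed elongated cell carries its larger-magnitude
stress eigenvalue *across* the elongation), the deviation is measured to the
nearest stress axis, on $[0, \pi/4]$.

## Parameters and parameter space

* `lam` ($\Lambda$): dimensionless line tension. Negative values describe
  cortical-tension-dominated tissue; positive values strong adhesion.
* `gam` ($\Gamma$): dimensionless contractility, $\Gamma > 0$. Typical
  fitted values for embryonic epithelia are a few times $10^{-1}$.
* `p_ext`: isotropic external pressure on the monolayer boundary; positive
  values compress. Default 0 (an unloaded explant).

For a regular N-gon, $L = \mu_N\sqrt A$ with
$\mu_N = 2(N\tan(\pi/N))^{1/2}$, and the effective pressure reduces to the
closed form `peff_regular()`. Its zero in $A$ — a depressed cubic in
$\sqrt A$, solved analytically with discriminant classification so that root
coalescence near the bistable boundary is detected exactly — defines the
equilibrium areas $A_N^*$ and, through the hexagon case, the parameter-space
map (`classify_region()`): region I (soft, no shear resistance,
$\Lambda < -2\mu_6\Gamma$), IIa (single equilibrium), IIb (bistable,
$\Lambda > 0$ below the repeated-root curve) and III (collapse). The dagger
transform rescales $(A, \Gamma, \Lambda)$ by powers of $(1+P_{\rm ext})$ to
map loaded states onto unloaded equivalents; `pext_scan()` uses its inverse
to hold the unloaded-equivalent parameters fixed while the load varies.

Elastic moduli: the disordered bulk modulus is the area-weighted sum
implemented in `bulk_modulus()`; for the uniform honeycomb it reduces to
$K = A - \Lambda\mu_6/8\sqrt A$ and the shear modulus to
$G = 3\sqrt3\,\Gamma(1 - L_0/L)$. The shear form is the *instantaneous
(affine)* modulus: it matches an affine pure-shear experiment on the
honeycomb to machine precision, while releasing the honeycomb's internal
sublattice degree of freedom softens the measured response to exactly
two-thirds of it — the honeycomb shear modulus is a point on which
published derivations of this model family genuinely differ. No closed
form is attempted for the disordered shear modulus. The test suite checks
the hexagonal forms against independent finite-strain experiments (box
dilation of $\pm 0.5\%$ re-relaxed for $K$; affine pure shear of $10^{-4}$
for $G$, plus the relaxed-softening inequality).

## The simulation pipeline and what the generator emulates

`generate_monolayer()` reproduces disordered equilibrium packings:

1. **Seeding.** A Matérn type II hard-core process draws cell centres in a
   periodic square box sized so the mean cell area matches $A_6^*$ at the
   imposed load (the larger root in region IIb). The hard-core radius is
   not specified by the underlying study; the default, 60% of the mean
   nearest-neighbour spacing, is a realistic inhibition strength that
   avoids sliver cells while remaining trivially feasible, and it is
   configurable.
2. **Tessellation.** A periodic Voronoi diagram (3×3 tiling of the points,
   central tiles re-identified across the boundary) gives the initial
   network; generic point sets make every vertex a trijunction.
   Cocircular degeneracies are resolved by a logged $10^{-9}$-box
   perturbation and retry.
3. **Relaxation.** Quasi-Newton (L-BFGS-B) minimization with the analytic
   forces as gradient, converged on the maximum vertex force
   (default $10^{-6}$) — the force residual, not the energy change, is the
   physically meaningful criterion. An outer loop fires topological
   transitions one at a time, shortest trigger first, re-relaxing after
   each: T1 intercalation for edges below $0.1\sqrt{A_6^*}$ (the new edge
   is laid perpendicular at 1.5× the threshold so the transition does not
   immediately re-fire; the post-T1 length is not specified by the study)
   and T2 extrusion for triangles below $0.3 A_6^*$. A T1 on a triangle
   edge is refused in favour of the T2 check, since it would create a
   2-gon.
4. **Load enforcement.** The box and all vertices are rescaled
   isotropically — first step sized by the analytic bulk modulus, then
   secant iterations, re-relaxing each time — until the area-weighted mean
   effective pressure matches `p_ext` within $10^{-3}$ (the study calls
   this tolerance "prescribed" without stating it).

The generator emulates the *equilibrium packing statistics* of real
epithelia: polygon-class proportions, per-class area and circularity
distributions, and their response to density. It does not emulate curved
cell edges, cell division, growth or motility, active fluctuations,
heterogeneous cell mechanics, or segmentation noise — so tests passing on
generated monolayers validate the mechanics and the statistics of this
model class, not the fidelity of any particular experimental image.

Reproducibility: every stochastic step is seeded; the same seed gives
bit-identical networks. Realization seeds in `grid_fit()` are
deterministic functions of the base seed and the grid index.

## Fitting

`class_summary()` pools cells and normalizes areas by the population mean
(mirroring per-experiment normalization of the observed data);
`log_likelihood()` scores $-\ln\sum_{i=4}^{8+}|\bar A_i^{\rm obs} -
\bar A_i^{\rm sim}|^2$ over polygon classes 4–8+; `grid_fit()` maximizes it
over a region-II parameter grid. Three-sided cells, absent from the
observed data, are excluded from the likelihood but reported. A class
missing from the pooled simulation contributes its squared observed mean —
a maximal penalty, chosen so that degenerate simulations cannot win the
argmax. A residual sum below $10^{-12}$ is capped (flagged perfect fit) to
keep the surface finite.

## Numerical choices and degenerate inputs

* Periodic geometry stores canonical coordinates in $[0, L)^2$; each cell
  unwraps by a minimum-image walk around its cycle (offset of the first
  vertex fixed at zero), valid while every edge is shorter than half the
  box — guaranteed by construction for monolayers of many cells.
* Voronoi tile vertices are merged by union-find over four shifted
  quantization grids (cell size $4\times10^{-6}$ box), which guarantees
  identification of numerically coincident junctions without splitting
  genuine short edges (observed tile-vertex coincidence error is below
  $10^{-6}$ box; genuine Voronoi edges of hard-core seeds sit orders of
  magnitude above the threshold).
* Clockwise input cycles are reversed with a warning rather than rejected;
  concave cells are reported by `validate_network()` but are not fatal
  (mild transient concavity occurs during relaxation, and the shoelace
  area remains exact).
* Collinear (degenerate) polygons get circularity 0 and a flag; tensors
  with relative eigenvalue gap below $10^{-6}$ are treated as isotropic
  and excluded from axis statistics. Near-degenerate experimental
  segmentations are reported, not repaired.
* Stress eigenvalues are ordered by magnitude (the convention for stress
  classification); shape eigenvalues by value. The two conventions are
  deliberately kept distinct.
* The cell centroid is the arithmetic mean of vertices, not the area
  centroid: the shape-tensor identities above hold only under this
  convention.

## Problem sizes used by the tests and the acceptance script

The test suite runs desk-scale versions of every experiment: property
checks on 3×4–4×4 lattices and 24–100-cell monolayers; the moduli
cross-checks on 4×4 honeycombs and a 200-cell monolayer; the packing-trend
check at three densities of a 200-cell monolayer; and parameter
self-recovery on a 5×5 region-II grid with 200-cell, 2-realization
simulations against 200-cell, 3-realization synthetic data. The acceptance
script runs the full 800-cell zero-load pipeline at three seeds. The
full-scale likelihood surface (5 realizations × 800 cells per grid point)
is available through `grid_fit()` but is a long-running computation best
launched deliberately.

## Known limitations

* Exact stress-shape coaxiality does not hold cell-by-cell (see above);
  alignment is strong but statistical.
* Under the per-cell line-tension convention used throughout, the
  zero-load density of a disordered 800-cell monolayer at
  $(\Lambda, \Gamma) = (-0.1, 0.1)$ converges to a box width near 17.8,
  bounded above by the ideal-honeycomb value $\sqrt{800 A_6^*} = 18.9$
  (irregular cells have $L > \mu_Z\sqrt A$, which raises $P^{\rm eff}$ at
  fixed area and shrinks the equilibrium). A doubled preferred perimeter —
  the per-edge convention — would raise this to about 20.
* The fitted model reproduces per-class areas well but overestimates
  circularity; increasing `p_ext` narrows but does not close that gap
  (`pext_scan()`), consistent with the need for higher-order terms in the
  energy.
* Finite-patch dynamics (drag on two-cell boundary vertices) are
  implemented but flagged experimental; quantification of segmented images
  is geometric only unless parameters are supplied.
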
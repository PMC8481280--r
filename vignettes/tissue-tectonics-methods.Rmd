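---
title: "Tissue tectonics on a spherical embryo: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue tectonics on a spherical embryo: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuetectonics)
```

## The model

A gastrula-stage embryo is, to good approximation, a sphere: the blastoderm
is a thin shell of cells spreading over the yolk. Given tracked nuclei —
a table of `(track_id, t_min, x_um, y_um, z_um)` — the package quantifies
tissue-scale deformation as fields on that sphere.

The computation is a chain of local linear estimates:

1. **Geometry.** A sphere is fitted to each frame's cell positions by
   geometric least squares and the per-frame fits are averaged into one
   static geometry (center $c$, radius $R$). Analysis happens on the unit
   sphere ($r_0 = 1$); all tensor arithmetic stays in physical units
   (µm, min). The user supplies the anatomical axes: the anterior
   direction and the dorsal reference, from which elevation $\theta$
   (0 at the anterior pole) and azimuth $\varphi$ (0 on the dorsal
   meridian, anticlockwise seen from the anterior pole) are measured.

2. **Mesh.** The surface is discretized into $n$ near-equally spaced
   nodes (default $n = 2000$) using the spherical Fibonacci lattice,
   triangulated by the convex hull of the nodes. The lattice is
   deterministic, needs no iterative relaxation, and has a
   nearest-neighbour spacing CV of about 0.013 at $n = 2000$.

3. **Domains and velocities.** Per-cell velocities are finite
   differences at the acquisition interval (2 min by default): central
   differences in the track interior, one-sided at ends and beside
   gaps. Cells are grouped into overlapping spherical domains: cell
   $j$ belongs to node $i$ iff $\lVert x_j - (c + R\,\hat r_i)\rVert
   \le \rho$ with $\rho = 110$ µm, a radius small enough to resolve the
   spatial patterns of gastrulation yet large enough to hold tens to
   hundreds of cells. The domain velocity is the arithmetic mean of its
   members' velocities (reported only for $\ge 4$ members).

4. **Velocity gradient.** At each node and time the $3{\times}3$
   velocity-gradient tensor $L_{ab} = \partial v_a / \partial x_b$ is
   estimated by weighted affine least squares,
   $v(x) \approx v_0 + L\,(x - x_{node})$, over the member cells'
   individual velocities and 3D positions. Weights are Gaussian in
   distance with bandwidth $\rho/2$. The estimator is exact (to machine
   precision) for any globally affine field, whatever the sampling
   geometry, provided the sampled positions span 3D.

5. **Decomposition.** $L$ splits into the strain-rate tensor
   $\dot E = (L + L^\top)/2$ and the spin tensor
   $\Omega = (L - L^\top)/2$. $\dot E$ is projected on the local
   anatomical frame ($e_{AP}, e_{ML}, e_r$): diagonal projections are
   the A–P, M–L and radial strain rates; $\operatorname{tr}\dot E$
   is the local volume-change rate (the divergence); the radial curl is
   $2\,\omega \cdot e_r$ with $\omega$ the spin axial vector. The
   eigendecomposition of $\dot E$ is also returned, sorted descending,
   but the figures of merit are the coordinate projections.

6. **Windowed strain and kymographs.** Component rates are integrated
   (trapezoid) over sliding windows $[t - W/2,\, t + W/2]$, $W = 30$
   min by default, giving dimensionless strain per window — the
   quantity shown in maps and kymographs. Kymographs average the
   integrated component over annular bands (equatorial, or axial along
   the dorsal/ventral meridian; full angular span 0.38 rad) in 5°
   angle bins.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `domain_radius` | 110 | µm | domain size; smoothing scale of all fields |
| `window` | 30 | min | strain integration window; 40 for perturbation contrasts, where the signature needs a longer window to emerge |
| `min_cells_per_domain` | 4 | – | below this, domain quantities are missing |
| `pole_exclusion` | 0.05 | rad | polar caps where $e_{AP}, e_{ML}$ are singular; components flagged missing there |
| `ridge_epsilon` | 1e-9 | – | relative ridge on the normal equations; a failsafe, see below |
| `cond_max` | 1e8 | – | condition-number cutoff above which a fit is invalid |
| `half_span` | 0.19 | rad | kymograph band half-width |
| `angle_bin` | 5 | deg | kymograph bin width |

## Radial derivatives and `gradient_mode`

A velocity field sampled only on a spherical *surface* cannot constrain
radial derivatives — yet radial strain is reported. The default
`cell_regression` mode resolves this by regressing the *member cells'*
velocities on their full 3D positions: the blastoderm shell has finite
radial thickness (~30 µm, plus the sagitta of a 110 µm cap, ~17 µm),
and that radial spread identifies $\partial/\partial r$. The
alternative `node_field` mode reproduces the construction in which the
node-level mean field is differentiated: it regresses neighbouring
nodes' domain-mean velocities, reproduces tangential components, and
leaves radial derivatives ridge-dominated. It is provided for
comparison; `cell_regression` is the default and is what all validation
uses.

On regularization: the spatial normal-equations block for a thin shell
is anisotropic (tangential spread ≫ radial spread). A ridge large
enough to "stabilize" it also biases the radial column of $L$ by a
factor of order $\lambda/\sigma_{min}$. We therefore keep the ridge
negligible (`1e-9` relative) and instead *flag* badly conditioned fits
invalid via `cond_max`: missing is better than fabricated. With the
default geometry and ≥ 10 cells per domain, condition numbers are
$O(10)$ and the ridge never matters.

## Component-then-integrate

Strain components are projected in the instantaneous local frame at
each time and then integrated over the window, rather than integrating
tensors in a fixed frame and projecting afterwards. This matches how
the kymographs are built, and for strain magnitudes of order $10^{-1}$
per window the difference between the two orders is second-order.

Windows with missing interior samples are integrated over the covered
sub-intervals and rescaled by $W/\text{covered}$ when coverage is at
least 80%, otherwise reported missing. The rescaling keeps the
estimate unbiased for slowly varying rates under missingness (and makes
a constant rate $s$ integrate to exactly $sW$ regardless of gaps).

## The synthetic embryo

No tracked-nuclei dataset ships with the package; validation instead
uses a simulator whose flows have closed-form velocity gradients, so
every downstream number has an analytic oracle. Cells live on a shell
(radius 350 µm, thickness 30 µm), are advected by classical RK4 at the
2-min frame interval, and are *observed* with Gaussian noise —
the noise is added to reported positions only, keeping true
trajectories on the analytic flow so that estimator error is separable
from dynamical noise. Divisions spawn daughters at a 2 µm tangential
offset under new ids; dropout removes detections.

The flow vocabulary (local spherical components, amplitudes in µm/min):

- *epiboly*: $v_\theta = A_{ep}\sin\theta$ — spreading toward the
  posterior (vegetal) pole;
- *convergence*: $v_\varphi = -A_{conv}\sin\varphi\,\sin\theta$ —
  azimuthal flow toward the dorsal meridian;
- *extension*: $v_\theta = A_{ext}\,u\,
  e^{-u^2/2\theta_{ext}^2} e^{-\varphi^2/2\sigma_{ext}^2}$ with
  $u = \theta - \pi/2$ — meridional divergence from the dorsal
  equatorial region. The envelope in $u$ is a Gaussian rather than a
  hard angular window: a hard window would make the velocity
  discontinuous at its edge and the Jacobian undefined there, whereas
  the Gaussian keeps the field smooth with a closed-form gradient
  everywhere;
- rigid rotation $v = \omega \times x$ and radial expansion
  $v_r = k\,r$ (so $L = k\,I$), plus a constant drift term.

**Preset amplitudes.** `gastrula` uses $A_{ep} = 1.0$,
$A_{conv} = 0.8$, $A_{ext} = 2.5$ µm/min
($\sigma_{ext} = 0.5$, $\theta_{ext} = 0.6$ rad) — surface speeds of
order 1 µm/min on a 350 µm embryo, i.e. strain rates of a few
$10^{-3}$ min$^{-1}$ and window strains of a few percent to ~0.2.
The extension amplitude is set high enough that the dorsal meridian
has a stagnation point with meridional outflow (the saddle between
head and trunk territories): on the dorsal meridian the meridional
speed is $A_{ep}\cos u + A_{ext}\,u\,e^{-u^2/2\theta_{ext}^2}$, which
only has a root if $A_{ext} \gtrsim 2.3\,A_{ep}$; below that, epiboly
dominates everywhere and no saddle exists. `c59` (emulating Wnt
secretion inhibition, which abolishes extension but not convergence)
is identical except $A_{ext} = 0$.

The `rigid` preset uses $|\omega| = 0.001$ rad/min. This is chosen
so that temporal discretization does not confound the *spatial*
estimator checks: a 2-point central difference of a rotation sampled
every $\Delta t$ recovers velocities scaled by
$\operatorname{sinc}(\omega\Delta t)$, an irreducible error of
$2\omega(1 - \operatorname{sinc}(\omega\Delta t)) \approx
\omega^3\Delta t^2/3$ on the recovered curl. At 0.001 rad/min and
2-min frames this floor is $1.3\times10^{-9}$ min$^{-1}$, an order
below the $10^{-8}$ exactness tolerance the validation asserts.

**Initial placement.** Cells are placed uniformly at random on the
shell by default. A `fibonacci` option places them on a low-discrepancy
lattice; it exists because benchmarking the nearest-neighbour tracker
at "displacement below half the minimum inter-cell spacing" requires a
guaranteed minimum spacing, which random placement cannot provide (its
minimum spacing tends to zero with $n$).

**What the simulator does not emulate.** Flows are steady, smooth and
noiseless in their dynamics; real gastrulation flows are
non-stationary, have cell-scale granularity, and the real embryo
deviates from a perfect sphere. Segmentation artefacts (false
positives/negatives beyond simple dropout), lineage structure, and the
real embryo's absolute strain magnitudes are out of scope. Passing
validation therefore demonstrates correctness of the *estimators* under
known kinematics, not biological fidelity of any particular magnitude.

## Numerical choices

- Eigenvalues of $\dot E$ use the closed-form trigonometric solution
  for symmetric 3×3 matrices, vectorized over all nodes and times.
- Curl sign convention: positive = anticlockwise viewed from outside
  the embryo ($\mathrm{curl}_r = 2\,\omega\cdot e_r$); a `flip_curl`
  flag inverts it for comparison with the opposite convention.
- Kymograph bins are centred (the dorsal 0° bin spans ±2.5°); the
  ventral ±180° bin wraps circularly. Band averages are unweighted
  across domains, with per-bin domain counts reported.
- Degenerate gradient fits (rank < 3 spatial spread beyond the ridge,
  condition number above `cond_max`) are flagged `valid = FALSE`;
  their components are missing downstream, never zero-filled.
- The tracker breaks nearest-neighbour ties deterministically by row
  order (smaller id); its default `max_disp` is 3× the median per-frame
  displacement estimated from an unbounded first pass.

## Problem sizes

The validation suite runs the study-scale configuration: 2000 mesh
nodes, 110 µm domains, 5000 cells at 2-min frames for 120 min
(61 frames) with 1 µm observation noise for the `gastrula`/`c59`
scenarios, and noiseless 5000-cell scenarios for the affine-flow
exactness checks. Unit tests use smaller meshes (200–1000 nodes) and
cell counts where the property under test does not depend on scale.

## Known limitations

- Anatomical axis registration is an input; the package does not infer
  anterior/dorsal from image content.
- The embryo is modelled as a fixed sphere; ellipsoidal or time-varying
  geometry is not supported.
- `node_field` mode cannot produce trustworthy radial derivatives
  (surface-only sampling); use `cell_regression` when radial strain
  matters.
- Stress, stiffness and constitutive modelling are out of scope: the
  package measures kinematics only.
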
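---
title: "Reversible cortical-folding simulation and geometry-driven fibers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversible cortical-folding simulation and geometry-driven fibers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

cortexfold simulates cortical folding as a quasi-static, approximately
reversible mechanical process on a two-tissue tetrahedral mesh (a gray-matter
shell over a white-matter core). The tissue is a neo-Hookean hyperelastic
solid with energy

$$\Psi_{\mathrm{Neo}} \;=\; \underbrace{\tfrac{\lambda}{2}\,(\det F - 1)^2}_{\Psi_H}
\;+\; \underbrace{\tfrac{\mu}{2}\,(\operatorname{tr}(F^{T}F) - 3)}_{\Psi_D},$$

where $F = D_s D_m^{-1}$ is the per-tetrahedron deformation gradient
(current vs. rest edge matrices) and $\lambda, \mu$ the Lamé parameters.
The energy is maintained as two XPBD constraints per tetrahedron (the
stable-constraint split): a hydrostatic constraint $C_H = \det F - \gamma$
with compliance $\alpha_H = 1/(\lambda V_0)$ and a deviatoric constraint
$C_D = \sqrt{\operatorname{tr}(F^{T}F)}$ with $\alpha_D = 1/(\mu V_0)$.

Unfolding is driven by two scheduled surface constraint families:

* a **surface-area constraint** per cortical face,
  $C = \tfrac12\lVert (x_2-x_1)\times(x_3-x_1)\rVert - R$, whose rest area
  $R$ starts at the face area and decays geometrically
  ($R \leftarrow R\,(1 - r_A\,\mathrm{d}t)$ per step), applying tangential
  contraction near the surface;
* a **smoothing constraint** per pair of adjacent cortical faces,
  $C = \tfrac12\lVert (a+b) - (s_0+s_1)\rVert - L$, which moves the shared
  edge toward the plane of the opposite vertices as $L$ decays, biasing the
  solve toward smooth, globally area-reducing configurations (under fixed
  volume a sphere minimizes area).

**Viscoelasticity.** Brain tissue relaxes deviatoric stress over time. Each
step the rest matrix is blended toward the current pose,
$D_m \leftarrow (1-\kappa)D_m + \kappa D_s$ with
$\kappa = 1 - e^{-\beta\,\mathrm{d}t}$. Rest *volumes* are never updated, so
hydrostatic (volume) memory is permanent while shape memory decays at rate
$\beta$. $\beta$ is the single most consequential dial of the model: large
$\beta$ lets the tissue flow (fast unfolding, weak fold memory), small
$\beta$ preserves the elastic imprint of the folds that refolding needs. The
default ($\beta = 10^{-3}\,\mathrm{s}^{-1}$, with $3\times10^{-4}$ used in
the bundled round-trip experiments) was chosen once, on the slab round-trip
and a relaxation experiment on the 1 mm³ white-matter cube, so that
unfold-then-refold recovers the fold pattern while the cube shows the
qualitative exponential stress relaxation expected of brain tissue.

**Quasi-statics.** Viscous damping is infinite: there is no inertial
predictor, every substep starts from the current positions, and `dt` is
purely a schedule clock. Each outer step advances the schedules and runs
`substeps` Gauss–Seidel sweeps (tet pairs, then area, then smoothing
constraints, in fixed index order — deterministic by construction).

## Material parameters

| parameter | default | unit | note |
|---|---|---|---|
| `E_white` | 1895 | Pa | white-matter stiffness |
| `E_gray` | 1389 | Pa | gray-matter stiffness |
| `nu` | 0.48 | — | nearly incompressible |
| `density` | 1040 | kg/m³ | lumped per node from tet volumes |
| `visco_beta` | 1e-3 | 1/s | rest-pose relaxation rate |

Per-tet Lamé parameters come from the mean stiffness of the four nodes'
tissues, so mixed gray/white tets interpolate the two phases.

## Numerical design choices

Several choices were genuinely open and are recorded here.

* **Hydrostatic rest target $\gamma$.** The printed energy ($\gamma = 1$)
  carries a residual deviatoric traction at the rest pose: its minimizer is
  a state compressed by roughly $\mu/\lambda$ (4% volume at $\nu = 0.48$).
  For a single tetrahedron this is harmless and the solver reproduces the
  brute-force minimizer of $\Psi_{\mathrm{Neo}}$ to $10^{-8}$ relative. On
  meshes, however, driving a nearly incompressible lattice toward that
  compressed state through sequential per-element projections produces
  volumetric locking and checkerboard inversion. The stable-constraint
  formulation resolves this with the offset target
  $\gamma = 1 + \mu_{\mathrm{eff}}/\lambda_{\mathrm{eff}}$, which makes the
  rest pose an exact critical point of the element energy (zero first
  Piola–Kirchhoff stress at $F = I$). Mesh simulations therefore default to
  the rest-stabilized target (`sim_config(rest_stable = TRUE)`), while
  `rest_stable = FALSE` gives the plain printed energy (used for the
  single-tet solver-vs-minimizer validation, where it is stable).
* **Variational sweep.** Inside `run_simulation()` the multiplier updates
  use the compliant-limit denominator $\tilde\alpha$ instead of the
  canonical $\sum_i w_i\lVert\nabla_i C\rVert^2 + \tilde\alpha$, and each
  tetrahedron's hydrostatic/deviatoric pair is applied simultaneously from
  the same positions. A sweep is then an exact mass-preconditioned
  gradient-descent pass over the total constraint energy: forces of
  unequal-stiffness families balance exactly at critical points, and a
  satisfied rest state is stationary to machine precision. The exported
  single-constraint operations (`project_tet_constraint()` and friends)
  keep the canonical XPBD update.
* **Solver metric.** Under infinite damping, node masses only define the
  projection metric, never the equilibria. Masses are rescaled to mean 1
  inside the solver and inverse masses clamped at 4× the mean (boundary
  lattice nodes otherwise carry ~10× the mean inverse mass and destabilize
  sweeps); a per-projection displacement cap of 0.2× the mean element size
  guards transients. All three devices alter the path only: fixed points are
  unchanged.
* **Accuracy order.** Because $C_D$ never vanishes at equilibrium, the
  per-substep multiplier reset leaves a stale-gradient bias of order
  $\mathrm{d}t_{\mathrm{sub}}^2$; the single-tet validation uses
  $\mathrm{d}t = 0.05$ with 5 substeps, where the bias is below $10^{-8}$
  relative.
* **Schedules and compliances.** The paper-style tangential contraction is
  reproduced with geometric decay rates `rate_area = rate_smooth = 0.004`
  (0.005 in the bundled acceptance experiments), area/smoothing compliances
  of 0.005 (0.002 in the acceptance experiments, where stiffer surface
  constraints complete the unfolding schedule in a few hundred steps and the
  short schedule preserves nearly all viscoelastic fold memory), and tet
  compliance scales `scale_hydro = scale_dev = 100`. A
  common scale on all compliances rescales the total energy and leaves every
  equilibrium unchanged; it is chosen so that sweeps stay in the stable
  compliance-dominated regime. These mirror the role of empirically tuned
  stability parameters in the original formulation; none is a biophysical
  constant.
* **Boundary conditions.** A slab is not a closed body: side-wall nodes are
  pinned along their outward axis (symmetry planes of the extruded
  sinusoid) and bottom nodes in z. Area and smoothing constraints act on
  the cortical (top) faces only.
* **Refolding.** Refolding replays the recorded per-step rest-area and
  rest-distance targets in reverse, resuming from the unfold's final solver
  state (positions and relaxed rest matrices). Because the replayed schedule
  ends exactly when the targets reach their original values — before the
  mesh has finished relaxing toward them — `settle_steps` appends
  frozen-schedule steps that let the state equilibrate at the restored
  targets.
* **Gyrification index.** The paper-style stop criterion needs a GI for
  arbitrary bodies. For closed surfaces the envelope is the convex hull of
  the surface nodes (computed by an incremental 3-D hull); for slabs it is
  the flat projection of the cortical faces, $\sum_f A_f |\hat n_{f,z}|$,
  which stays valid while the slab deforms. The envelope type is recorded in
  the result's attributes.
* **Point location** snaps points within $10^{-6}$ (barycentric) of a face
  onto it; interior points reconstruct to $10^{-9}$ mm. Inter-snapshot
  interpolation of $\Phi_t$ is linear in displacement-normalized time.
* **Strain aggregation** averages per-fiber elongation ratios per voxel
  (ratio first, voxel average second); the alternative order (average
  lengths first) differs only where fibers of very different lengths share a
  voxel.
* **Primary peaks** per voxel are the principal eigenvector of the
  orientation tensor $\sum_i d_i d_i^T$ of unit segment directions — the
  standard sign-invariant estimator for axial data; eigenvalue ties within
  $10^{-6}$ are flagged ambiguous and excluded (and counted).
* **Radial fibers** integrate through the smoothed voxelized normal field
  with a fixed step; with zero smoothing iterations and a single step they
  reduce to strictly straight normal fibers, covering both readings of
  "straight fibers along local surface normals".

## What the synthetic geometries emulate — and what they do not

The folded slab is a 2.5-D idealization: a sinusoid in x extruded in y, with
a gray shell over a white core. Folds are 2.5-D so that the ground-truth
radial orientation field is *analytic* (the inward surface normal propagated
along straight normal lines, with the symmetric branch beyond focal
caustics), giving an exact target for the cosine-similarity evaluation. The
wavy sphere exercises the isoperimetric property of the surface constraints;
the 1 mm³ cube is the viscoelasticity calibration body.

The slab reproduces several brain-scale phenomena qualitatively: unfolding
to a target gyrification index with conserved volume, quasi-reversibility of
the deformation, straight radial fibers bending into fold-following
trajectories, and heterogeneous fiber strain organized by fold phase. Two
brain-scale findings do **not** transfer to this geometry, by construction
rather than by simulation error:

* *Gyri aligning better than sulci.* In the brain, the reference (diffusion)
  orientations beneath sulci are dominated by tangential U-fibers that
  radial-fiber simulations cannot capture, depressing sulcal scores. The
  slab's ground truth is the radial field itself, so sulcal voxels — where
  fibers stay nearly vertical under radial compression — match *best*
  (typical means ≈ 0.96 sulcal vs ≈ 0.88 under crowns, where material
  converging into the rising gyrus tilts fibers away from the analytic
  normal). The slab cannot exhibit the gyral>sulcal ordering without
  abandoning its own analytic ground truth.
* *Elongation concentrated on sulcal banks.* For a volume-conserving
  extruded sinusoid, the material column under a crown is taller in the
  folded state than in the flat state, and the column under a fundus is
  shorter; radial-fiber strain is therefore necessarily largest under crowns
  (≈ +0.1) and negative near fundi (≈ −0.2), with banks in between. The
  U-shaped positive-strain bands along sulcal banks seen at brain scale
  arise from adjacent gyri separating and stretching the inter-gyral
  tissue — a mechanism a single-wavelength slab with symmetric side walls
  excludes. The corresponding acceptance checks assert the brain-scale
  ordering and are expected to fail on this geometry; they are retained
  unchanged as a documented negative result.

Passing tests on the slab therefore demonstrate the correctness of the
machinery (solver, map, fibers, evaluation) and the qualitative folding
phenomenology, not fidelity to cortical surface statistics (curvature
spectra, sulcal depth distributions), which the generators make no attempt
to mimic.

## Problem sizes and tolerances

The bundled experiments use a slab of 16×3×6 mm with amplitude 2 mm and
wavelength 8 mm (A/W = 0.25, ≈ 20k tets, element size 0.45 mm), 1000 radial
fibers of up to 4 mm at 0.2 mm steps, and 0.325 mm isotropic evaluation
voxels; the wavy sphere uses radius 1 mm with 3 lobes of 0.15 mm at 0.2 mm
elements. Unfolding stops at GI ≤ 1.03–1.05 (checked at snapshots every 10
steps). Smaller variants of the same experiments power the unit tests.

## Known limitations

* No self-collision handling: fold separation relies on correct input
  meshing, as in the companion meshing work; contact is an extension point.
* Isometric whole-brain growth is ignored (it does not contribute to the
  deformation mapping).
* Whole-brain meshes at the published scale (~850k tets, ten million
  fibers) are outside the desk-scale scope exercised here; the machinery is
  the same, the constants are not re-validated at that scale.
* The cosine-similarity evaluation assumes grid-aligned fields; no
  registration is performed.
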
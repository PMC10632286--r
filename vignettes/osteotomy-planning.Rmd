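---
title: "Automatic osteotomy planning: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic osteotomy planning: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoplanr)
```

## The planning problem

A malunited forearm bone — a radius or ulna that healed in the wrong
alignment — is corrected surgically by cutting the bone (an osteotomy) and
repositioning the distal fragment. Because the deformity is usually
unilateral, the healthy bone of the opposite arm, mirrored across the
sagittal plane, serves as the reconstruction template. `osteoplanr`
implements a deterministic planning workflow on 3D surface models derived
from segmented CT or MRI:

0. Segmentation volumes are resampled to isotropic voxels and converted to
   triangulated surface meshes.
1. The deformed bone is rigidly aligned to the mirrored contralateral
   template.
2. Proximal and distal joint-end fragments are isolated (a terminal
   fraction of the bone's axial extent).
3. Each fragment is registered to its counterpart on the template by rigid
   point-to-surface ICP, giving two homogeneous matrices `M_prox` and
   `M_dist`.
4. A candidate cutting plane — a center point on the bone's centerline
   plus two tilts about the transverse axes of the bone-local frame — cuts
   the bone in two; the saved matrices reposition the fragments onto the
   template.
5. An exhaustive grid search over centerline stations and tilt pairs picks
   the plane minimizing the residual gap between the two osteotomy
   surfaces.

The realignment a surgeon must produce is the relative transform
`M = M_prox^-1 %*% M_dist`, decomposed into translations `(dx, dy, dz)`
and fixed-axis X-Y-Z Euler angles `(phi_x, phi_y, phi_z)` with totals
`T = sqrt(dx^2 + dy^2 + dz^2)` and `R = sqrt(phi_x^2 + phi_y^2 + phi_z^2)`.
Two planning variants of the same bone are compared by
`delta_T = |t_1 - t_2|` and `Phi_R = |phi_1 - phi_2|` (component-wise
Euclidean distances), and by plane descriptors: `delta_z`, the axial offset
of the cut from the proximal end, and two tilt differences `psi` about the
transverse axes.

## Conventions and numerical choices

**Euler convention.** Angles use the fixed-axis X-then-Y-then-Z convention
(`R = Rz %*% Ry %*% Rx`), with domains `phi_x, phi_z` in `[-pi, pi)` and
`phi_y` in `[-pi/2, pi/2)`; this is the convention whose middle-angle
restriction matches those domains. The convention is held in a single
constant in the source. Inputs within `1e-9` of the `|phi_y| = pi/2`
singularity raise a gimbal-lock error rather than silently splitting
`phi_x` and `phi_z` arbitrarily, which would corrupt `R` and `Phi_R`.

**Meshing.** Label volumes are iso-surfaced at the 0.5 level of each
label's indicator function by marching tetrahedra (six tetrahedra per grid
cube sharing the main diagonal, trilinear interpolation along cube edges).
This decomposition is face-consistent between neighbouring cubes and its
edge vertices are shared through a global edge table, so meshes are
watertight and consistently wound by construction. Marching tetrahedra
slightly over-tessellates compared to table-based marching cubes; volumes
agree with voxel counts to within a few percent at the working
resolutions.

**Resampling.** Labels are resampled as indicator functions with trilinear
interpolation and a 0.5 threshold; where several labels claim a voxel the
largest interpolated weight wins. The new lattice is edge-aligned with the
old one (it tiles the same physical block), which keeps voxel-counting
volumes unbiased.

**Registration.** ICP matches every moving vertex to its nearest point on
the fixed surface (a uniform spatial grid over triangles accelerates the
queries) and applies a closed-form rigid update per iteration: a
linearized point-to-plane solve, falling back to the Kabsch point-to-point
solution whenever the point-to-plane step would not decrease the RMS
residual. The residual is therefore non-increasing by construction, and no
random sampling is used anywhere, so registration is deterministic.
Defaults: fragment fraction 0.20 of the axial extent, convergence at an
RMS change below `1e-4` mm, at most 100 iterations, correspondence gating
at 10 times the current RMS.

Long-bone surfaces are nearly tubular, so registration has near-symmetric
local minima (azimuthal spins, end swaps, 180-degree flips). Three
deterministic countermeasures are built in. The initial whole-bone
alignment fans all four proper principal-axes sign combinations times
eight azimuthal rotations about the long axis, polishing each with a short
ICP on a whole-bone probe subsample; because a mid-shaft deformity can
make a flipped pose tie with the true one at whole-bone scale, the best
pose is returned together with up to two runner-up poses rotated more
than 60 degrees from it. Each fragment registration likewise starts from
a fan of eight azimuthal rotations about the target's long axis and keeps
the converged pose with the lowest residual. Finally, the pipeline
arbitrates among the initial candidate poses by the summed fragment RMS:
under the true pose the joint-end fragments reach the boundary-noise
floor, while under a flipped pose they stay visibly above it. All fans are
fixed candidate sets, not stochastic restarts.

When several segmentation variants of the same bone are compared, the
workflow's first step aligns them jointly. The study driver therefore
plans a reference variant with the full arbitration, aligns every other
variant onto the reference mesh (same-bone alignment is unambiguous
because the deformity is common to both sides), and hands the reference's
per-end registrations to the other variants as starting points, refined
within a small local fan and a 30-degree trust region. This matters
because an independently planned variant can settle in a globally spun
pose that its own fragments absorb consistently — the realignment's
rotation magnitude is invariant to such a spin, but its translation and
Euler components are not, which would corrupt every between-method
difference.

**Plane search.** The cutting plane is nominally six-parameter (a center
point and three rotations), but rotation about the plane normal is a
no-op, and the center is constrained to the centerline; the search
therefore iterates centerline stations and the two transverse tilts. The
default grid spaces stations every 2 mm over the middle 60% of the bone
(the registered joint ends are excluded) with tilts in [-45, +45] degrees
at 5-degree steps — about 13,000 nodes for a 120 mm bone, under half a
minute per bone; the cohort study driver uses a coarser grid (3 mm
stations, +/-30 degrees at 15-degree steps) to keep a three-variant,
ten-case study tractable. Step sizes are configuration,
not algorithm: any `search_grid()` can be passed, and the optimum is the
exact minimum over the given grid with a fully deterministic tie-break
(smallest distance from mid-shaft, then lexicographic in station and
tilts).

**Objective.** The default objective is the symmetric mean distance
between the two osteotomy surfaces after reconstruction — zero when the
fragments mate exactly. Cut faces are tagged during cutting so the
objective can address them; caps are fan-triangulated from a boundary
vertex, which adds no interior vertices (valid for the star-shaped
cross-sections of long-bone shafts) and makes the per-node search
objective identical to the capped-fragment objective. A volume-overlap
reward against the template is available with a configurable weight
(default 0); the weight is echoed in every report.

**Wedge classification and the secondary cut.** After reconstruction the
two cut faces form a wedge. If any part of the distal cut face penetrates
behind the proximal one the osteotomy is a closing wedge: bone must be
removed, and the secondary cut is the image of the primary plane under the
realignment transform. The report flags whether the secondary plane
crosses the primary cut polygon inside the bone (the "red" case where the
two cuts intersect) by testing whether the polygon straddles the secondary
plane. Pure opening wedges (all gap) have no secondary cut.

**Statistics.** The intraclass correlation is the two-way random,
absolute-agreement, single-measures form computed from the mean-square
decomposition `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
This model is sometimes labelled ICC(3,1) in the applied literature even
though that label conventionally denotes the mixed model; the package
names it by its description. Normality checks use Shapiro-Wilk, mean
differences two-tailed paired t-tests, correlations Pearson's R (the form
consistent with fitted linear trendlines), and the cartilage-age trend an
exponential fit by least squares on `log(RCV) ~ age`. No multiple-testing
correction is applied; reports expose raw p-values. Study reports attach
the literature reference constants for residual surgical error (5.6 +/-
4.2 degrees rotation, 2.0 +/- 1.4 mm translation) for the
clinical-relevance comparison.

## The synthetic phantom cohort

Patient scans behind the original study design are not public, so the
package ships a fully synthetic generator whose ground truth is known by
construction, and every validation claim is made against it.

A healthy bone is a lofted tube along z: flared ends (the proximal
epiphysis 15% smaller than the distal), a gentle planar bow of the shaft
(2.5% of length, peaking mid-shaft), a seed-specific azimuthal radius
modulation dominated by the k = 1 harmonic (an egg-shaped cross-section
with a slow helical twist, 12-18% of the radius) with weaker k = 2, 3
terms, a one-sided styloid-like lobe on each epiphysis (20-30% of the
local radius), and a narrow full-length ridge on the shaft mimicking the
interosseous crest (8-12%, cos^6 profile). The asymmetries are not
decoration: they break the rotational, end-swap and mirror degeneracies
that would otherwise let rigid registration slide or flip. Smooth
low-order harmonics alone are insufficient — an egg-shaped section rotated
about its axis equals, to first order, a laterally shifted circle, and an
end lobe can nestle into the axisymmetric flare — so the sharp,
non-compensable crest is what ultimately pins the azimuth, exactly as on a
real radius. Default dimensions (length 120 mm, shaft radius 6 mm,
epiphysis radius 10 mm) are in the range of pediatric forearm bones.

A deformity is planted by rotating the distal part by a known wedge angle
about a known transverse axis anchored at a known centerline station, with
a +/- 2 mm smooth blend band to keep the mesh manifold (the band slightly
smears the true plane location, which is why plane-recovery tolerances are
stated as one grid step). The contralateral side is the pre-deformation
mesh mirrored sagittally, so the mirrored template is exactly congruent to
the correctable deformity and the ideal objective is ~0; contralateral
asymmetry is deliberately absent so that recovery errors are attributable
to the algorithms.

Segmentation variants per case: the clean voxelization at 0.5 mm stands in
for CT bone segmentation (CTb); a boundary perturbation by a smooth seeded
Gaussian random field, calibrated by measure-and-rescale so the achieved
mean absolute surface distance matches a commanded target (default ~0.4
mm, the scale of reported CT-vs-MRI segmentation differences), stands in
for MRI bone segmentation (MRb); adding a morphological cartilage shell
over the articular ends gives the MRI bone-and-cartilage variant (MRbc).
For MRbc planning both sides use the bone+cartilage union surface, the
only composite surface both sides possess. Cohort ages span 7-18 years
with cap thickness decaying exponentially with age, so relative cartilage
volume (RCV) falls with age as in skeletally immature patients. Planning
meshes are extracted at 1 mm (a working-resolution choice that keeps a
three-variant, ten-case study around ten minutes on one CPU); agreement
metrics between variants are computed on the 0.5 mm volumes.

What the phantom does *not* emulate: anatomically realistic bone shape
(no statistical shape model), multi-bone interaction between radius and
ulna (bones are planned independently), real scanner noise and partial
volume effects, or asymmetry between a patient's two arms. Passing tests
therefore demonstrate the correctness and determinism of the geometry,
registration, search and statistics on idealized inputs — not clinical
accuracy on patient data.

## Validation surface

The test-suite checks that stand in for the method's core claims:

- agreement metrics equal brute-force double-loop computation on random
  mask pairs, and the Dice of a shifted cube follows the analytic
  `(n-k)/n` law exactly;
- Euler decomposition round-trips 10,000 random rigid transforms within
  `1e-9`, and `delta_T`/`Phi_R` match their printed formulas within
  `1e-12`;
- ICP recovers seeded fragment displacements up to 20 degrees / 10 mm
  within 0.5 degrees / 0.5 mm with a monotone residual;
- planning a case whose deformed bone equals its mirrored contralateral
  returns the identity realignment (within 0.1 degree / 0.1 mm) and a
  near-zero objective;
- planted wedges over angles {10, 20, 30} degrees and stations {40, 60,
  80} mm are recovered within 1 degree and one grid step, and closing
  wedges carry a secondary-cut intersection flag that matches an
  independent polygon oracle;
- the exhaustive search equals a naive full-grid re-evaluation exactly;
- the ICC matches a hand-computed mean-squares oracle within `1e-10` and
  the paired t-test's type-I error at alpha = 0.05 is calibrated;
- a ten-case cohort runs the complete comparative study (three variants
  per case, realignment/agreement/plane tables, RCV-age fit) end to end,
  with the commanded perturbation MASD achieved within 25% and a negative
  fitted RCV-age slope.

`scripts/acceptance.R` recomputes all of these quantities from scratch
against the installed package and writes them to JSON.

## Known limitations

- Cut-face capping assumes star-shaped cross-sections; highly concave
  sections (not produced by the generator) could yield self-intersecting
  caps.
- The interpenetration test classifying opening vs closing wedges uses the
  cut-face planes, not a full mesh boolean; for the plane-cut fragments
  produced here the two agree.
- Anisotropic NIfTI input is auto-resampled to the smallest voxel edge;
  strongly anisotropic data will show staircase artifacts in the meshes.
- The whole workflow is rigid; deformable anatomy (cartilage compression,
  growth-plate remodelling) is out of scope.
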
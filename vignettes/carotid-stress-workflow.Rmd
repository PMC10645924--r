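---
title: "Quantifying wall stress in atherosclerotic carotid arteries: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wall stress in atherosclerotic carotid arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`carofem` turns segmented surfaces of a stenotic carotid artery — a lumen
plus calcific and lipid plaque components, the typical output of
threshold-based CT-angiography segmentation — into a per-element von Mises
stress field and the VM₉₉ summary statistic on the fibrous plaque tissue.
This vignette is the package's own account of the science: what is modelled,
which parameters matter, what the synthetic data generator does and does not
emulate, and where the numerical design was genuinely open.

## The mechanical model

The vessel wall and all plaque components are treated as isotropic,
nearly incompressible, linear elastic solids in small-deformation statics.
Each element subset carries its own Young's modulus (defaults, in kPa:
calcific 20 000, lipid 4, fibrous 400, healthy wall 550) and all subsets
share a Poisson ratio of 0.49. The load is a constant uniform pressure on
the lumen surface equal to the *differential* local carotid pressure
ΔP = P_S − P_D measured by ultrasound wall tracking (the bundled
per-patient table spans 30.4–88.5 mmHg), applied as a dead load on the
reference configuration. The distal ICA and ECA ends and the proximal CCA
end are constrained in their longitudinal and circumferential directions in
a per-end cylindrical frame centered at the end-section centroid; the
radial direction stays free so the ring can breathe.

These are deliberate simplifications: arterial tissue is nonlinear and
anisotropic, the in-vivo configuration is pre-stressed and axially
pre-stretched, and the true load is a pressure waveform on a moving fluid
boundary. None of that is modelled. The working assumption — common to a
sizeable body of plaque-stress literature — is that for *comparing* plaque
morphologies under identical treatment, a linear static analysis of the
differential load already localizes the stress concentrations of interest.
Working units are mm / N / MPa, so stresses come out in MPa and are
reported in kPa (1 mmHg = 133.322387415 Pa).

The statistic of interest is VM₉₉: elements of a subset (by default the
fibrous tissue, the region whose thinning and rupture is clinically
relevant) are sorted by increasing von Mises stress, their volumes are
accumulated, and the stress of the first element at or beyond 99 % of the
subset volume is reported, together with that element's centroid. No
interpolation is performed between elements — the definition is a
first-crossing rule, and ties in stress are broken by element index so the
statistic is deterministic. A rule-based location tag accompanies it:
within 1 mm of the lipid surface the peak sits in the fibrous cap, within
1 mm of the calcific surface at the calcific plaque shoulder, within 3 mm
of the bifurcation apex at the bifurcation. When the peak is in the
fibrous cap, the cap thickness is measured on the transversal plane of the
VM₉₉ element as the minimum lumen-to-lipid contour distance within a ±30°
angular window about the element's direction; the window rule is this
package's own choice, made because a bare global minimum could pick up an
unrelated part of the section.

## The synthetic anatomy generator

The generator exists so that every downstream stage is testable without
patient data, and its defaults *are* the study conditions used throughout
the tests. The common carotid runs along z and bifurcates into internal
and external branches whose circular cross-sections drift apart linearly;
default radii are CCA 3.0 mm, ICA 3.0 mm, ECA 2.2 mm, with a small seeded
radius wobble (0.03 mm) so nothing is accidentally exact. Radii are
constant per branch: this makes the outer-wall rule (below) exactly
self-consistent, so reconstruction errors measure the method rather than a
modelling mismatch. In the merging zone the lumen cross-section is the
planar union of the two branch disks; a bridging radius of 0.8 mm keeps
the crotch saddle open near the tangency station, because the exact
two-disk union degenerates into a bowtie there and no watertight loft
exists through a bowtie.

A stenosis is a smooth multiplicative narrowing of the branch radius,
`r(θ,z) = r_h(z)·(1 − A·g(z)·w(θ))`, with a raised-cosine axial profile
g over the stenosis extent and an angular profile w = ((1+cos(θ−θ₀))/2)^k.
The amplitude A is solved in closed form so the cross-sectional *area*
reduction at the stenosis center equals the requested severity; if a
localized bump (k = 2) cannot reach the severity, k is halved until it
can, degenerating gracefully into a uniform ring narrowing. The default
stenosis: proximal ICA, 8–10 mm extent, 50 % area reduction — the
clinically typical site and a moderate-to-severe degree.

Calcific and lipid components are radial bands inside the stenotic gap
(between the narrowed lumen and the healthy radius): the calcific band
sits on the lumen, the lipid band is separated from it by a fibrous cap of
default 0.4 mm and from the calcific band radially. Angular window widths
are solved by a monotone root search so the bands occupy the requested
fractions of the gap volume (defaults 25 % calcific, 15 % lipid). The
ground-truth fibrous solid is the gap minus the calcific band, with the
lipid represented as a reversed cavity surface inside it — exactly
disjoint from both components by construction. This plays the role of the
reference fibrous model an expert's manual segmentation would provide.

What the generator does **not** emulate: irregular, non-star-shaped lumen
cross-sections; plaque at the bifurcation transition itself (stenoses are
restricted to single-branch zones, and the generator rejects specs that
cross the transition); CT noise, partial-volume and beam-hardening
effects (the optional Hounsfield-unit volume uses clean per-class value
ranges with a constant 100 HU soft-tissue background, chosen strictly
between the lipid ≤ 60 HU and blood 200–700 HU ranges so thresholding is
unambiguous — the 100 HU figure is a stand-in for "intermediate density",
not a claim); and vessel tortuosity out of the bifurcation plane. Passing
tests on these anatomies therefore demonstrates the *method's* internal
consistency — contour Booleans that close, parameter recovery of a known
fibrous solid — not robustness to the segmentation artifacts of real CTA.

## The wall reconstruction and its open choices

The reconstruction is contour-driven throughout. Cutting planes are
horizontal (perpendicular to the trunk axis, matching the axial frame of
the imaging volume) at 0.5 mm spacing — finer than the 0.8 mm global mesh
size; lumen contours are rebuilt as least-squares periodic cubic B-splines
(16 control points, resampled to 64 vertices). Cubic B-splines stand in
for NURBS: the smoothing exists to remove segmentation staircase, not for
exact shape control, and a periodic cubic fit does that with a linear
solve. A fit whose output self-intersects is retried with doubled control
points and rejected only if that fails.

Per plane, the lumen and plaque-envelope contours are merged by a 2-D
convex hull, and the merged section is enlarged by radial scaling about
its area centroid until its equivalent radius √(area/π) reaches the
outer-wall target: the distal inner radius of the respective branch
increased by 30 %. The trunk uses the larger of the two daughter radii,
and sections in the bifurcation transition (where the merged trunk section
is two-lobed) are scaled by the factor 1.3 directly, which is the only
reading of the rule that stays continuous through the merge. Several
sub-choices here were genuinely open and are package decisions: the
centroid as the scaling center (the only canonical center for non-circular
contours); equivalent-radius targeting rather than constant offset; and
the treatment of the transition zone.

Sections where the enlarged outer curve *narrows* — equivalent radius
below 98 % of the linear interpolation between neighboring retained
stations — are removed iteratively (worst dip first) and refilled by
per-vertex linear blending of the adjacent retained contours. The 98 %
threshold makes "showed a narrowing" precise; transition-zone union
sections are exempt because their radius legitimately necks down toward
the split. The healthy lumen is obtained by shrinking each outer section
about its centroid by the inverse factor 1.3 — the inverse-of-enlargement
rule is this package's decision for a shrinkage whose magnitude is
otherwise unspecified — with two-lobed sections shrunk lobe-wise so the
smaller branch is not dragged toward the common centroid.

All Booleans are per-plane radial-interval operations on star-shaped
contours, re-lofted afterwards: the wall solid is the annular loft between
outer and inner surfaces closed by end rings (its volume equals
outer − inner exactly, a conservation the tests assert); the fibrous
component is healthy-minus-stenotic with lumen-attached components
subtracted radially and strictly interior components subtracted as
reversed cavity surfaces. Trunk stations above the bifurcation are
excluded from the fibrous Boolean: the gap between the convexified
healthy section and the two-lobed lumen there is the crotch saddle, not a
stenosis, and including it would manufacture fibrous tissue in every
healthy vessel. Lofting uses greedy arc-length stitching between rings
(no resampling constraints), a "pant" construction at the one-to-two
contour split whose chord vertices are shared exactly by both legs (so
the surface stays edge-manifold), fan or annular end caps, a global
orientation repair by breadth-first traversal, and a fillet at the
bifurcation apex implemented as localized Laplacian smoothing within a
1.5 mm radius — a fillet radius is named by the procedure but not
quantified anywhere, so 1.5 mm (half the CCA radius) is the package
default.

## Discretization

Two tetrahedral meshers are provided. The structured annulus mesher
(`tube_tet_mesh`) splits a cylindrical hexahedral grid into six
tetrahedra per cell with a conforming template; it exists for
verification, where boundary fidelity must not pollute the discretization
error. The general mesher (`tetrahedralize`) fills any watertight solid
with body-centered-cubic lattice tetrahedra on a graded tensor grid
(target cell size `global_size`, refined to `local_size` inside the
1 mm-dilated bounding box of the plaque components, defaults 0.8/0.3 mm
with the background cell additionally capped at 0.5 mm so the ~0.9 mm
wall stays at least two cells thick), snaps near-surface lattice nodes
onto the solid boundary (inside nodes within 0.45 of the local cell size,
outside nodes within 0.6 of the coarsest local step — the asymmetry lets
ghost cell centers half a step outside reach the surface), keeps elements
whose nodes are all inside or on the surface, welds coincident snapped
nodes, discards elements below 10⁻⁶ mm³, and finally keeps only the
largest *face-connected* element component: clusters attached through a
single node or edge can hinge freely and would render the stiffness
singular. On the test solids this captures the enclosed volume to within
1 %.

Subset labelling implements the minimum-distance-vector rule: an element
belongs to a component when the vector from the nearest surface point to
the element centroid opposes the surface's outward normal. When the
nearest point falls strictly inside a triangle the triangle normal is
used; when it falls on an edge or vertex the face normal is ambiguous and
the angle-weighted pseudonormal of that feature is used instead, which
makes the sign test exact for watertight, non-self-intersecting surfaces.
The centroid is the test point (the rule names "each tetrahedron" without
one), overlaps resolve with priority calcific > lipid > fibrous
(construction subtracts calcific and lipid from fibrous, implying that
precedence), and elements claimed by nothing are healthy wall. Borderline
elements straddling a surface are decided implicitly by their centroid
side; the tests therefore compare against a ray-parity oracle only for
centroids farther than 0.05 mm from the surface.

## Solver verification and the locking caveat

The element is the displacement-only constant-strain (P1) tetrahedron.
Assembly builds per-subset unit-modulus stiffness blocks — the elasticity
matrix is linear in E at fixed ν, so the operator for any modulus set is
a weighted sum, and the sensitivity sweep re-solves with seven moduli at
the cost of seven factorizations and one assembly. The reduced system is
solved by sparse Cholesky factorization with iterative refinement, and a
relative residual above 10⁻⁹ is an error, not a warning.

Verification uses the pressurized thick-walled cylinder (inner radius
3 mm, outer 3.9 mm — exactly the 30 % wall rule) against the Lamé closed
form, at Poisson ratio 0.3. That choice is deliberate: with ν = 0.49,
displacement-only P1 tetrahedra lock volumetrically, and a dedicated test
asserts exactly that (the coarse-mesh Lamé error at ν = 0.49 *exceeds*
the ν = 0.3 error). Running the production analyses at ν = 0.49
reproduces the reference modelling choice faithfully — locking
acknowledged and covered by tests — while the convergence benchmark is
run at a Poisson ratio where the element is known to converge, as is
standard verification practice. At 0.3 mm element size the benchmark
meets 5 % on inner-surface radial displacement and layer-averaged hoop
stress, with the displacement error roughly halving from 0.45 mm to
0.3 mm meshes (first-order-in-energy behaviour of P1 elements).

The per-plane Boolean tolerances are volume-based: wall-solid bookkeeping
closes to round-off by construction, fibrous/annulus constructions are
asserted within 2–3 % against closed forms (the residual is contour
faceting, 64 vertices per ring), and containment of the stenotic lumen in
the healthy lumen is asserted pointwise within 0.15 mm — the scale of the
seeded radius wobble plus smoothing bias, which genuinely limits exact
containment.

## Problem sizes

The default synthetic vessel for end-to-end runs spans 30 mm (bifurcation
at 10 mm), giving roughly 1.8 × 10⁵ elements and 1.2 × 10⁵ degrees of
freedom at the default mesh sizes — a solve of a couple of minutes on one
core. The verification tube at 0.3 mm is 3.5 × 10⁴ elements; unit tests
use 4–8 mm tubes at 0.45 mm so the whole suite stays in minutes. These
sizes were chosen as the smallest at which each property being tested is
meaningfully resolved.

## Known limitations

- Geometry is assumed star-shaped per cross-section about the section
  centroid; heavily ulcerated or dissected lumina would violate this.
- The bifurcation transition zone supports no stenosis, and the apex
  fillet slightly contracts the crotch (Laplacian smoothing is not
  volume-preserving).
- The generated inner fibrous surface can fold locally where the calcific
  window edge moves between stations; the pseudonormal sign test is exact
  only for non-self-intersecting surfaces, so isolated points near such a
  pleat can mislabel (harmless in practice because the calcific priority
  overrides fibrous there).
- The lattice mesher's snapped boundary is crinkled at the element scale:
  enclosed volume converges, but boundary *areas* are overestimated and
  boundary-element stresses are noisier than on the structured mesh —
  which is why verification uses the structured annulus.
- P1 displacement elements at ν = 0.49 lock; absolute stress magnitudes
  at the default Poisson ratio should be read with that in mind. The
  linear model also means all stresses scale exactly with ΔP, so ranking
  and localization, not absolute magnitude, are the robust outputs.
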
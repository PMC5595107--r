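---
title: "The needlesim engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The needlesim engine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlesim)
```

## What the engine simulates

The inferior alveolar nerve block (IANB) is the most common dental nerve
block: the needle enters the mucosa on the medial side of the mandibular
ramus at roughly 45 degrees to the occlusal plane and advances until the tip
sits next to the inferior alveolar nerve at the mandibular foramen — without
touching the nerve. In children the foramen sits slightly below the occlusal
plane, which is why a pediatric scene differs from an adult one.

`needlesim` is the headless computational core of a haptic trainer for this
task. It contains no renderer and no device driver; everything is data in,
data out, and therefore testable: synthetic anatomy scenes, collision
detection between a needle segment and anatomical triangle meshes, a
per-tissue elastic force model with user calibration, task scoring with
user-facing messages, and session recording/replay.

Units are millimeters, seconds and newtons throughout; coordinates are
right-handed, and the slab phantom inserts along $-z$.

## Synthetic anatomy

Two seeded generators stand in for patient models, so every stage of the
pipeline is testable without third-party meshes.

`generate_slab_phantom()` builds a stack of closed axis-aligned boxes, one
per tissue layer, tiling depth $[0, \sum \text{thickness}]$ below the surface
plane $z = 0$. It is a bench phantom: its purpose is that the force-depth
curve of a straight insertion is known in closed form.

`generate_ianb_scene()` builds the stylized training scene: a mucosa sheet on
the medial ramus surface, a muscle volume behind it, the ramus block
(~30x25x10 mm), and the nerve as a watertight cylinder (radius 1 mm,
24 segments) whose surface meets the foramen landmark on the medial bone
face. Facial skin, teeth, tongue and a blood vessel complete the anatomical
inventory; they are decorative in the sense that the task path does not cross
them, and their placement jitters with the seed (task-critical geometry is
exact and seed-independent). For the child profile the foramen sits 2 mm
below the occlusal plane; for the adult profile it sits on the plane. No
published dimensions exist for these fixtures; the values are declared
defaults chosen to be anatomically plausible, not measurements, and are the
conditions every downstream test uses.

The mucosal entry landmark is constructed so that the 45-degree line through
it passes exactly through the nerve axis. That choice makes "ideal" behaviour
constructible by design, which the archetype generator and the task tests
rely on.

What these phantoms deliberately do not model: real anatomical shape
variation, soft-tissue deformation, mesh resolution of CT-derived surfaces.
A green test suite shows the engine's computations are correct on watertight
polyhedra; it does not validate anatomical fidelity of any particular
patient model.

## Collision detection

All triangles of the active structures are indexed in one shared octree
(structure and face id stored per triangle). Subdivision splits a cell into
its eight octants and stops at a leaf capacity of 16 triangles, a maximum
depth of 10, or a minimum cell edge of 1 mm — defaults chosen so that typical
generated scenes (a few hundred triangles) produce trees of a few hundred
nodes.

`query_nearest()` finds the triangle nearest to the needle segment by
best-first branch-and-bound: children are visited in order of a box-distance
lower bound and pruned once the bound exceeds the incumbent. Because pruning
uses the exact incumbent rather than an epsilon stop, the result equals the
exhaustive scan (`brute_force_nearest()`) to floating point, which the test
suite asserts over a thousand randomized scene/segment pairs. Equidistant
faces are tie-broken by lowest (structure name, face index) so results are
deterministic.

The segment-triangle distance kernel is exact: zero if the parametric
intersection test hits (boundary touches count), otherwise the minimum over
endpoint-triangle and edge-edge closest-point distances. Near-parallel
(coplanar) configurations are resolved through the edge and vertex terms
rather than the plane intersection, which avoids the ill-conditioned
division. The intersection predicate is cross-checked in the tests against an
independent signed-volume orientation oracle.

`crossings_along_step()` classifies each surface crossing of a straight tip
step as entering or exiting from the sign of the step direction against the
outward face normal — well defined because every generated mesh is watertight
with consistent winding. Crossings are ordered along the step; at a shared
boundary (two layers sharing a face) the exit precedes the entry. A sample
landing exactly on a surface would report the crossing twice (end of one
step, start of the next); the session runner drops the duplicate.

## The force model

Axial resistance follows Hooke's law per tissue,
$F = k\,(x_0 - x_1)$, with $k$ the structure's resistance constant (N/mm),
$x_0$ the coordinate of the current tissue's surface along the insertion
axis, and $x_1$ the tip coordinate. Only the current (innermost) tissue
exerts axial force: $x_0$ resets at each entry, so the force-depth curve is
piecewise linear, restarting at zero at every layer boundary. The engine
deliberately does not sum drag from already-traversed layers — whether the
shaft should keep feeling superficial layers is left open by the underlying
model, and the single-tissue reading is the literal one. The slab phantom
makes this testable: the simulated curve must match the analytic piecewise
curve to 1e-9 N before clamping.

Lateral force grows with insertion depth. The functional form is a choice
(the underlying model states only monotonicity): a restoring force
$\mathbf{F}_\perp = -c\, d\, \mathbf{o}$, with $d$ the total depth from first
entry, $\mathbf{o}$ the perpendicular offset of the tip from the entry axis,
and $c$ = 0.01 N/mm^2 by default. It is linear in depth at fixed offset,
zero at zero depth or zero offset.

Hard tissues (bone, teeth) carry a yield cap (default 3 N): if the axial
force would exceed it, the force saturates and the state is flagged blocked —
the needle does not drill through bone. The combined axial + lateral output
is finally clamped to the device's maximum renderable force (default 3.3 N,
a typical value for the class of desktop haptic arms this engine targets;
configurable). Logs keep both the raw model force and the clamped output, so
analyses are not distorted by the device limit.

Default stiffness values for the seven structure classes (skin 0.4,
mucosa 0.25, tongue 0.15, gums 0.5, bones 2.5, muscles 0.35, nerves 0.6
N/mm) are placeholders in the calibration config: the published source for
this engine gives no numbers, and the whole point of the calibration module
is that users fit their own. `calibrate_stiffness()` is the through-origin
least-squares slope of force on penetration, reporting the RMSE and the
slope's standard error; recovery within three standard errors on simulated
noisy data is an acceptance property.

## Task evaluation

`task_spec()` encodes the direct technique: target angle 45 degrees with a
+/- 10 degree tolerance ("approximately 45" is not quantified further, so the
tolerance is a declared default), an entry disc of radius 4 mm around the
mucosal landmark, a tip-to-nerve distance window of 0.5-3 mm, and forbidden
nerve contact. Zone size and depth window are configuration, not anatomical
claims.

Checks, in fixed message order:

* **Entry point** — Euclidean distance of the first mucosa crossing from the
  zone center. A session that never crosses the mucosa fails with a
  "no insertion" message.
* **Angle** — angle between the needle direction at the entry crossing and
  the occlusal plane ($\arcsin |d \cdot n|$).
* **Depth** — tip-to-nerve surface distance at the *deepest* sample, not the
  final one, so retracting after a correct placement still passes (an
  interpretation aligned with training intent). Measured with the octree
  query restricted to the nerve; since the query contract requires a proper
  segment, a 1e-9 mm probe stands in for the point, an error far below any
  tolerance in play. Passing emits the "correct point to deposit the
  anesthetic solution" message; injection itself is not simulated.
* **Nerve contact** — count of nerve entry events; any contact fails when
  forbidden.

Evaluation is a pure function of (log, scene, spec); logs carry a scene
fingerprint and evaluation refuses a mismatched scene.

## Synthetic student input

`generate_archetype_trajectory()` constructs straight, seeded,
noise-jittered trajectories in the sagittal plane of the scene from its
landmarks, solving a small linear problem for the entry offset and stop
length so that each archetype realizes its intent exactly:

* `ideal` — 45 degrees through the entry landmark, stopping with the tip
  2.75 mm from the nerve axis (1.75 mm from the surface, mid depth-window);
* `shallow` — same line, stopping 6 mm short of the nerve surface;
* `wrong_angle` — 25 degrees, entry offset solved so the closest approach
  still lands in the depth window (only the angle check fails);
* `nerve_hit` — 45 degrees aimed 0.7 mm off the nerve axis (inside the 1 mm
  radius), passing through the nerve and stopping past it at a correct
  depth (only the contact check fails).

Default tip jitter is Gaussian, sd 0.05 mm — small against every geometric
margin (the smallest is the 0.3 mm chord clearance of the nerve-hit path),
so the intended pass/fail pattern is stable under the default noise, and the
tests assert it both at zero and default noise. The archetypes assume the
generated scene's geometry (nerve axis perpendicular to the insertion
plane); they are not a general inverse planner.

## Numerical choices and degenerate inputs

* Distances and intersections are exact floating-point computations; the
  only tolerances are a 1e-10 barycentric boundary tolerance (boundary
  touches count as hits) and a relative 1e-13 parallelism guard.
* Tie-breaks (equidistant faces) are lexicographic; event ordering at shared
  boundaries is exit-before-enter; coincident duplicate crossings collapse.
* Degenerate (zero-area) faces are rejected at construction, or dropped with
  a count when loading external meshes. Degenerate needle segments
  (tip = tail), non-monotone timestamps, non-unit directions and empty
  scenes are errors, not silent fixes.
* Scene and log serialization writes 17 significant digits, which
  round-trips IEEE doubles exactly; identical seeds therefore produce
  byte-identical files, and write-read-evaluate equals direct evaluation.
* The RNG is used only inside explicitly seeded generators, and the seed
  state is restored afterwards.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: 1000 random 50-triangle
scenes for oracle equivalence; a 379-point force-depth sweep of the 3-layer
slab; 500 random parameter draws for the Hooke identities; 50 noisy samples
(sd 0.05 N) for calibration recovery; and the four archetypes on the child
scene. These sizes make the whole suite run in well under a minute while
leaving the property spaces densely sampled; all are trivially enlargeable.

## Known limitations

* No soft-tissue deformation and no needle bending: the needle is a rigid
  segment, tissues are rigid boundaries. Only the force magnitudes are
  elastic.
* One octree spans all structures (a per-structure tree would also be
  defensible); rebuilt after activation changes rather than updated.
* Entry-zone membership is Euclidean, not geodesic on the mucosa surface.
* The six-degree-of-freedom torque channel of real devices is out of scope,
  as are graphics, stereo viewing and the physical syringe coupling.
* Anesthetic injection and aspiration are not simulated; the depth-check
  message only marks the correct deposit location.
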
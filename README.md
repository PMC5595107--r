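# needlesim

A headless, fully testable R engine for simulating the needle-insertion task
of the **inferior alveolar nerve block (IANB)**, the most common dental
anesthesia technique. It is the computational core a haptic VR trainer needs,
with the graphics, device driver and UI stripped away: everything is data in,
data out.

The engine targets dental educators and simulation researchers who want to
prototype, calibrate and score the IANB direct technique — entering the
mucosa on the medial mandibular ramus at approximately 45 degrees to the
occlusal plane and advancing the tip next to the inferior alveolar nerve at
the mandibular foramen, without touching the nerve. Child anatomy is the
default profile (the foramen sits slightly below the occlusal plane in
children).

## What is inside

* **Synthetic anatomy** — seeded generators for a layered tissue slab
  phantom and a stylized child/adult mandible-ramus scene (mucosa, muscle,
  ramus bone, nerve cylinder entering the foramen, plus skin, teeth, tongue,
  vessel), all watertight meshes; OBJ/STL mesh I/O; lossless JSON scene
  serialization.
* **Collision detection** — an octree over the scene's triangles with an
  exact best-first nearest-triangle query (verified against a brute-force
  oracle), segment-triangle intersection, and entering/exiting surface
  crossing detection along needle steps.
* **Haptics** — per-tissue Hooke's-law axial resistance
  `F = k (x0 - x1)`, where `k` (N/mm) is the structure's resistance constant,
  `x0` the tissue-surface position and `x1` the tip position along the
  insertion axis; a depth-dependent lateral restoring force; yield caps for
  bone/teeth; device clamping; and least-squares stiffness calibration from
  force-displacement samples.
* **Task evaluation** — entry point, insertion angle, depth next to the
  nerve, nerve contact; pass/fail with the trainer's user-facing messages.
* **Session logging** — deterministic simulation runs, JSON-lines logs that
  round-trip exactly, summaries (training time, path length, structures
  traversed, contact counts), and four synthetic trajectory archetypes
  (ideal / shallow / wrong-angle / nerve-hit) standing in for student input.
* **CLI** — `gen-anatomy`, `run`, `validate`, `report`, `calibrate`
  subcommands (`inst/cli/needlesim`).

## Worked example

```r
library(needlesim)

scene <- generate_ianb_scene(seed = 1, patient_profile = "child")
scene
#> <needle_scene: 8 structures (8 active), profile 'child'>
#>   mucosa            12 faces  k=0.25 N/mm
#>   muscle            12 faces  k=0.35 N/mm
#>   bone              12 faces  k=2.50 N/mm
#>   nerve             96 faces  k=0.60 N/mm  [target nerve]
#>   skin              12 faces  k=0.40 N/mm
#>   teeth             12 faces  k=2.50 N/mm
#>   tongue            12 faces  k=0.15 N/mm
#>   vessel            48 faces  k=0.30 N/mm

traj   <- generate_archetype_trajectory(scene, "ideal", seed = 1)
log    <- run_session(scene, traj, default_calibration(), seed = 1)
result <- evaluate_session(log, scene, default_task_spec(scene))
result
#> Task PASSED
#>   - Correct insertion point (0.0 mm from the target spot.)
#>   - Correct insertion angle (45.0 degrees).
#>   - Correct point to deposit the anesthetic solution (tip 1.79 mm from the nerve).
#>   - No nerve contact.

summarize_session(log)
#> Session summary
#>   training time : 3.00 s
#>   path length   : 16.99 mm
#>   max depth     : 9.91 mm
#>   traversed     : mucosa > muscle
#>   contacts[mucosa] = 1
#>   contacts[muscle] = 1
```

The trajectory enters the mucosa at the entry landmark, crosses into muscle,
and stops with the tip 1.79 mm from the nerve surface — inside the 0.5–3 mm
deposit window — at exactly 45 degrees to the occlusal plane, never touching
the nerve, so all four checks pass. A `"nerve_hit"` archetype instead ends
with `Error: contact of the needle with the nerve (1 time).` and a failed
session.

The same pipeline from a shell:

```sh
inst/cli/needlesim gen-anatomy --seed 1 --profile child -o scene/
inst/cli/needlesim run --scene scene/scene.json --archetype ideal \
    --seed 1 -o log.jsonl
inst/cli/needlesim validate --log log.jsonl --scene scene/scene.json \
    --task scene/task.json    # exit 0 pass / 1 fail
inst/cli/needlesim report --log log.jsonl
```

See `vignettes/needle-insertion-engine.Rmd` for the force model, parameter
defaults (and why), numerical choices and limitations.

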
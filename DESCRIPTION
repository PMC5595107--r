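Package: needlesim
Title: Headless Simulation Engine for Dental Anesthesia Needle-Insertion Training
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, testable engine for simulating the needle-insertion
    task of the inferior alveolar nerve block (IANB), the most common dental
    anesthesia technique. Provides seeded procedural anatomy phantoms (layered
    tissue slabs and a stylized child mandible-ramus scene with nerve and
    foramen landmarks), octree-accelerated collision and proximity queries
    between a needle segment and triangle meshes, a per-tissue Hooke's-law
    force-feedback model with user calibration, evaluation of the IANB direct
    technique (entry point, ~45 degree insertion angle, depth next to the
    nerve, no nerve contact), and recording, replay and summary of training
    sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
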
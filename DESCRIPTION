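Package: sapmnet
Title: Structural and Physiological Modeling of Brainstem and Spinal Cord
    BOLD Networks
Version: 0.1.0
Authors@R:
    person("SAPMnet", "Developers", email = "sapmnet@example.org",
           role = c("aut", "cre"))
Description: Effective-connectivity analysis of blood-oxygenation-level-
    dependent (BOLD) fMRI time-courses from brainstem and spinal cord
    regions using a latent-input directed network model (structural and
    physiological modeling, SAPM).  Provides the predefined descending
    pain-regulation network, a synthetic-data generator emulating a
    noxious heat stimulation paradigm, voxel extraction and balanced
    k-means sub-region parcellation, per-participant alternating
    least-squares fitting of signed connectivity (DB) weights and latent
    input time-courses, phase-randomized surrogate null references, and
    group-level statistics (null-referenced t-tests with Bonferroni
    correction, connectivity-versus-pain-rating regression, and
    group-by-covariate ANCOVA), orchestrated by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
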
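Package: reflexneck
Title: Reduced-Order Head-Neck Simulation with Reflexive Muscle Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sagittal-plane multibody simulation of the human head and
    cervical spine for low-speed rear-impact (whiplash) analysis.
    Implements Hill-type line muscles with a parallel damping element
    (PDE), baseline co-contraction, and a delayed proportional-derivative
    reflex controller on head orientation (a vestibulocollic-reflex
    surrogate), driven by prescribed T1 kinematics or sled pulses.
    Includes CORA-style objective rating (corridor and cross-correlation
    methods) with hierarchical score aggregation, an eight-configuration
    feature-ablation matrix, bounded parameter identification by seeded
    differential evolution, crash-channel utilities (SAE J211 CFC
    filtering, resampling, differentiation, integration, NIC computation),
    and a synthetic-reference generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
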
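Package: looprigor
Title: Binding-Loop Rigidity and Potency Analysis for Canonical Protease Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in-silico screens of canonical-loop serine
    protease inhibitor variants. Computes geometric hydrogen-bond networks and
    per-bond occupancies from multi-model PDB trajectories, binding-loop
    rigidity via Kabsch superposition and C-alpha RMSD, tight-binding
    (Morrison) and slow-binding inhibition kinetics, exponential stability
    half-lives, and the rank correlation between loop rigidity and measured
    potency. Includes synthetic-data generators that emulate molecular-dynamics
    trajectories with programmable hydrogen-bond occupancies and simulated
    kinetic assays, so every stage is testable without an MD engine or lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
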
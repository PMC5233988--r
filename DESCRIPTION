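Package: NaKGate
Title: Protonation-State Analysis of the Sodium-Bound Na+,K+-ATPase Ion Pocket
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to determine plausible protonation schemes of the
    transmembrane ion-binding pocket of the sodium-bound Na+,K+-ATPase.
    Enumerates all protonation states of the six titratable pocket residues
    under a compact site-code grammar, computes per-ion root mean square
    fluctuation and hydration number from multi-model PDB trajectories,
    classifies states as stable or unstable against fluctuation and hydration
    thresholds, counts water transit events through defined pathway corridors
    to test the glutamate water-gate hypothesis, carves capped quantum-cluster
    models of the binding pocket with frozen alpha carbons and formal-charge
    accounting, and books counterpoise-corrected sodium binding energies
    against a single-ion water-shell hydration reference. A synthetic-data
    generator plants known fluctuation, hydration, transit and energy ground
    truth so every pipeline stage is testable without molecular dynamics or
    quantum chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'registry.R'
    'protonation.R'
    'pdb-io.R'
    'trajectory.R'
    'metrics.R'
    'pathways.R'
    'qm-cluster.R'
    'binding-energy.R'
    'synthetic.R'
    'pipeline.R'
    'NaKGate-package.R'
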
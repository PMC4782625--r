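Package: fondaka
Title: Electrostatic Model of Polymer Antidote Association with Fondaparinux
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the association kinetics of spherical cationic
    polymer antidotes with the rod-like anticoagulant fondaparinux. Implements
    Debye-Hueckel screened electrostatic interaction energies, the Schreiber
    electrostatically modulated association rate constant on top of the
    Smoluchowski diffusion-limited sphere-rod basal rate, Monte-Carlo placement
    of cationic binding groups on a spherical scaffold under a minimum-distance
    constraint, greedy binding-site identification with sequential fondaparinux
    binding and charge bookkeeping, and ensemble sweeps over group number,
    polymer radius, effective charge and group identity. A companion toolkit
    reconstructs potential-of-mean-force profiles from restrained-window mean
    restraint forces, aggregates replicates with confidence intervals, extracts
    binding free energies, and generates synthetic window data for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
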
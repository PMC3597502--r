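Package: phagedyn
Title: Semi-Stochastic Population Dynamics of Lytic Phage and Bacteria
    with CRISPR-Cas Immunity
Version: 0.1.0
Authors@R:
    person("phagedyn", "maintainers", email = "phagedyn@example.org",
           role = c("aut", "cre"))
Description: A hybrid deterministic-stochastic simulator of batch and
    serial-transfer cultures of lytic bacteriophage and bacteria carrying a
    CRISPR-cas adaptive immune system.  Bacteria and phage occur in "orders"
    (number of spacers acquired, or protospacer mutations accumulated); growth
    is resource-limited (Monod), adsorption is mass action, lysis is delayed by
    a latent period realized with an exact delay buffer, and the creation of
    bacteriophage-insensitive mutants (BIMs) and CRISPR escape mutant phage
    (CEMs) is simulated as discrete Monte Carlo events layered on explicit
    Euler integration.  An extended model adds a lysis-released compound that
    kills dividing cells and induces persistence.  The package also provides
    the matching assay-analysis routines (growth-rate regression, one-step
    growth-curve analysis of latent period and burst size, plaque-ratio escape
    mutant frequencies, optical-density calibration), scenario presets,
    synthetic-data generators, config round-tripping, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
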
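Package: tautkin
Title: Transition-State-Theory Kinetics and QTAIM Energetics of
    Intramolecular Proton-Transfer Tautomerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-quantum-chemistry analysis of intramolecular
    proton-transfer tautomerization. Computes Eyring transition-state-theory
    rate constants with the Wigner tunneling correction, equilibration times,
    tautomer lifetimes and a dynamic-stability classification from Gibbs
    activation barriers and imaginary transition-state wavenumbers; estimates
    energies of intramolecular hydrogen bonds and attractive van der Waals
    contacts from bond-critical-point descriptors via the empirical
    Espinosa-Molins-Lecomte, Brovarets'-Yurenko-Hovorun and
    Nikolaienko-Bulavin-Hovorun formulas with class-based dispatch. Ships a
    transcription of the reference tautomerization network of the quercetin
    molecule, JSON/TSV interchange for reaction sets, a seeded synthetic
    reaction generator, and tabular/graphical reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
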
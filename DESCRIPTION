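Package: soluterm
Title: Solubility Modeling and Dissolution Thermodynamics in Cosolvent Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium mole-fraction solubility modeling of a poorly
    water-soluble drug in pure solvents and binary cosolvent (Transcutol
    HP-water) mixtures. Implements the modified Apelblat, van't Hoff,
    Buchowski-Ksiazaczak lambda-h, Yalkowsky log-linear, and Jouyban-Acree
    van't Hoff models with MRD/RMSD fit scoring; ideal solubility and
    activity coefficients from fusion properties; apparent dissolution
    thermodynamics (enthalpy, Gibbs energy, entropy at the mean harmonic
    temperature) with enthalpy-entropy compensation analysis; KAT-LSER
    solvatochromic regression of solubility on Kamlet-Taft descriptors; a
    composition-selection rule for liquid anti-solvent precipitation; and a
    seeded synthetic-data generator so every stage can be exercised without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    minpack.lm,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
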
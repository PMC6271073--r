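Package: nmrtitr
Title: NMR Titration Analysis of Acidity and Prototropic Tautomerism
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for proton-NMR titration experiments on acid-base systems
    with intramolecular hydrogen bonds, such as ortho-hydroxyaryl Schiff
    bases. Reads and writes titration tables of pH readings and chemical
    shifts, fits acid dissociation constants (pKa) by the semilogarithmic
    Henderson-Hasselbalch linearization, builds chemical-shift (delta)
    diagrams for paired reporter nuclei, estimates the tautomeric
    site-constant quotient by Perrin bilinear regression and by
    Polster-Lachmann Gibbs-triangle analysis, and derives the associated
    thermodynamics (delta-pK, delta-delta-G, tautomer classification).
    Includes a synthetic titration generator under the fast-exchange
    two-state averaging model for monoprotic, coupled tautomeric and
    diprotic systems.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
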
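Package: nmrtitr
Title: Denaturant-Titration NMR Analysis of Protein Folding and Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-residue analysis of protein NMR denaturant titrations in
    mixed DMSO-water solvents. Computes secondary C-alpha chemical shifts
    against solvent-fraction-weighted random-coil baselines and calls
    contiguous helix/sheet propensity segments; measures 3J(HN-HA) couplings
    from resolved HSQC doublets with preceding-residue corrections and
    classifies them into secondary-structure bands; fits per-residue R2
    transverse relaxation rates from CPMG intensity decays and detects
    conformational-exchange segments; tracks peak disappearance across a
    denaturant ladder to order the incorporation of chain segments into a
    self-assembly and to locate the folding/association nucleation site. A
    seeded synthetic-data generator emulates all observables from a planted
    ground truth so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
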
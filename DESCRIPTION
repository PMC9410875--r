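Package: foxcoop
Title: Cooperative Binding of Forkhead-Box Transcription Factors to
    Homotypic DNA Site Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying how forkhead-box (FOX)
    transcription factors assemble on promoters carrying two adjacent
    binding elements. Implements strand-aware IUPAC consensus scanning for
    FOX-binding elements, an equilibrium two-site lattice binding model
    with a cooperativity factor estimated from electrophoretic mobility
    shift assay (EMSA) band fractions under ligand depletion, simulation
    and fitting of isothermal titration calorimetry (ITC) isotherms for
    one-site versus sequential two-site binding, stoichiometry inference
    from light-scattering masses, and DNA minor-groove-width geometry from
    atomic structures including an ideal fiber B-DNA reference generator.
    Seeded synthetic-data generators emulate every experimental input so
    the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
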
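Package: cdr3scope
Title: CDR3 Length-Dependent Analysis of Nanobody (VHH) Repertoires and Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the length of the third complementarity-
    determining region (CDR3) shapes single-domain antibody (VHH, nanobody)
    repertoires and structures. Ingests IMGT-numbered repertoire tables and
    applies read-count, deduplication and CDR3-length z-score filters; computes
    per-region net charge (pH 7.4), Kyte-Doolittle hydropathy and seven-class
    amino-acid compositions; correlates regional and per-position residue usage
    with CDR3 length under Benjamini-Hochberg FDR control; extracts structural
    features from VHH and VHH-antigen complexes (4 Angstrom residue contacts,
    the FR2-CDR3 minimum centroid distance, Shrake-Rupley solvent-accessible
    surface area, buried surface area, surface hydrophobicity, interface and
    secondary-structure summaries); classifies bent versus extended CDR3
    conformations from the trough of a bimodal density; and provides synthetic
    repertoire and pseudo-structure generators so the full pipeline is testable
    without external sequencing or structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
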
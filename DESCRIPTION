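Package: crydimer
Title: Disulfide-Linked Homodimer Screening and Interface Analysis for
    Cryptochrome-Like Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for identifying and characterising
    disulfide-linked protein homodimers from coordinate data. Provides a
    Shrake-Rupley solvent-accessible surface area engine with Gly-X-Gly
    maximum-SASA normalisation for per-residue exposure, distance-based
    screening of rigid-body dimer poses for disulfide feasibility, an
    interface metric panel over coordinate ensembles (inter-monomer
    non-bonded energy with a switched 12 A cutoff, radius of gyration,
    Kabsch RMSD, RMSF, buried interface area, hydrogen bonds and
    occupancy-filtered salt bridges), cross-linking mass-spectrometry
    distance-constraint mapping, Ellman (DTNB) accessible-cysteine
    arithmetic, and a fully deterministic synthetic-fixture generator so
    the whole pipeline is testable without any structure downloads.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
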
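Package: zfarray
Title: Sequence and NMR-Ensemble Analysis of Tandem C2H2 Zinc-Finger Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural bioinformatics of tandemly arrayed
    C2H2 zinc-finger proteins. Detects and classifies C2H2 fingers in a
    protein sequence (Cys and His spacer classes, bulged-out versus
    canonical recognition helices, interfinger linker typing, tandem-unit
    grouping), analyses multi-model NMR ensembles (backbone phi/psi
    statistics with circular means, pi i->i-5 hydrogen bonds, tetrahedral
    zinc-site geometry, Kabsch superposition), quantifies interfinger
    flexibility as the ensemble RMSD of one finger after fitting on a
    neighbour, and predicts DNA subsites per finger from an editable
    recognition-code table with antiparallel assembly across tandem units.
    A synthetic-data module builds peptides at prescribed dihedrals, noisy
    finger ensembles and hinged two-domain ensembles with known ground
    truth, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
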
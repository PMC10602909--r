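Package: kzfpscreen
Title: Screening KRAB Zinc-Finger Proteins That Target Retroviral Primer-Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a computational screen for KRAB zinc-finger
    proteins (KZFPs) that bind the 18-nucleotide primer-binding site (PBS) of
    endogenous retroviruses. Provides PBS motif derivation from tRNA 3' ends and
    genome scanning, C2H2 zinc-finger detection with fingerprint extraction and a
    recognition-code DNA-binding motif predictor, Needle-style global pairwise
    alignment with identity/similarity reporting, LTR-divergence molecular dating of
    ERV insertions with invasion-time profiles, ortholog-based gene-age estimation
    with a temporal co-occurrence screen, ChIP-seq peak/PBS overlap ranking, a
    two-arm screening pipeline joining all stages, and a seeded synthetic-data
    generator with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
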
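Package: invtoe
Title: Inverse Toeprinting Analysis of Ribosome Stalling Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing inverse-toeprinting sequencing experiments,
    in which a 3'-5' exonuclease (RNase R) trims an mRNA up to the leading
    stalled ribosome so that the 3' end of the protected fragment reports
    the ribosome position at codon resolution. The package trims and
    filters merged reads, verifies the tri-nucleotide periodicity of
    fragment 3' ends, estimates the cleavage offset between the ribosomal
    P-site and the protected 3' end from stop-codon-stalled reads, assigns
    a P-site codon to every read, and computes tripeptide (or tricodon)
    motif frequencies, pause strengths, replicate-partitioning error
    models, fold changes with propagated inter-replicate errors, and
    drug-dependent motif classes. A focused-library module calls peptide
    variants against a wild type and selects condition-discriminating
    variants. A synthetic-data module simulates degenerate (NNS) and
    per-nucleotide mutagenised template libraries, sequential ribosome
    stalling, exonucleolytic cleavage geometry and two-replicate counting
    noise, so that every analysis stage can be validated against ground
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
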
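Package: tlr7scan
Title: Transcriptome Screen for Sex-Biased, UU-Rich Sources of TLR7 Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate self-RNA sources of TLR7 ligands from a
    transcriptome FASTA and a sex-annotated bulk RNA-seq counts matrix.
    Computes per-transcript UU-dinucleotide counts, maximum local UU richness
    in a sliding window, and exact-match positions of the TLR7-stimulatory
    motif 5'-GUCCUUCAA-3'; derives TPM and female/male expression bias per
    tissue; tests sex-biased expression with a moderated t statistic and
    Benjamini-Yekutieli correction; and aggregates four ascending criterion
    ranks into a per-tissue TLR7 ligation score with cross-tissue
    normalization. Also provides a bin-matched-control gene-set module score
    for single-cell data with a per-patient correlation screen, small qPCR
    and reporter-assay formulas, and seeded synthetic-data generators with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Matrix
Suggests:
    withr,
    testthat (>= 3.0.0),
    limma,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
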
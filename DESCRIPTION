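Package: SFPGtools
Title: Functional Grouping of Transcript Isoforms for RNA-Seq Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores all pairs of proteins in a proteome for functional
    similarity from pairwise sequence-alignment features (identity, coverage,
    gaps) and ordered domain-architecture comparison across an ensemble of
    InterPro analyses, forms Similar Function Protein Groups (SFPGs) above a
    confidence-score cutoff, and recomputes RNA-Seq expression per functional
    group instead of per gene or transcript locus. Raw transcript counts are
    normalized with median-of-ratios size factors, converted to FPKM via
    effective lengths, and redistributed to groups by equal or group-size
    weighted distribution. Includes a seeded synthetic-proteome fixture
    generator with planted ground-truth families so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, GeneExpression, Normalization
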
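Package: spliceneo
Title: Splice-Junction-Derived MHC-I Neoantigen Discovery and Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate MHC class I neoantigens arising from
    tumor-specific alternative splicing. Starting from aligner splice-junction
    tables, the pipeline filters junctions by read support, percent-spliced-in
    (psi5/psi3) and a panel-of-normals junction database, inserts surviving
    junctions into annotated reference isoforms to build novel isoforms,
    translates them in the annotated reading frame, chops the novel proteins
    into 8-11-mer peptides, subtracts the normal proteome, and prioritizes
    surviving peptides with a multiplicative immune score combining MHC
    binding percentile ranks, dissimilarity to the nearest normal peptide,
    antigen-processing efficiency, hydrophobicity and T-cell recognition
    probability. Binding and processing predictors are pluggable; built-in
    deterministic surrogates allow fully offline runs, and a synthetic
    fixture generator produces complete ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
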
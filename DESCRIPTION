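Package: metapep
Title: Metaproteomic Spectral-Count Analysis with Protein Metaclusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for shotgun metaproteomics of complex
    microbial communities quantified by spectral counting. Implements
    target-decoy false discovery rate filtering of peptide-spectrum
    matches, parsimony protein inference (minimal explanatory protein
    set), homology-based metaclustering of inferred proteins across taxa
    via shared gene names, shared peptide evidence and shared UniRef50
    cluster membership, per-rank taxonomic profiling from uniquely
    assignable peptides, comparison of proteomic genus profiles against
    16S rRNA gene read counts, pairwise metacluster correlations between
    subjects, and pathway-level spectral-count contrasts. Ships a
    synthetic community generator that emulates an infant fecal
    microbiome cohort for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
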
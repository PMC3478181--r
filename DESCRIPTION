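Package: coevolib
Title: Coevolving-Site Detection and Combinatorial Saturation Mutagenesis
    Library Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects coevolving residue pairs in a protein family alignment
    with row-and-column-weighted mutual information (base-20 logarithm over
    the amino-acid alphabet), reduces gapped alignments by dropping sequences
    to maximise the gap-free area, and designs the focused NNK
    saturation-mutagenesis libraries built at the selected site pairs:
    degenerate-codon algebra, complementary mutagenic primer design, library
    coverage statistics, and post-screening tallies and classification of
    sequenced variants. Includes a synthetic-data generator with planted
    covarying column pairs and NNK variant pools for validation, and a
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
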
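Package: lavrec
Title: Reconstruction of Overlapping Inversion-Deletion Rearrangements and
    Associated Phenotype Models in Japanese Quail
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise a complex structural allele built from
    overlapping chromosomal inversions and a deletion, modelled on the lavender
    plumage-dilution allele of Japanese quail in the 60-kb region carrying MLPH,
    PRLH, RAB17 and LRRFIP1. Provides a strand-signed segment-painting algebra
    with exact cross-allele liftover, tiled-amplicon deletion screening,
    chromosome-walk junction-read interpretation, breadth-first enumeration of
    most-parsimonious event scenarios, an integer solver for breakpoint
    coordinates under printed distance constraints, in-silico PCR and RT-PCR
    assay prediction with genotype calling, and the companion phenotype
    statistics (monomolecular growth-curve fitting, sex-specific residual feed
    intake, full-versus-reduced linear models). A seeded synthetic-data module
    generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
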
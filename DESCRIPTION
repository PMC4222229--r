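Package: allopotential
Title: HLA-Specific Alloreactivity Potential from Donor-Recipient Exome Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts paired donor/recipient exome variant calls into a
    library of candidate minor histocompatibility antigens (mHA) presented
    by patient-specific HLA class I molecules. Directional nonsynonymous
    SNV sets (graft-versus-host and host-versus-graft vectors) are mapped
    onto transcript models, variant-centered padded peptides and 9-mer
    windows are enumerated, and peptides are scored against HLA class I
    alleles with an additive log-IC50 scoring matrix or with captured
    output of a pan-specific predictor. Per-pair results are summarized as
    presentation counts, a quadratic-fit area-under-curve alloreactivity
    potential in nM*Peptide, an expression-weighted potential, power-law
    affinity-rank fits, and exact Mann-Whitney group comparisons. Includes
    a seeded synthetic-data generator for all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
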
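Package: emschar
Title: Characterization of EMS-Mutagenized Wheat Populations and
    Salt-Tolerance Selection Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize ethyl methanesulfonate (EMS) induced
    point mutations in hexaploid wheat resequencing data and to run the
    phenotype analytics used to select salt-tolerant lines.  Variant sets
    are read from VCF, filtered on depth and quality, and cleaned of
    background polymorphisms by subtracting the unmutagenized parent;
    the remaining substitutions are classified into the twelve base-change
    types, summarized as transition/transversion and G>A/C>T (EMS
    canonical) shares, and converted into mutation densities genome-wide,
    per sub-genome (A, B, D) and per chromosome.  Coding substitutions
    are classified as synonymous, non-synonymous or nonsense against CDS
    gene models.  Phenotype modules score salt germination assays against
    a tolerance threshold, compare root and shoot growth between groups,
    apply multi-criterion field-trial cut-offs and run principal component
    analysis as a covariance eigendecomposition.  A synthetic-data module
    simulates a toy sub-genome-structured genome, gene models, background
    polymorphisms, EMS-mutated samples with a configurable substitution
    spectrum, and phenotype tables, so the whole pipeline is testable
    without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
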
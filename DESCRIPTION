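Package: poolarray
Title: Multi-Species Pooled-DNA SNP Array Design, Simulation, Calling, and
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the full lifecycle of a multi-species SNP genotyping
    array in which DNA from two distantly related species (one plant, one
    fish) is pooled into a single reaction. Covers candidate SNP selection
    and probe design (missingness/depth/MAF filters, A/T-C/G exclusion,
    proximity thinning, LD pruning, flank extraction, cross-taxon
    cross-hybridization screening, secondary-genome checks, probe scoring,
    Dish Quality Control probe design); simulation of two-channel probe
    intensities for pooled reactions with controllable population structure,
    pedigrees, null alleles, ploidy and DNA quality; cluster-based genotype
    calling with SNP classification (PolyHighResolution, NoMinorHom,
    MonoHighResolution, OffTargetVariant, CallRateBelowThreshold, Other)
    and two-stage sample QC; tetraploid dosage calling; and downstream
    validation analytics (PCA, discriminant clustering, Weir-Cockerham FST,
    identity-by-state duplicate detection, trio parentage by Mendelian
    exclusion, pooled-vs-non-pooled quality comparison with Welch t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    MASS,
    methods,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
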
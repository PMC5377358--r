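Package: padlockxci
Title: Allele-Specific RNA Allelotyping of X-Chromosome Inactivation from
    Padlock SNP Capture Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for padlock-capture RNA allelotyping of the
    mouse X chromosome. Takes per-SNP allele-resolved base-call count tables
    and calls per-SNP allelotypes (sequencing-error deduction, detection
    thresholding, pseudo-counted 129/Cast ratios), aggregates SNPs to genes
    and calls gene reactivation along the Xist-deleted inactive X, classifies
    non-coding SNP expression patterns across pre-XCI, post-XCI and mutant
    cell types with multi-combination consensus, quantifies XCI impairment in
    differentiation time courses, correlates reactivation with repeat-element
    density tracks (sliding-window TSS flank profiles, intronic density
    normalisation), processes 5C chromatin contact matrices (depth
    normalisation, median binning, sign-preserving subtractive log maps), and
    implements the padlock SNP-selection rules. A synthetic-data generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
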
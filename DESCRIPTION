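Package: xistruct
Title: Allele-Specific Hi-C Structure of the Inactive X Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific chromosome-structure analysis of the
    inactive X (Xi) in hybrid mouse cells: SNP-based segregation of Hi-C read
    pairs into parental alleles, construction, filtering, iterative-correction
    balancing, quantile normalization and Pearson transformation of binned
    contact matrices, contact decay curves, virtual 4C profiles, compartment
    principal-component scores, coverage scores for superdomain hinge
    detection, insulation scores with TAD boundary calling, allelic d-score
    classification of ChIP/ATAC peaks, and binomial calling of genes that
    escape X-chromosome inactivation. Includes a synthetic-data generator
    that emulates the bipartite Xi contact map (two superdomains separated
    by a hinge with a directional contact flame), compartment and TAD
    structure, allelic read pairs, peaks and expression with known ground
    truth, so every step of the pipeline can be exercised and validated end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    limma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
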
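Package: tetradose
Title: Allele Dosage Genotyping-by-Sequencing for Autotetraploids
Version: 0.1.0
Authors@R:
    person("tetradose", "maintainers", email = "tetradose@example.org",
           role = c("aut", "cre"))
Description: Tools for genotyping-by-sequencing of autotetraploid organisms,
    where each biallelic locus carries an allele copy number (dosage) between
    0 and 4. Implements binomial-likelihood dosage calling from
    allele-specific read depths with phred-scaled genotype quality and
    depth/quality filters, read-depth power design for discriminating dosage
    classes, population diversity statistics (minor-allele-frequency spectra,
    gene and nucleotide diversity, variant saturation curves), concordance
    validation against an orthogonal single-marker assay, accessible-region
    calling from per-base coverage profiles, and dosage-coded principal
    component / k-means structure analysis with additive and dominant
    marker-trait association under step-up false-discovery-rate control.
    A synthetic-data module generates tetraploid panels (Hardy-Weinberg
    dosages, L-shaped allele-frequency spectra, log-normal read depths,
    binomial allele-specific read sampling with error and capture bias, and
    duplicate orthogonal-assay signals) so the whole pipeline is testable
    without access to real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
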
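Package: archintro
Title: Archaic Introgression and Selection Scans on Phased Haplotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting positive selection and archaic (Neanderthal/
    Denisovan) adaptive introgression from phased haplotype panels. Implements
    windowed Hudson F_ST, Fay and Wu's H and cross-population extended
    haplotype homozygosity (XP-EHH) with genomic-outlier calibration, a
    candidate-variant filter combining allele-frequency differentiation with
    functional annotation, archaic-aware haplotype distances and
    haplostrips-style ordering against an archaic reference genome, minimum
    spanning haplotype networks, the U and Q95 archaic-sharing window scan
    with genomewide percentile thresholds, and the incomplete-lineage-sorting
    (ILS) shared-haplotype length test based on a gamma recombination clock.
    A seeded generator of structured haplotype panels with a known archaic
    introgression pulse provides ground truth for every statistic, and a
    pipeline runner orchestrates the stages into reproducible, fully logged
    runs over VCF input or simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
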
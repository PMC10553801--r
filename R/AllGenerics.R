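#' Accessors for panel-like objects
#'
#' `positions()` returns the 0-based site positions, `haplotypeMatrix()` the
#' 0/1 haplotype matrix (rows are phased haplotypes), `populationLabels()`
#' and `sampleIds()` the per-row annotation, `nSites()` and `nHaplotypes()`
#' the dimensions, and `isPolarized()` whether 0/1 code ancestral/derived.
#'
#' @param x A [HaplotypePanel-class], [ArchaicGenotypes-class] or
#'   [JointPanel-class] object.
#' @return The corresponding slot content (see Description).
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname panel-accessors
#' @export
setGeneric("haplotypeMatrix", function(x) standardGeneric("haplotypeMatrix"))

#' @rdname panel-accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' @rdname panel-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname panel-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname panel-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname panel-accessors
#' @export
setGeneric("isPolarized", function(x) standardGeneric("isPolarized"))

#' @rdname panel-accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' Polarize alleles to ancestral/derived
#'
#' Recode reference/alternate alleles as ancestral (0) / derived (1) using an
#' ancestral-allele annotation.  Sites whose ancestral allele equals the
#' alternate allele are bit-flipped; sites with an unknown or third-allele
#' ancestral state are dropped.  A report counting
#' `c(unchanged, flipped, dropped)` sites is stored in the result's
#' `metadata$polarization`.
#'
#' @param x A [HaplotypePanel-class] or [ArchaicGenotypes-class] object in
#'   reference/alternate coding.
#' @param ancestral A `data.frame` with columns `chrom`, `pos` (1-based, VCF
#'   convention) and `allele`, or the path of such a tab-separated table
#'   (see [readAncestralTable()]).  Use allele `"."` or `NA` for unknown.
#' @return An object of the same class as `x`, polarized, with the report in
#'   `metadata(x)$polarization`.
#' @seealso [polarizationReport()]
#' @export
setGeneric("polarize", function(x, ancestral) standardGeneric("polarize"))

#' @rdname polarize
#' @export
setGeneric("polarizationReport", function(x) standardGeneric("polarizationReport"))
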
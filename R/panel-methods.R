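## Accessors, show and subsetting for the core S4 containers.

#' @rdname panel-accessors
setMethod("positions", "HaplotypePanel", function(x) x@positions)
#' @rdname panel-accessors
setMethod("positions", "ArchaicGenotypes", function(x) x@positions)
#' @rdname panel-accessors
setMethod("positions", "JointPanel", function(x) x@panel@positions)

#' @rdname panel-accessors
setMethod("haplotypeMatrix", "HaplotypePanel", function(x) x@haplotypes)
#' @rdname panel-accessors
setMethod("haplotypeMatrix", "JointPanel", function(x) x@panel@haplotypes)

#' @rdname panel-accessors
setMethod("populationLabels", "HaplotypePanel", function(x) x@population)
#' @rdname panel-accessors
setMethod("populationLabels", "JointPanel", function(x) x@panel@population)

#' @rdname panel-accessors
setMethod("sampleIds", "HaplotypePanel", function(x) x@sampleId)
#' @rdname panel-accessors
setMethod("sampleIds", "JointPanel", function(x) x@panel@sampleId)

#' @rdname panel-accessors
setMethod("nSites", "HaplotypePanel", function(x) length(x@positions))
#' @rdname panel-accessors
setMethod("nSites", "ArchaicGenotypes", function(x) length(x@positions))
#' @rdname panel-accessors
setMethod("nSites", "JointPanel", function(x) length(x@panel@positions))

#' @rdname panel-accessors
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@haplotypes))
#' @rdname panel-accessors
setMethod("nHaplotypes", "JointPanel", function(x) nrow(x@panel@haplotypes))

#' @rdname panel-accessors
setMethod("isPolarized", "HaplotypePanel", function(x) x@polarized)
#' @rdname panel-accessors
setMethod("isPolarized", "ArchaicGenotypes", function(x) x@polarized)

#' @rdname panel-accessors
setMethod("dosageMatrix", "ArchaicGenotypes", function(x) x@dosage)
#' @rdname panel-accessors
setMethod("dosageMatrix", "JointPanel", function(x) x@archaic@dosage)

#' Modern panel and archaic component of a JointPanel
#'
#' @param x A [JointPanel-class].
#' @return `modernPanel()` the [HaplotypePanel-class]; `archaicGenotypes()`
#'   the [ArchaicGenotypes-class]; `archaicReference()` the reference
#'   individual's name.
#' @export
modernPanel <- function(x) {
  stopifnot(is(x, "JointPanel"))
  x@panel
}

#' @rdname modernPanel
#' @export
archaicGenotypes <- function(x) {
  stopifnot(is(x, "JointPanel"))
  x@archaic
}

#' @rdname modernPanel
#' @export
archaicReference <- function(x) {
  stopifnot(is(x, "JointPanel"))
  x@reference
}

#' @rdname polarize
setMethod("polarizationReport", "HaplotypePanel",
          function(x) x@metadata$polarization)
#' @rdname polarize
setMethod("polarizationReport", "ArchaicGenotypes",
          function(x) x@metadata$polarization)

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d sites on %s (%s)\n",
              nHaplotypes(object), nSites(object), object@chrom,
              if (object@polarized) "ancestral/derived" else "ref/alt"))
  tb <- table(object@population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  if (nSites(object))
    cat(sprintf("  positions: %d..%d (0-based)\n",
                min(object@positions), max(object@positions)))
})

setMethod("show", "ArchaicGenotypes", function(object) {
  cat(sprintf("ArchaicGenotypes: %d individuals x %d sites on %s (%s)\n",
              nrow(object@dosage), nSites(object), object@chrom,
              if (object@polarized) "derived dosage" else "alt dosage"))
  if (nrow(object@dosage))
    cat("  individuals:", paste(rownames(object@dosage), collapse = ", "),
        "\n")
})

setMethod("show", "JointPanel", function(object) {
  cat(sprintf(
    "JointPanel: %d haplotypes x %d shared sites, reference '%s'\n",
    nHaplotypes(object), nSites(object), object@reference))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  sequenceLength: %g bp  (blocks of %g bp)\n",
              object@sequenceLength, object@blockLength))
  cat(sprintf("  mu: %g  recRate: %g  (per bp per generation)\n",
              object@mu, object@recRate))
  cat(sprintf(
    "  tArchaicSplit: %g  tArchaicCoalescence: %g  tAdmixture: %g  tModernCoalescence: %g\n",
    object@tArchaicSplit, object@tArchaicCoalescence, object@tAdmixture,
    object@tModernCoalescence))
  cat(sprintf(
    "  admixProportion: %g  targetFreq: %g  outgroupLeak: %g  seed: %d\n",
    object@admixProportion, object@postAdmixtureTargetFreq,
    object@outgroupLeak, object@seed))
  cat("  popSizes:",
      paste(sprintf("%s=%d", names(object@popSizes), object@popSizes),
            collapse = " "), "\n")
})

setMethod("show", "IlsParams", function(object) {
  L <- expectedIlsLength(object)
  cat(sprintf(
    "IlsParams: r=%g, t1=%g yr, t2=%g yr, g=%g, k=%g  (expected L = %.0f bp)\n",
    object@r, object@t1, object@t2, object@g, object@k, L))
})

setMethod("show", "ArchaicScanResult", function(object) {
  w <- object@windows
  cat(sprintf(
    "ArchaicScanResult: %d windows of %g bp, target '%s' vs outgroup '%s'\n",
    nrow(w), object@params$window, object@target, object@outgroup))
  cat(sprintf("  U(w=%g, x=%g, y=%g): max %s; 99.9th pct %.3g\n",
              object@params$w, object@params$x, object@params$y,
              if (nrow(w)) max(w$U) else NA, object@thresholds["u_q999"]))
  q <- w$Q95[!is.na(w$Q95)]
  cat(sprintf("  Q95 defined in %d windows; 99.9th pct %.3g\n",
              length(q), object@thresholds["q95_q999"]))
})

setMethod("show", "HaploOrdering", function(object) {
  cat(sprintf(
    "HaploOrdering: %d rows (reference first) over %d retained sites\n",
    length(object@haplotypeId), length(object@retainedSites)))
  cat(sprintf("  distance to reference: %g .. %g\n",
              min(object@distance), max(object@distance)))
})

#' Subset a HaplotypePanel
#'
#' `x[i, j]` keeps haplotype rows `i` and site columns `j` (logical, integer
#' or, for rows, population-name character indices).
#'
#' @param x A [HaplotypePanel-class].
#' @param i Haplotype rows: index vector or population name(s).
#' @param j Site columns: index vector.
#' @param ... Ignored.
#' @param drop Ignored (always `FALSE`).
#' @return A [HaplotypePanel-class].
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@haplotypes))
  if (is.character(i)) i <- which(x@population %in% i)
  if (missing(j)) j <- seq_along(x@positions)
  if (is.logical(j)) j <- which(j)
  new("HaplotypePanel", chrom = x@chrom,
      positions = x@positions[j],
      haplotypes = x@haplotypes[i, j, drop = FALSE],
      sampleId = x@sampleId[i], population = x@population[i],
      ref = if (length(x@ref)) x@ref[j] else x@ref,
      alt = if (length(x@alt)) x@alt[j] else x@alt,
      polarized = x@polarized, metadata = x@metadata)
})

#' Subset a JointPanel by site
#'
#' @param x A [JointPanel-class].
#' @param i Haplotype rows (as for [HaplotypePanel-class] subsetting).
#' @param j Site columns.
#' @param ... Ignored.
#' @param drop Ignored.
#' @return A [JointPanel-class].
#' @export
setMethod("[", "JointPanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(j)) j <- seq_along(x@panel@positions)
  if (is.logical(j)) j <- which(j)
  arch <- x@archaic
  new("JointPanel",
      panel = if (missing(i)) x@panel[, j] else x@panel[i, j],
      archaic = new("ArchaicGenotypes", chrom = arch@chrom,
                    positions = arch@positions[j],
                    dosage = arch@dosage[, j, drop = FALSE],
                    ref = if (length(arch@ref)) arch@ref[j] else arch@ref,
                    alt = if (length(arch@alt)) arch@alt[j] else arch@alt,
                    polarized = arch@polarized, metadata = arch@metadata),
      reference = x@reference)
})
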
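#' @import methods
#' @importFrom stats quantile rexp rpois runif sd setNames rbinom wilcox.test
#'   dist as.dist hclust as.dendrogram order.dendrogram reorder pgamma
#' @importFrom utils read.table write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## HaplotypePanel
## ---------------------------------------------------------------------------

#' Phased haplotype panel
#'
#' A `HaplotypePanel` holds a matrix of phased biallelic haplotypes (one row
#' per haplotype, one column per site) together with their genomic positions
#' and a haplotype-to-sample-to-population mapping.  Allele coding is either
#' reference/alternate (as read from a VCF, `polarized = FALSE`) or
#' ancestral/derived (`0` = ancestral, `1` = derived, `polarized = TRUE`).
#' Positions are 0-based internally; VCF and region-string interfaces use the
#' 1-based inclusive convention and convert at the boundary.
#'
#' @slot chrom Chromosome label (single string).
#' @slot positions Integer vector of 0-based site positions, strictly
#'   increasing.
#' @slot haplotypes Integer matrix in `{0, 1}`, one row per haplotype.
#' @slot sampleId Character vector, the sample each haplotype row belongs to.
#' @slot population Character vector, one population label per haplotype row.
#' @slot ref,alt Character vectors of reference/alternate alleles per site
#'   (may be empty for simulated or polarized panels that no longer track
#'   nucleotide identity).
#' @slot polarized Logical flag: `TRUE` when 0/1 mean ancestral/derived.
#' @slot metadata List of provenance entries (read logs, polarization
#'   reports).
#'
#' @seealso [readPhasedVcf()], [polarize()], [simulateStructuredPanel()]
#' @export
setClass("HaplotypePanel",
  representation(
    chrom = "character",
    positions = "integer",
    haplotypes = "matrix",
    sampleId = "character",
    population = "character",
    ref = "character",
    alt = "character",
    polarized = "logical",
    metadata = "list"
  ),
  prototype(
    chrom = "chr1", positions = integer(0),
    haplotypes = matrix(integer(0), nrow = 0, ncol = 0),
    sampleId = character(0), population = character(0),
    ref = character(0), alt = character(0),
    polarized = FALSE, metadata = list()
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character(0)
  if (length(object@chrom) != 1L)
    msg <- c(msg, "'chrom' must be a single string")
  if (ncol(object@haplotypes) != length(object@positions))
    msg <- c(msg, "matrix width must equal the number of positions")
  if (length(object@positions) > 1L &&
      any(diff(object@positions) <= 0L))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (length(object@positions) && any(object@positions < 0L))
    msg <- c(msg, "'positions' must be non-negative (0-based)")
  if (nrow(object@haplotypes) != length(object@sampleId) ||
      nrow(object@haplotypes) != length(object@population))
    msg <- c(msg, "each haplotype row needs one sampleId and one population")
  vals <- object@haplotypes
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "haplotype matrix entries must be 0 or 1")
  if (length(object@ref) && length(object@ref) != length(object@positions))
    msg <- c(msg, "'ref' must be empty or one allele per site")
  if (length(object@alt) && length(object@alt) != length(object@positions))
    msg <- c(msg, "'alt' must be empty or one allele per site")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param chrom Chromosome label.
#' @param positions Integer vector of 0-based positions, strictly increasing.
#' @param haplotypes 0/1 matrix, one row per haplotype.
#' @param population Population label per row.
#' @param sampleId Sample id per row; defaults to one pseudo-sample per
#'   haplotype.
#' @param ref,alt Optional per-site alleles.
#' @param polarized Whether 0/1 code ancestral/derived.
#' @param metadata Optional list of provenance entries.
#' @return A [HaplotypePanel-class] object.
#' @examples
#' p <- HaplotypePanel("chr4", c(0L, 100L), rbind(c(0, 1), c(1, 1)),
#'                     population = c("YRI", "CHB"))
#' nSites(p)
#' @export
HaplotypePanel <- function(chrom, positions, haplotypes, population,
                           sampleId = NULL, ref = character(0),
                           alt = character(0), polarized = TRUE,
                           metadata = list()) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (is.null(sampleId))
    sampleId <- sprintf("hap%03d", seq_len(nrow(haplotypes)))
  new("HaplotypePanel", chrom = as.character(chrom),
      positions = as.integer(positions), haplotypes = haplotypes,
      sampleId = as.character(sampleId),
      population = as.character(population),
      ref = as.character(ref), alt = as.character(alt),
      polarized = polarized, metadata = metadata)
}

## ---------------------------------------------------------------------------
## ArchaicGenotypes
## ---------------------------------------------------------------------------

#' Archaic diploid genotypes
#'
#' Diploid genotypes for one or more archaic individuals as allele dosages
#' (0 = homozygous reference/ancestral, 1 = heterozygous, 2 = homozygous
#' alternate/derived, `NA` = missing).  Coding follows the `polarized` flag
#' exactly as in [HaplotypePanel-class].
#'
#' @slot chrom Chromosome label.
#' @slot positions Integer vector of 0-based positions, strictly increasing.
#' @slot dosage Integer matrix, one row per individual (rownames are the
#'   individual names), values in `{0, 1, 2, NA}`.
#' @slot ref,alt Optional per-site alleles.
#' @slot polarized Logical; `TRUE` when dosages count derived alleles.
#' @slot metadata Provenance list.
#' @export
setClass("ArchaicGenotypes",
  representation(
    chrom = "character",
    positions = "integer",
    dosage = "matrix",
    ref = "character",
    alt = "character",
    polarized = "logical",
    metadata = "list"
  ),
  prototype(
    chrom = "chr1", positions = integer(0),
    dosage = matrix(integer(0), nrow = 0, ncol = 0),
    ref = character(0), alt = character(0),
    polarized = FALSE, metadata = list()
  )
)

setValidity("ArchaicGenotypes", function(object) {
  msg <- character(0)
  if (ncol(object@dosage) != length(object@positions))
    msg <- c(msg, "dosage width must equal the number of positions")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (is.null(rownames(object@dosage)) && nrow(object@dosage) > 0L)
    msg <- c(msg, "dosage rows must be named by individual")
  vals <- object@dosage
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L) | is.na(vals)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an ArchaicGenotypes object
#'
#' @param chrom Chromosome label.
#' @param positions 0-based positions, strictly increasing.
#' @param dosage Dosage matrix (individuals x sites), rownames required.
#' @param ref,alt Optional per-site alleles.
#' @param polarized Whether dosages count derived alleles.
#' @param metadata Provenance list.
#' @return An [ArchaicGenotypes-class] object.
#' @export
ArchaicGenotypes <- function(chrom, positions, dosage, ref = character(0),
                             alt = character(0), polarized = TRUE,
                             metadata = list()) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  new("ArchaicGenotypes", chrom = as.character(chrom),
      positions = as.integer(positions), dosage = dosage,
      ref = as.character(ref), alt = as.character(alt),
      polarized = polarized, metadata = metadata)
}

## ---------------------------------------------------------------------------
## JointPanel
## ---------------------------------------------------------------------------

#' Modern panel aligned with archaic genotypes
#'
#' A polarized [HaplotypePanel-class] restricted to the sites that are
#' genotyped and homozygous in a designated archaic reference individual
#' (the Denisova role in the archaic-sharing analyses), together with the
#' archaic dosages on exactly those sites.  Other archaic individuals may be
#' heterozygous or missing at retained sites.
#'
#' @slot panel The modern [HaplotypePanel-class].
#' @slot archaic [ArchaicGenotypes-class] on the same sites.
#' @slot reference Name of the archaic reference individual; its dosage row
#'   contains only 0 or 2.
#' @export
setClass("JointPanel",
  representation(
    panel = "HaplotypePanel",
    archaic = "ArchaicGenotypes",
    reference = "character"
  )
)

setValidity("JointPanel", function(object) {
  msg <- character(0)
  if (!identical(object@panel@positions, object@archaic@positions))
    msg <- c(msg, "panel and archaic site lists must be identical")
  if (length(object@reference) != 1L ||
      !(object@reference %in% rownames(object@archaic@dosage)))
    msg <- c(msg, "'reference' must name one archaic individual")
  else {
    d <- object@archaic@dosage[object@reference, ]
    if (anyNA(d) || any(d == 1L))
      msg <- c(msg, "reference individual must be genotyped and homozygous at every retained site")
  }
  if (!object@panel@polarized)
    msg <- c(msg, "panel must be polarized (0 = ancestral, 1 = derived)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Configuration of the structured-panel simulator
#'
#' Parameters of the seeded generator behind [simulateStructuredPanel()].
#' Times are in generations, rates per bp per generation.  The generator
#' draws the modern background from a per-block Kingman coalescent (mean
#' pairwise coalescence time `tModernCoalescence`), attaches an archaic
#' lineage that diverged `tArchaicSplit` generations ago, and overlays a
#' single shared introgressed tract copied from the archaic donor haplotype
#' onto a fixed fraction of target (and, via `outgroupLeak`, outgroup)
#' haplotypes.
#'
#' @slot sequenceLength Simulated chromosome length in bp.
#' @slot mu Mutation rate per bp per generation.
#' @slot recRate Recombination rate per bp per generation (controls the
#'   exponential introgressed tract length, mean `1/(recRate*tAdmixture)`).
#' @slot tArchaicSplit Archaic/modern split, generations before present.
#' @slot tArchaicCoalescence Within-archaic coalescence time (controls
#'   archaic heterozygosity), generations.
#' @slot tAdmixture Introgression pulse, generations before present; must be
#'   younger than `tArchaicSplit`.
#' @slot tModernCoalescence Mean pairwise coalescence time of the modern
#'   background, generations (the coalescent is run with `Ne` equal to half
#'   this value).
#' @slot admixProportion Initial archaic pulse fraction in `[0, 1]`; the
#'   pulse is suppressed entirely when 0.
#' @slot postAdmixtureTargetFreq Present-day carrier fraction of the
#'   introgressed tract in each target population (selection surrogate:
#'   the frequency is set, not evolved).
#' @slot outgroupLeak Carrier fraction in the outgroup population
#'   (back-migration surrogate).
#' @slot blockLength Length in bp of the independently simulated genealogy
#'   blocks (free recombination between blocks, none within).
#' @slot popSizes Named integer vector of haplotype counts for
#'   `outgroup`, `target1`, `target2`, `oceanian`; all even and `>= 2`.
#' @slot seed Integer seed; all randomness flows from it.
#' @export
setClass("SimulationConfig",
  representation(
    sequenceLength = "numeric",
    mu = "numeric",
    recRate = "numeric",
    tArchaicSplit = "numeric",
    tArchaicCoalescence = "numeric",
    tAdmixture = "numeric",
    tModernCoalescence = "numeric",
    admixProportion = "numeric",
    postAdmixtureTargetFreq = "numeric",
    outgroupLeak = "numeric",
    blockLength = "numeric",
    popSizes = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  chk1 <- function(x, nm) if (length(slot(object, nm)) != 1L ||
                              !is.finite(slot(object, nm)))
    sprintf("'%s' must be a single finite number", nm) else character(0)
  for (nm in c("sequenceLength", "mu", "recRate", "tArchaicSplit",
               "tArchaicCoalescence", "tAdmixture", "tModernCoalescence",
               "admixProportion", "postAdmixtureTargetFreq", "outgroupLeak",
               "blockLength"))
    msg <- c(msg, chk1(slot(object, nm), nm))
  if (!length(msg)) {
    if (object@sequenceLength < 1) msg <- c(msg, "'sequenceLength' must be >= 1")
    if (object@mu < 0) msg <- c(msg, "'mu' must be >= 0")
    if (object@recRate < 0) msg <- c(msg, "'recRate' must be >= 0")
    if (object@tArchaicSplit <= 0) msg <- c(msg, "'tArchaicSplit' must be > 0")
    if (object@tArchaicCoalescence < 0 ||
        object@tArchaicCoalescence >= object@tArchaicSplit)
      msg <- c(msg, "'tArchaicCoalescence' must be in [0, tArchaicSplit)")
    if (object@tAdmixture <= 0 || object@tAdmixture >= object@tArchaicSplit)
      msg <- c(msg, "'tAdmixture' must be positive and < 'tArchaicSplit'")
    if (object@tModernCoalescence <= 0)
      msg <- c(msg, "'tModernCoalescence' must be > 0")
    for (nm in c("admixProportion", "postAdmixtureTargetFreq", "outgroupLeak")) {
      v <- slot(object, nm)
      if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must be in [0, 1]", nm))
    }
    if (object@blockLength < 1) msg <- c(msg, "'blockLength' must be >= 1")
    ps <- object@popSizes
    if (!identical(sort(names(ps)),
                   sort(c("outgroup", "target1", "target2", "oceanian"))))
      msg <- c(msg,
        "'popSizes' must name outgroup, target1, target2 and oceanian")
    else if (any(ps < 2L) || any(ps %% 2L != 0L))
      msg <- c(msg, "'popSizes' entries must be even and >= 2")
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "'seed' must be a single integer")
  }
  if (length(msg)) msg else TRUE
})

#' Default simulator configuration
#'
#' Defaults emulate the data structure of the zinc-transporter introgression
#' study at desk scale: a 4 Mb chromosome (one hundred 40 kb scan windows),
#' human-like mutation rate, the target region's average recombination rate
#' (1.58 cM/Mb), an archaic donor diverged 22,000 generations ago (550 kya
#' at 25 years per generation), a single admixture pulse 1,500 generations
#' ago whose tract segregates at frequency 0.7 in both target populations
#' and the Oceanian-like population, and a 5% back-migrated presence in the
#' African-like outgroup.  The tract extends exponentially (mean
#' `1/(recRate*tAdmixture)`, ~42 kb) to each side of its focal adaptive
#' site, giving a mean total length of ~84 kb, on the scale of the ~70.6 kb
#' haplotype the scan statistics are designed to recover.
#'
#' @param sequenceLength,mu,recRate,tArchaicSplit,tArchaicCoalescence
#'   See [SimulationConfig-class].
#' @param tAdmixture,tModernCoalescence,admixProportion See
#'   [SimulationConfig-class].
#' @param postAdmixtureTargetFreq,outgroupLeak,blockLength,popSizes,seed See
#'   [SimulationConfig-class].
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(sequenceLength = 4e5, seed = 1L)
#' cfg
#' @export
SimulationConfig <- function(sequenceLength = 4e6,
                             mu = 1.25e-8,
                             recRate = 1.58e-8,
                             tArchaicSplit = 22000,
                             tArchaicCoalescence = 2000,
                             tAdmixture = 1500,
                             tModernCoalescence = 10000,
                             admixProportion = 0.02,
                             postAdmixtureTargetFreq = 0.7,
                             outgroupLeak = 0.05,
                             blockLength = 40000,
                             popSizes = c(outgroup = 50L, target1 = 50L,
                                          target2 = 50L, oceanian = 20L),
                             seed = 1L) {
  obj <- new("SimulationConfig",
             sequenceLength = sequenceLength, mu = mu, recRate = recRate,
             tArchaicSplit = tArchaicSplit,
             tArchaicCoalescence = tArchaicCoalescence,
             tAdmixture = tAdmixture,
             tModernCoalescence = tModernCoalescence,
             admixProportion = admixProportion,
             postAdmixtureTargetFreq = postAdmixtureTargetFreq,
             outgroupLeak = outgroupLeak, blockLength = blockLength,
             popSizes = setNames(as.integer(popSizes), names(popSizes)),
             seed = as.integer(seed))
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid simulation configuration: ", paste(ok, collapse = "; "),
         call. = FALSE)
  obj
}

## ---------------------------------------------------------------------------
## IlsParams
## ---------------------------------------------------------------------------

#' Parameters of the ILS shared-haplotype length test
#'
#' Parameters of the recombination clock used to ask whether a haplotype
#' shared between modern and archaic humans could persist by incomplete
#' lineage sorting (ILS) alone.  The expected shared length is
#' `L = 1 / (r * (t1 + t2) / g)` and the survival probability of an observed
#' length is the upper tail of a Gamma(shape `k`, rate `1/L`).
#'
#' Defaults are the published calibration for the zinc-transporter region:
#' the region's average recombination rate 1.58 cM/Mb, split times rescaled
#' to a mutation rate of 1e-9 per bp per year (t1 = 275,000 years between
#' modern and archaic humans; t2 = 190,500 years between Denisovans and
#' Neanderthals), 25 years per generation and shape k = 2.
#'
#' @slot r Recombination rate per bp per generation.
#' @slot t1 Modern/archaic split time in years.
#' @slot t2 Denisovan/Neanderthal split time in years.
#' @slot g Years per generation.
#' @slot k Gamma shape (integer, >= 1).
#' @export
setClass("IlsParams",
  representation(r = "numeric", t1 = "numeric", t2 = "numeric",
                 g = "numeric", k = "numeric"))

setValidity("IlsParams", function(object) {
  msg <- character(0)
  for (nm in c("r", "t1", "t2", "g", "k")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
  }
  if (!length(msg) && (object@k < 1 || object@k != round(object@k)))
    msg <- c(msg, "'k' must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname IlsParams-class
#' @param r,t1,t2,g,k See slots.
#' @return A validated [IlsParams-class] object.
#' @examples
#' expectedIlsLength(IlsParams())
#' @export
IlsParams <- function(r = 1.58e-8, t1 = 275000, t2 = 190500, g = 25, k = 2) {
  obj <- new("IlsParams", r = r, t1 = t1, t2 = t2, g = g, k = k)
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid ILS parameters: ", paste(ok, collapse = "; "), call. = FALSE)
  obj
}

## ---------------------------------------------------------------------------
## ArchaicScanResult
## ---------------------------------------------------------------------------

#' Result of the windowed U/Q95 archaic-sharing scan
#'
#' @slot windows `data.frame` with one row per window: `chrom`, `start`,
#'   `end` (0-based half-open), `nSites`, `nQualifying`, `U`, `Q95`
#'   (`NA` when no site passes the outgroup and archaic conditions),
#'   and significance flags at the two percentile thresholds.
#' @slot thresholds Named numeric vector: genomewide `u_q99`, `u_q999`,
#'   `q95_q99`, `q95_q999` (linear-interpolation percentiles).
#' @slot params Named list of scan parameters (`w`, `x`, `y`, `window`).
#' @slot outgroup,target Population labels used.
#' @export
setClass("ArchaicScanResult",
  representation(windows = "data.frame", thresholds = "numeric",
                 params = "list", outgroup = "character",
                 target = "character"))

## ---------------------------------------------------------------------------
## HaploOrdering
## ---------------------------------------------------------------------------

#' Haplostrips-style ordering of haplotypes
#'
#' Row order of a haplotype panel after minor-allele-frequency filtering,
#' hierarchical clustering and leaf rotation so that distance to the archaic
#' reference is non-decreasing wherever the dendrogram permits; the reference
#' occupies the first row at distance 0.
#'
#' @slot haplotypeId Haplotype labels in display order (reference first).
#' @slot population Population label per displayed row.
#' @slot distance Distance to the archaic reference per displayed row
#'   (homozygous mismatch 1, heterozygous archaic 0.5, missing excluded).
#' @slot comparable Number of comparable (non-missing) sites per row.
#' @slot order Integer permutation of the input panel rows (0 marks the
#'   prepended reference row).
#' @slot retainedSites Indices of sites surviving the MAF filter, relative
#'   to the input panel.
#' @slot matrix The filtered 0/1 matrix in display order (reference first),
#'   for plotting.
#' @export
setClass("HaploOrdering",
  representation(haplotypeId = "character", population = "character",
                 distance = "numeric", comparable = "numeric",
                 order = "integer", retainedSites = "integer",
                 matrix = "matrix"))
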
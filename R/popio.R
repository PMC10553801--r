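## Reading and writing the standard formats, ancestral/derived polarization
## and alignment of modern panels with archaic genotypes.
##
## Coordinate conventions: VCF, ancestral-allele tables and region strings
## are 1-based inclusive; HaplotypePanel positions and BED are 0-based
## half-open.  Conversion happens here and nowhere else.

#' Read a phased VCF into a HaplotypePanel
#'
#' Reads phased diploid genotypes for the samples listed in a population
#' panel table and returns a reference/alternate-coded
#' [HaplotypePanel-class] with two haplotype rows per sample.  Multiallelic
#' sites, sites with any unphased genotype and sites with any missing
#' genotype are dropped panel-wide; the counts are recorded in
#' `metadata(x)$readLog`.
#'
#' @param vcf Path to a VCF 4.2 file (plain text or bgzip).
#' @param panel Path to a tab-separated table with columns `sample` and
#'   `population`, or an equivalent `data.frame`.
#' @param region Optional region string `"chrom:start-end"` (1-based
#'   inclusive); records outside it are discarded.
#' @return A [HaplotypePanel-class] with `polarized = FALSE`.
#' @seealso [polarize()] to recode to ancestral/derived.
#' @export
readPhasedVcf <- function(vcf, panel, region = NULL) {
  if (is.character(panel))
    panel <- read.table(panel, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(panel)))
    stop("panel table needs 'sample' and 'population' columns",
         call. = FALSE)
  v <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  have <- colnames(v)
  missing <- setdiff(panel$sample, have)
  if (length(missing))
    stop("samples in panel but not in VCF: ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- v[, panel$sample]
  rr <- SummarizedExperiment::rowRanges(v)
  keep <- rep(TRUE, length(rr))
  if (!is.null(region)) {
    gr <- parseRegion(region)
    keep <- as.vector(GenomicRanges::seqnames(rr)) ==
      as.character(GenomicRanges::seqnames(gr)) &
      GenomicRanges::start(rr) >= GenomicRanges::start(gr) &
      GenomicRanges::start(rr) <= GenomicRanges::end(gr)
  }
  nMulti <- sum(S4Vectors::elementNROWS(VariantAnnotation::alt(v)) != 1L &
                  keep)
  keep <- keep & S4Vectors::elementNROWS(VariantAnnotation::alt(v)) == 1L
  gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]
  rr <- rr[keep]
  miss <- rowSums(matrix(grepl("\\.", gt), nrow = nrow(gt))) > 0L
  unph <- rowSums(matrix(!grepl("^[0-9]+\\|[0-9]+$", gt) & !grepl("\\.", gt),
                         nrow = nrow(gt))) > 0L
  nMissing <- sum(miss)
  nUnphased <- sum(unph & !miss)
  gt <- gt[!miss & !unph, , drop = FALSE]
  rr <- rr[!miss & !unph]
  ord <- order(GenomicRanges::start(rr))
  gt <- gt[ord, , drop = FALSE]
  rr <- rr[ord]
  if (anyDuplicated(GenomicRanges::start(rr)))
    stop("duplicated positions in VCF after filtering", call. = FALSE)
  chrom <- if (length(rr)) as.character(GenomicRanges::seqnames(rr)[1L])
           else "chrUnknown"
  nS <- nrow(gt)
  nSamp <- nrow(panel)
  M <- matrix(0L, nrow = 2L * nSamp, ncol = nS)
  if (nS) {
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    M[seq(1L, 2L * nSamp, by = 2L), ] <- t(matrix(as.integer(a1 != "0"),
                                                  nrow = nS))
    M[seq(2L, 2L * nSamp, by = 2L), ] <- t(matrix(as.integer(a2 != "0"),
                                                  nrow = nS))
  }
  refA <- as.character(VariantAnnotation::ref(v)[keep][!miss & !unph][ord])
  altA <- as.character(unlist(VariantAnnotation::alt(v)[keep])[!miss & !unph][ord])
  msg <- sprintf("dropped sites: %d multiallelic, %d unphased, %d missing",
                 nMulti, nUnphased, nMissing)
  if (nMulti + nUnphased + nMissing > 0) message(msg)
  HaplotypePanel(
    chrom = chrom,
    positions = as.integer(GenomicRanges::start(rr)) - 1L,
    haplotypes = M,
    population = rep(panel$population, each = 2L),
    sampleId = rep(panel$sample, each = 2L),
    ref = refA, alt = altA, polarized = FALSE,
    metadata = list(readLog = c(multiallelic = nMulti,
                                unphased = nUnphased,
                                missing = nMissing)))
}

#' Read archaic diploid genotypes from a VCF
#'
#' Genotypes are returned as alternate-allele dosages (0/1/2, `NA` for
#' missing) for every sample in the VCF; heterozygous and missing genotypes
#' are retained.  Multiallelic sites are dropped with a logged count.
#'
#' @param vcf Path to a VCF file.
#' @param region Optional region string (1-based inclusive).
#' @return An [ArchaicGenotypes-class] with `polarized = FALSE`.
#' @export
readArchaicVcf <- function(vcf, region = NULL) {
  v <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  keep <- S4Vectors::elementNROWS(VariantAnnotation::alt(v)) == 1L
  if (!is.null(region)) {
    gr <- parseRegion(region)
    keep <- keep & as.vector(GenomicRanges::seqnames(rr)) ==
      as.character(GenomicRanges::seqnames(gr)) &
      GenomicRanges::start(rr) >= GenomicRanges::start(gr) &
      GenomicRanges::start(rr) <= GenomicRanges::end(gr)
  }
  nMulti <- sum(!keep)
  gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]
  rr <- rr[keep]
  ord <- order(GenomicRanges::start(rr))
  gt <- gt[ord, , drop = FALSE]
  rr <- rr[ord]
  chrom <- if (length(rr)) as.character(GenomicRanges::seqnames(rr)[1L])
           else "chrUnknown"
  dose <- function(g) {
    a1 <- substr(g, 1L, 1L)
    a2 <- substr(g, 3L, 3L)
    d <- (a1 != "0") + (a2 != "0")
    d[a1 == "." | a2 == "."] <- NA_integer_
    as.integer(d)
  }
  D <- t(apply(gt, 2L, dose))
  if (!is.matrix(D)) D <- matrix(D, nrow = ncol(gt))
  rownames(D) <- colnames(gt)
  ArchaicGenotypes(
    chrom = chrom,
    positions = as.integer(GenomicRanges::start(rr)) - 1L,
    dosage = D,
    ref = as.character(VariantAnnotation::ref(v)[keep][ord]),
    alt = as.character(unlist(VariantAnnotation::alt(v)[keep])[ord]),
    polarized = FALSE,
    metadata = list(readLog = c(multiallelic = nMulti)))
}

#' Read an ancestral-allele table
#'
#' @param path Tab-separated file with columns `chrom`, `pos` (1-based) and
#'   `allele` (`"."` or empty for unknown).
#' @return A `data.frame`.
#' @export
readAncestralTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "character"))
}

## shared polarization bookkeeping: returns per-site action
## ("keep", "flip" or "drop") given ref/alt and the ancestral table
polarizeActions <- function(chrom, positions0, ref, alt, ancestral) {
  if (is.character(ancestral)) ancestral <- readAncestralTable(ancestral)
  if (!all(c("pos", "allele") %in% names(ancestral)))
    stop("ancestral table needs 'pos' and 'allele' columns", call. = FALSE)
  if (!length(ref) || !length(alt))
    stop("polarization requires ref/alt alleles on the input object",
         call. = FALSE)
  idx <- match(positions0 + 1L, ancestral$pos)
  aa <- toupper(ancestral$allele[idx])
  aa[is.na(aa) | aa == "." | aa == "" | aa == "N"] <- NA
  action <- rep("drop", length(positions0))
  action[!is.na(aa) & aa == toupper(ref)] <- "keep"
  action[!is.na(aa) & aa == toupper(alt)] <- "flip"
  action
}

#' @rdname polarize
setMethod("polarize", "HaplotypePanel", function(x, ancestral) {
  action <- polarizeActions(x@chrom, x@positions, x@ref, x@alt, ancestral)
  keep <- action != "drop"
  M <- x@haplotypes[, keep, drop = FALSE]
  flip <- action[keep] == "flip"
  M[, flip] <- 1L - M[, flip, drop = FALSE]
  report <- c(unchanged = sum(action == "keep"),
              flipped = sum(action == "flip"),
              dropped = sum(action == "drop"))
  anc <- ifelse(flip, x@alt[keep], x@ref[keep])
  der <- ifelse(flip, x@ref[keep], x@alt[keep])
  meta <- x@metadata
  meta$polarization <- report
  HaplotypePanel(chrom = x@chrom, positions = x@positions[keep],
                 haplotypes = M, population = x@population,
                 sampleId = x@sampleId, ref = anc, alt = der,
                 polarized = TRUE, metadata = meta)
})

#' @rdname polarize
setMethod("polarize", "ArchaicGenotypes", function(x, ancestral) {
  action <- polarizeActions(x@chrom, x@positions, x@ref, x@alt, ancestral)
  keep <- action != "drop"
  D <- x@dosage[, keep, drop = FALSE]
  flip <- action[keep] == "flip"
  D[, flip] <- 2L - D[, flip, drop = FALSE]
  report <- c(unchanged = sum(action == "keep"),
              flipped = sum(action == "flip"),
              dropped = sum(action == "drop"))
  anc <- ifelse(flip, x@alt[keep], x@ref[keep])
  der <- ifelse(flip, x@ref[keep], x@alt[keep])
  meta <- x@metadata
  meta$polarization <- report
  ArchaicGenotypes(chrom = x@chrom, positions = x@positions[keep],
                   dosage = D, ref = anc, alt = der, polarized = TRUE,
                   metadata = meta)
})

#' Align a modern panel with archaic genotypes
#'
#' Restricts a polarized panel and a polarized set of archaic genotypes to
#' their shared sites and keeps only the sites at which the designated
#' reference individual (the Denisova role) is genotyped and homozygous.
#' Other archaic individuals may be heterozygous or missing at retained
#' sites; their genotypes are carried along unchanged.
#'
#' @param panel Polarized [HaplotypePanel-class].
#' @param archaic Polarized [ArchaicGenotypes-class] on the same assembly.
#' @param reference Name of the reference archaic individual (default
#'   `"Denisova"`).
#' @return A [JointPanel-class].
#' @export
mergeWithArchaic <- function(panel, archaic, reference = "Denisova") {
  if (!isPolarized(panel) || !isPolarized(archaic))
    stop("both panel and archaic genotypes must be polarized first",
         call. = FALSE)
  if (!reference %in% rownames(archaic@dosage))
    stop("reference individual '", reference,
         "' not present in archaic genotypes", call. = FALSE)
  shared <- intersect(positions(panel), positions(archaic))
  if (!length(shared))
    stop("empty overlap: panel and archaic genotypes share no sites",
         call. = FALSE)
  pj <- match(shared, positions(panel))
  aj <- match(shared, positions(archaic))
  refDose <- archaic@dosage[reference, aj]
  hom <- !is.na(refDose) & refDose != 1L
  pj <- pj[hom]
  aj <- aj[hom]
  if (!length(pj))
    stop("empty overlap: no site is homozygous in '", reference, "'",
         call. = FALSE)
  sub <- panel[, pj]
  archSub <- new("ArchaicGenotypes", chrom = archaic@chrom,
                 positions = archaic@positions[aj],
                 dosage = archaic@dosage[, aj, drop = FALSE],
                 ref = if (length(archaic@ref)) archaic@ref[aj] else character(0),
                 alt = if (length(archaic@alt)) archaic@alt[aj] else character(0),
                 polarized = TRUE, metadata = archaic@metadata)
  new("JointPanel", panel = sub, archaic = archSub, reference = reference)
}

#' Write result tables as TSV
#'
#' Writes each table of a named list as `<name>.tsv` with a header row,
#' tab separation, the column order given and `NA` serialized as `"NA"`.
#' Files are written atomically (temp file + rename).
#'
#' @param tables Named list of `data.frame`s.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
writeResultsTsv <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory '", dir, "'", call. = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    atomicWriteTsv(tables[[nm]], p)
    p
  }, character(1))
  paths
}
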
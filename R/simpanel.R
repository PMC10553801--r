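## Seeded generator of structured haplotype panels with known archaic
## introgression.  The modern background is a Kingman coalescent run
## independently per block (free recombination between blocks, none within);
## the archaic lineage diverges tArchaicSplit generations before present and
## accumulates branch mutations under the infinite-sites approximation; a
## single introgressed tract (uniform start, exponential length) is copied
## from the archaic donor haplotype onto a fixed fraction of target
## haplotypes, plus a minor back-migrated presence in the outgroup.

## Kingman coalescent genealogy for n labelled leaves with effective size Ne
## (pairwise coalescence rate 1/(2*Ne) per generation, so the mean pairwise
## coalescence time is 2*Ne generations).
kingmanTree <- function(n, Ne) {
  nn <- 2L * n - 1L
  parent <- integer(nn)
  child1 <- integer(nn)
  child2 <- integer(nn)
  tim <- numeric(nn)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1L, rate = k * (k - 1) / 2 / (2 * Ne))
    pick <- sample(length(active), 2L)
    pair <- active[pick]
    parent[pair] <- nxt
    child1[nxt] <- pair[1L]
    child2[nxt] <- pair[2L]
    tim[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  ## leaf descendants per node; children always have smaller indices
  leaves <- vector("list", nn)
  leaves[seq_len(n)] <- as.list(seq_len(n))
  for (nd in seq.int(n + 1L, nn))
    leaves[[nd]] <- c(leaves[[child1[nd]]], leaves[[child2[nd]]])
  list(parent = parent, time = tim, leaves = leaves, n = n, nn = nn)
}

#' Draw introgressed tract lengths
#'
#' Tract lengths follow the standard recombination-clock model: exponential
#' with mean `1/(recRate * tAdmixture)` bp, rounded up to at least 1 bp.
#' Draws consume the current R random number stream; seed with `set.seed()`
#' for reproducibility.
#'
#' @param recRate Recombination rate per bp per generation (> 0).
#' @param tAdmixture Time of the admixture pulse in generations (> 0).
#' @param n Number of draws.
#' @return Numeric vector of `n` tract lengths in bp (each `>= 1`).
#' @examples
#' set.seed(1)
#' mean(sampleTractLength(1e-8, 2000, 1000))
#' @export
sampleTractLength <- function(recRate, tAdmixture, n = 1L) {
  if (!is.finite(recRate) || recRate <= 0)
    stop("'recRate' must be > 0", call. = FALSE)
  if (!is.finite(tAdmixture) || tAdmixture <= 0)
    stop("'tAdmixture' must be > 0", call. = FALSE)
  ceiling(rexp(n, rate = recRate * tAdmixture))
}

#' Simulate a structured haplotype panel with archaic introgression
#'
#' Generates a phased modern panel (an African-like `outgroup`, two
#' non-African targets and an `oceanian`-like population), a diploid archaic
#' individual built from two simulated archaic haplotypes (so heterozygous
#' sites occur naturally), and the ground-truth introgressed tracts.
#' Everything is deterministic given `config@seed`.
#'
#' The model is a fixed-topology donor-copying model, not a full
#' coalescent-with-recombination: modern haplotypes descend from a neutral
#' Kingman genealogy drawn independently per `blockLength` block; the
#' archaic lineage carries independent Poisson branch mutations (shared
#' branch of length `tArchaicSplit - tArchaicCoalescence` appearing
#' homozygous, plus per-haplotype private mutations appearing heterozygous);
#' carriers copy archaic haplotype 1 over a single shared tract and add
#' private Poisson(`mu * tractLength * tAdmixture`) post-admixture
#' mutations.  The shared tract is anchored at a uniformly placed focal
#' adaptive site and extends an independent exponential distance (mean
#' `1/(recRate * tAdmixture)`) to each side, reflecting that an adaptively
#' introgressed haplotype is ascertained around its selected variant.  Each
#' mutation hits a new position (infinite sites; collisions are re-drawn).
#'
#' @param config A [SimulationConfig-class] object.
#' @return A list with elements:
#'   \describe{
#'     \item{panel}{Polarized [HaplotypePanel-class] of modern haplotypes.}
#'     \item{archaic}{[ArchaicGenotypes-class] with one diploid individual
#'       (`"Denisova"`, the donor role) on the union site list.}
#'     \item{tracts}{`data.frame` of truth tracts (`haplotype`, `start`,
#'       `end`; 0-based half-open).}
#'     \item{donor}{Integer vector: the donor haplotype (archaic haplotype
#'       1) over the panel's site list.}
#'     \item{config}{The input configuration.}
#'   }
#' @examples
#' sim <- simulateStructuredPanel(SimulationConfig(sequenceLength = 2e5,
#'                                                 seed = 7L))
#' sim$panel
#' @export
simulateStructuredPanel <- function(config) {
  ok <- validObject(config, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid simulation configuration: ", paste(ok, collapse = "; "),
         call. = FALSE)
  set.seed(config@seed)
  L <- as.integer(config@sequenceLength)
  B <- as.integer(config@blockLength)
  mu <- config@mu
  nPop <- config@popSizes[c("outgroup", "target1", "target2", "oceanian")]
  nHap <- sum(nPop)
  popLab <- rep(names(nPop), nPop)
  Ne <- config@tModernCoalescence / 2

  used <- logical(L)
  drawPositions <- function(lo, hi, n) {
    ## n distinct unused 1-based positions in [lo, hi]
    out <- integer(0)
    if (n > hi - lo + 1L - sum(used[lo:hi]))
      stop("infinite-sites approximation exhausted: block saturated",
           call. = FALSE)
    while (length(out) < n) {
      cand <- unique(sample.int(hi - lo + 1L, n - length(out),
                                replace = TRUE) + lo - 1L)
      cand <- cand[!used[cand]]
      used[cand] <<- TRUE
      out <- c(out, cand)
    }
    out
  }

  modPos <- vector("list", 0L)
  modCarriers <- vector("list", 0L)
  archShared <- integer(0)
  archH1 <- integer(0)
  archH2 <- integer(0)

  blockStarts <- seq.int(1L, L, by = B)
  for (bs in blockStarts) {
    be <- min(bs + B - 1L, L)
    blen <- be - bs + 1L
    ## modern background
    if (mu > 0) {
      tr <- kingmanTree(nHap, Ne)
      nonroot <- seq_len(tr$nn - 1L)
      elen <- tr$time[tr$parent[nonroot]] - tr$time[nonroot]
      nm <- rpois(length(nonroot), mu * blen * elen)
      hit <- nonroot[nm > 0L]
      for (nd in hit) {
        k <- nm[nd]
        pp <- drawPositions(bs, be, k)
        modPos <- c(modPos, as.list(pp))
        modCarriers <- c(modCarriers, rep(list(tr$leaves[[nd]]), k))
      }
      ## archaic lineage: shared branch (homozygous) + private (het)
      nsh <- rpois(1L, mu * blen *
                     (config@tArchaicSplit - config@tArchaicCoalescence))
      if (nsh > 0L) archShared <- c(archShared, drawPositions(bs, be, nsh))
      np1 <- rpois(1L, mu * blen * config@tArchaicCoalescence)
      if (np1 > 0L) archH1 <- c(archH1, drawPositions(bs, be, np1))
      np2 <- rpois(1L, mu * blen * config@tArchaicCoalescence)
      if (np2 > 0L) archH2 <- c(archH2, drawPositions(bs, be, np2))
    }
  }

  ## introgression pulse: one shared tract, fixed carrier fractions
  tracts <- data.frame(haplotype = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  carriers <- integer(0)
  tractStart <- tractEnd <- NA_integer_
  privPos <- vector("list", 0L)
  privCarrier <- integer(0)
  doPulse <- config@admixProportion > 0 &&
    (config@postAdmixtureTargetFreq > 0 || config@outgroupLeak > 0)
  if (doPulse && config@recRate > 0) {
    ## the tract is ascertained around a focal adaptive site and extends
    ## an independent Exp(recRate * tAdmixture) distance to each side,
    ## so its total length is Gamma(shape 2) under the recombination clock
    focal <- sample.int(L, 1L) - 1L                # 0-based
    sides <- sampleTractLength(config@recRate, config@tAdmixture, 2L)
    tractStart <- as.integer(max(0, focal - sides[1L]))
    tractEnd <- as.integer(min(L, focal + sides[2L]))
    popStart <- c(0L, cumsum(nPop))[seq_along(nPop)]
    fracs <- c(outgroup = config@outgroupLeak,
               target1 = config@postAdmixtureTargetFreq,
               target2 = config@postAdmixtureTargetFreq,
               oceanian = config@postAdmixtureTargetFreq)
    for (p in seq_along(nPop)) {
      k <- round(fracs[[names(nPop)[p]]] * nPop[[p]])
      if (k > 0L) {
        rows <- popStart[p] + sample.int(nPop[[p]], k)
        carriers <- c(carriers, rows)
      }
    }
    carriers <- sort(carriers)
    ## post-admixture private mutations, one Poisson draw per carrier
    if (mu > 0 && tractEnd > tractStart) {
      for (h in carriers) {
        k <- rpois(1L, mu * (tractEnd - tractStart) * config@tAdmixture)
        if (k > 0L) {
          pp <- drawPositions(tractStart + 1L, tractEnd, k)
          privPos <- c(privPos, as.list(pp))
          privCarrier <- c(privCarrier, rep(h, k))
        }
      }
    }
  }

  ## assemble the site-by-haplotype matrix over the union of positions
  pos1 <- sort(unique(c(unlist(modPos), archShared, archH1, archH2,
                        unlist(privPos))))
  S <- length(pos1)
  M <- matrix(0L, nrow = nHap, ncol = S)
  if (length(modPos)) {
    colIdx <- match(unlist(modPos), pos1)
    for (i in seq_along(modPos))
      M[modCarriers[[i]], colIdx[i]] <- 1L
  }
  donor <- integer(S)
  donor[match(c(archShared, archH1), pos1)] <- 1L
  hap2 <- integer(S)
  hap2[match(c(archShared, archH2), pos1)] <- 1L
  dosage <- matrix(donor + hap2, nrow = 1L,
                   dimnames = list("Denisova", NULL))
  pos0 <- pos1 - 1L

  if (length(carriers)) {
    onTract <- which(pos0 >= tractStart & pos0 < tractEnd)
    for (h in carriers) M[h, onTract] <- donor[onTract]
    if (length(privPos)) {
      colIdx <- match(unlist(privPos), pos1)
      for (i in seq_along(colIdx)) M[privCarrier[i], colIdx[i]] <- 1L
    }
    hapId <- hapIdsFor(popLab, nPop)
    tracts <- data.frame(haplotype = hapId[carriers],
                         start = rep(tractStart, length(carriers)),
                         end = rep(tractEnd, length(carriers)),
                         stringsAsFactors = FALSE)
  }

  hapId <- hapIdsFor(popLab, nPop)
  sampleId <- sub("_[ab]$", "", hapId)
  panel <- HaplotypePanel(
    chrom = "chrS", positions = pos0, haplotypes = M,
    population = popLab, sampleId = sampleId, polarized = TRUE,
    metadata = list(sequenceLength = L, seed = config@seed,
                    haplotypeId = hapId))
  archaic <- ArchaicGenotypes(
    chrom = "chrS", positions = pos0, dosage = dosage, polarized = TRUE,
    metadata = list(sequenceLength = L))
  list(panel = panel, archaic = archaic, tracts = tracts, donor = donor,
       config = config)
}

## Haplotype ids: two phased haplotypes (a/b) per diploid sample.
hapIdsFor <- function(popLab, nPop) {
  unlist(lapply(names(nPop), function(p) {
    n <- nPop[[p]]
    samp <- sprintf("%s%03d", p, rep(seq_len(n / 2L), each = 2L))
    paste0(samp, "_", rep(c("a", "b"), n / 2L))
  }))
}

#' Write a simulated fixture set to disk
#'
#' Emits the simulated data in the standard formats: a phased VCF for the
#' modern panel, a VCF for the archaic diploid individual(s), a population
#' panel TSV (`sample<TAB>population`), an ancestral-allele table
#' (`chrom pos allele`, 1-based) and a BED (0-based half-open) of truth
#' tracts.  Both VCFs share the union site list.  To exercise polarization
#' on re-read, the ancestral allele is written as REF at even site ranks and
#' as ALT at odd ranks; reading the files back with [readPhasedVcf()] and
#' [polarize()] reproduces the input panel exactly.
#'
#' @param panel Polarized modern [HaplotypePanel-class].
#' @param archaic [ArchaicGenotypes-class] (polarized) on the same sites.
#' @param tracts Truth-tract `data.frame` (may have zero rows).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths.
#' @export
writeFixtureSet <- function(panel, archaic, tracts, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory '", dir, "'", call. = FALSE)
  if (file.access(dir, 2L) != 0L)
    stop("directory '", dir, "' is not writable", call. = FALSE)
  stopifnot(identical(positions(panel), positions(archaic)))
  chrom <- panel@chrom
  pos1 <- positions(panel) + 1L
  S <- length(pos1)
  contigLen <- panel@metadata$sequenceLength
  if (is.null(contigLen)) contigLen <- if (S) max(pos1) else 1L
  ## ancestral is REF at even site ranks, ALT at odd ranks (deterministic)
  swap <- if (S) (seq_len(S) %% 2L == 1L) else logical(0)
  anc <- rep("A", S)
  der <- rep("G", S)
  ref <- ifelse(swap, der, anc)
  alt <- ifelse(swap, anc, der)

  vcfHeader <- function(samples) c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contigLen),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  paths <- c(modern_vcf = file.path(dir, "modern.vcf"),
             archaic_vcf = file.path(dir, "archaic.vcf"),
             panel_tsv = file.path(dir, "panel.tsv"),
             ancestral_tsv = file.path(dir, "ancestral.tsv"),
             tracts_bed = file.path(dir, "tracts.bed"))

  ## modern phased VCF: pair consecutive haplotype rows into diploid samples
  M <- haplotypeMatrix(panel)
  sampleId <- sampleIds(panel)
  if (nrow(M) %% 2L != 0L || !all(sampleId[c(TRUE, FALSE)] ==
                                  sampleId[c(FALSE, TRUE)]))
    stop("modern panel rows must pair into diploid samples", call. = FALSE)
  samples <- sampleId[c(TRUE, FALSE)]
  lines <- vcfHeader(samples)
  if (S) {
    ## VCF allele index: 0 = REF; derived is ALT unless swapped
    code <- M
    code[, swap] <- 1L - code[, swap, drop = FALSE]
    gt <- matrix(paste(code[c(TRUE, FALSE), , drop = FALSE],
                       code[c(FALSE, TRUE), , drop = FALSE], sep = "|"),
                 nrow = length(samples))
    body <- paste(chrom, pos1, ".", ref, alt, ".", "PASS",
                  paste0("AA=", anc), "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, paths["modern_vcf"])

  ## archaic VCF: unphased diploid genotypes with natural het/missing codes
  D <- dosageMatrix(archaic)
  lines <- vcfHeader(rownames(D))
  if (S) {
    gtFor <- function(d, swapped) {
      d[swapped & !is.na(d)] <- 2L - d[swapped & !is.na(d)]
      g <- c("0/0", "0/1", "1/1")[d + 1L]
      g[is.na(d)] <- "./."
      g
    }
    gt <- vapply(seq_len(S), function(j)
      paste(gtFor(D[, j], swap[j]), collapse = "\t"), character(1))
    body <- paste(chrom, pos1, ".", ref, alt, ".", "PASS",
                  paste0("AA=", anc), "GT", gt, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, paths["archaic_vcf"])

  writeLines(c("sample\tpopulation",
               paste(samples, populationLabels(panel)[c(TRUE, FALSE)],
                     sep = "\t")),
             paths["panel_tsv"])
  writeLines(c("chrom\tpos\tallele",
               if (S) paste(chrom, pos1, anc, sep = "\t")),
             paths["ancestral_tsv"])
  bed <- if (nrow(tracts))
    paste(chrom, tracts$start, tracts$end, tracts$haplotype, sep = "\t")
  else character(0)
  writeLines(bed, paths["tracts_bed"])
  paths
}
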
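# Shared fixtures built in code: small simulation configs, tiny hand
# fixtures and a hand-written VCF.

smallConfig <- function(seed = 1L, ...) {
  args <- list(sequenceLength = 4e5, popSizes = c(outgroup = 20L,
               target1 = 20L, target2 = 20L, oceanian = 10L), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(SimulationConfig, args)
}

# tiny polarized panel from an explicit matrix
tinyPanel <- function(M, positions = NULL, population = NULL) {
  M <- as.matrix(M)
  if (is.null(positions)) positions <- seq_len(ncol(M)) * 100L - 100L
  if (is.null(population)) population <- rep("pop1", nrow(M))
  HaplotypePanel("chrT", positions, M, population = population)
}

# tiny JointPanel: panel rows + one archaic dosage row ("Denisova")
tinyJoint <- function(M, dosage, positions = NULL, population = NULL,
                      extraArchaic = NULL) {
  p <- tinyPanel(M, positions, population)
  D <- rbind(Denisova = as.integer(dosage))
  if (!is.null(extraArchaic))
    D <- rbind(D, do.call(rbind, extraArchaic))
  arch <- ArchaicGenotypes("chrT", positions(p), D, polarized = TRUE)
  new("JointPanel", panel = p, archaic = arch, reference = "Denisova")
}

# hand-written 2-sample, 3-site phased VCF (plus knobs for malformed rows)
writeHandVcf <- function(path, extraLines = character(0),
                         gt = c("0|1\t1|1", "0|0\t0|1", "1|0\t0|0")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr4,length=100000>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste0("chr4\t101\trsA\tA\tG\t.\tPASS\tAA=A\tGT\t", gt[1]),
    paste0("chr4\t205\trsB\tC\tT\t.\tPASS\tAA=T\tGT\t", gt[2]),
    paste0("chr4\t309\trsC\tG\tA\t.\tPASS\tAA=G\tGT\t", gt[3]),
    extraLines)
  writeLines(lines, path)
  path
}

handPanelTable <- function() {
  data.frame(sample = c("S1", "S2"), population = c("YRI", "CHB"),
             stringsAsFactors = FALSE)
}

# Independent site-by-site enumeration oracles for U and Q95.
bruteU <- function(pos, fOut, fTgt, frac, start, end, w, x, y) {
  cnt <- 0L
  for (i in seq_along(pos)) {
    if (pos[i] < start || pos[i] >= end) next
    if (is.na(frac[i])) next
    if (fOut[i] < w && fTgt[i] > x && frac[i] >= y) cnt <- cnt + 1L
  }
  cnt
}
bruteQ95 <- function(pos, fOut, fTgt, frac, start, end, w, y) {
  q <- numeric(0)
  for (i in seq_along(pos)) {
    if (pos[i] < start || pos[i] >= end) next
    if (is.na(frac[i])) next
    if (fOut[i] < w && frac[i] >= y) q <- c(q, fTgt[i])
  }
  if (!length(q)) return(NA_real_)
  q <- sort(q)
  h <- (length(q) - 1) * 0.95 + 1
  lo <- floor(h)
  if (lo >= length(q)) return(q[length(q)])
  q[lo] + (h - lo) * (q[lo + 1] - q[lo])
}

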
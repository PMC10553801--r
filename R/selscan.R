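## Windowed selection statistics and the candidate-variant filter.

#' Hudson's F_ST from derived-allele counts
#'
#' Per-site Hudson estimator
#' \deqn{\hat F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) -
#'   p_2(1-p_2)/(n_2-1)}{p_1(1-p_2) + p_2(1-p_1)}}
#' and the window value as the ratio of summed numerators to summed
#' denominators ("ratio of averages").  Per-site values are also reported
#' clamped to `[0, 1]` for display; the window ratio always uses the raw
#' sums.  Sites with a zero denominator (monomorphic in both samples) are
#' flagged undefined (`NaN`) and excluded from the sums.
#'
#' @param derived1,derived2 Derived-allele counts per site in each sample.
#' @param size1,size2 Haplotype sample sizes (scalar or per site, `>= 2`).
#' @return List with `perSite` (raw), `perSiteClamped`, and `fst` (the
#'   window ratio-of-averages; `NaN` when every site is undefined).
#' @examples
#' hudsonFst(8, 10, 2, 10)$fst   # ~0.477
#' @export
hudsonFst <- function(derived1, size1, derived2, size2) {
  if (any(size1 < 2) || any(size2 < 2))
    stop("sample sizes must be >= 2", call. = FALSE)
  p1 <- derived1 / size1
  p2 <- derived2 / size2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (size1 - 1) -
    p2 * (1 - p2) / (size2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  perSite <- ifelse(den == 0, NaN, num / den)
  ok <- den != 0
  fst <- if (any(ok)) sum(num[ok]) / sum(den[ok]) else NaN
  list(perSite = perSite,
       perSiteClamped = pmin(1, pmax(0, perSite)),
       fst = fst)
}

#' Fay and Wu's H
#'
#' Unnormalized H = theta_pi - theta_H computed from the derived-allele
#' count spectrum of a sample of `n` haplotypes:
#' `theta_pi = sum 2 i (n - i) / (n (n - 1))` and
#' `theta_H = sum 2 i^2 / (n (n - 1))` over segregating sites with derived
#' count `i`.  Negative values indicate an excess of high-frequency derived
#' alleles, the hallmark of a completed or ongoing sweep.
#'
#' @param derivedCounts Integer vector of derived-allele counts, one per
#'   segregating site; each must satisfy `0 < i < n` (polarized input).
#' @param n Haplotype sample size.
#' @return The H value (0 when there are no segregating sites).
#' @examples
#' fayWuH(3, 4)   # -1
#' fayWuH(1, 4)   # +1/3
#' @export
fayWuH <- function(derivedCounts, n) {
  if (!length(derivedCounts)) return(0)
  if (any(derivedCounts <= 0) || any(derivedCounts >= n))
    stop("derived counts must satisfy 0 < i < n; ",
         "input must be polarized and restricted to segregating sites",
         call. = FALSE)
  i <- derivedCounts
  thetaPi <- sum(2 * i * (n - i)) / (n * (n - 1))
  thetaH <- sum(2 * i^2) / (n * (n - 1))
  thetaPi - thetaH
}

#' Windowed selection statistics over a panel
#'
#' Computes Hudson's F_ST (between `popA` and `popB`) or Fay and Wu's H
#' (within `pop`) in non-overlapping windows tiled from the panel's first
#' position rounded down to a multiple of the window size; a trailing
#' partial window is kept and flagged.
#'
#' @param panel Polarized [HaplotypePanel-class].
#' @param popA,popB Population labels for the F_ST contrast.
#' @param windowSize Window size in bp.
#' @return `data.frame` with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open), `nSites`, `value` and `partial`.
#' @export
windowedFst <- function(panel, popA, popB, windowSize = 40000) {
  stopifnot(isPolarized(panel))
  win <- panelWindows(panel, windowSize)
  fA <- popFrequencies(panel, popA)
  fB <- popFrequencies(panel, popB)
  nA <- sum(populationLabels(panel) %in% popA)
  nB <- sum(populationLabels(panel) %in% popB)
  pos <- positions(panel)
  win$nSites <- 0L
  win$value <- NA_real_
  for (i in seq_len(nrow(win))) {
    j <- which(pos >= win$start[i] & pos < win$end[i])
    seg <- j[fA[j] + fB[j] > 0 & fA[j] + fB[j] < 2]
    win$nSites[i] <- length(seg)
    if (length(seg))
      win$value[i] <- hudsonFst(fA[seg] * nA, nA, fB[seg] * nB, nB)$fst
  }
  win
}

#' @rdname windowedFst
#' @param pop Population label for the H statistic.
#' @export
windowedFayWuH <- function(panel, pop, windowSize = 40000) {
  stopifnot(isPolarized(panel))
  win <- panelWindows(panel, windowSize)
  rows <- which(populationLabels(panel) %in% pop)
  n <- length(rows)
  counts <- colSums(haplotypeMatrix(panel)[rows, , drop = FALSE])
  pos <- positions(panel)
  win$nSites <- 0L
  win$value <- NA_real_
  for (i in seq_len(nrow(win))) {
    j <- which(pos >= win$start[i] & pos < win$end[i])
    seg <- j[counts[j] > 0 & counts[j] < n]
    win$nSites[i] <- length(seg)
    win$value[i] <- fayWuH(counts[seg], n)
  }
  win
}

panelWindows <- function(panel, windowSize) {
  pos <- positions(panel)
  if (!length(pos)) stop("panel has no sites", call. = FALSE)
  win <- tileWindows(min(pos), max(pos), windowSize)
  win$partial <- win$end > max(pos) + 1L & seq_len(nrow(win)) == nrow(win)
  data.frame(chrom = panel@chrom, win[, c("start", "end", "partial")])
}

## EHH curve outward from a core site.  Identity of a haplotype pair at
## position x is identity at every site from the core to x inclusive of
## both; EHH at the core itself is 1 by convention.  Returns positions and
## EHH values ordered outward.
ehhCurve <- function(M, pos, coreIdx, side = c("right", "left")) {
  side <- match.arg(side)
  N <- nrow(M)
  idx <- if (side == "right") seq_len(ncol(M)) > coreIdx
         else seq_len(ncol(M)) < coreIdx
  idx <- which(idx)
  if (side == "left") idx <- rev(idx)
  ehh <- numeric(length(idx))
  cls <- M[, coreIdx]                      # classes include the core allele
  npairs <- N * (N - 1) / 2
  for (k in seq_along(idx)) {
    cls <- cls * 2L + M[, idx[k]]
    tab <- tabulate(match(cls, unique(cls)))
    ehh[k] <- sum(tab * (tab - 1) / 2) / npairs
    cls <- match(cls, unique(cls))         # recompact to avoid overflow
  }
  list(pos = pos[idx], ehh = ehh)
}

## Integrated EHH (trapezoids over physical distance from the core,
## truncated after the first position where EHH < truncEhh).
integratedEhh <- function(M, pos, coreIdx, truncEhh = 0.05) {
  total <- 0
  for (side in c("left", "right")) {
    curve <- ehhCurve(M, pos, coreIdx, side)
    prevPos <- pos[coreIdx]
    prevEhh <- 1
    for (k in seq_along(curve$pos)) {
      e <- curve$ehh[k]
      total <- total + abs(curve$pos[k] - prevPos) * (prevEhh + e) / 2
      if (e < truncEhh) break
      prevPos <- curve$pos[k]
      prevEhh <- e
    }
  }
  total
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' Unstandardized XP-EHH at a core site: `ln(iHH_A / iHH_B)` where iHH is
#' the integral of the extended haplotype homozygosity over physical
#' distance on both sides of the core, truncated after the first position
#' where EHH drops below `truncEhh` (or at the region edge).  EHH at the
#' core is 1 by convention; identity is evaluated over all sites from the
#' core outward, core included.
#'
#' @param panelA,panelB [HaplotypePanel-class] objects (or plain 0/1
#'   matrices) over the same positions.
#' @param coreSite Index of the core site (must be segregating in the
#'   pooled sample).
#' @param truncEhh EHH truncation threshold (default 0.05).
#' @return The unstandardized score; `NA` (flagged by a warning) when
#'   `iHH_B` is zero.
#' @seealso [normalizeXpehh()], [xpehhScan()]
#' @export
xpehh <- function(panelA, panelB, coreSite, truncEhh = 0.05) {
  MA <- if (is(panelA, "HaplotypePanel")) haplotypeMatrix(panelA) else panelA
  MB <- if (is(panelB, "HaplotypePanel")) haplotypeMatrix(panelB) else panelB
  posA <- if (is(panelA, "HaplotypePanel")) positions(panelA)
          else seq_len(ncol(MA)) - 1L
  posB <- if (is(panelB, "HaplotypePanel")) positions(panelB)
          else seq_len(ncol(MB)) - 1L
  if (!identical(posA, posB))
    stop("panels must share the same positions", call. = FALSE)
  pooled <- c(MA[, coreSite], MB[, coreSite])
  if (all(pooled == 0L) || all(pooled == 1L))
    stop("core site must be segregating in the pooled sample",
         call. = FALSE)
  iA <- integratedEhh(MA, posA, coreSite, truncEhh)
  iB <- integratedEhh(MB, posB, coreSite, truncEhh)
  if (iB == 0) {
    warning("iHH of the reference panel is zero at core ", coreSite,
            "; score undefined", call. = FALSE)
    return(NA_real_)
  }
  log(iA / iB)
}

#' Standardize XP-EHH scores
#'
#' Centers and scales a vector of unstandardized XP-EHH scores to mean 0
#' and unit sample standard deviation over all finite values.
#'
#' @param values Numeric vector of unstandardized scores.
#' @return Z-scores (NAs preserved).
#' @export
normalizeXpehh <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2L || sd(values[fin]) == 0)
    stop("need at least two distinct finite values to standardize",
         call. = FALSE)
  (values - mean(values[fin])) / sd(values[fin])
}

#' XP-EHH over many cores
#'
#' Computes unstandardized XP-EHH between two populations of a panel at a
#' set of core sites and standardizes over the computed cores.
#'
#' @param panel Polarized [HaplotypePanel-class].
#' @param popA Population whose long haplotypes push the score positive.
#' @param popB Reference population.
#' @param cores Site indices; default: all sites segregating in the pooled
#'   two-population sample.
#' @param truncEhh EHH truncation threshold.
#' @return `data.frame` with `site`, `position`, `raw` and `z`.
#' @export
xpehhScan <- function(panel, popA, popB, cores = NULL, truncEhh = 0.05) {
  pA <- panel[popA, ]
  pB <- panel[popB, ]
  pos <- positions(panel)
  if (is.null(cores)) {
    f <- colMeans(rbind(haplotypeMatrix(pA), haplotypeMatrix(pB)))
    cores <- which(f > 0 & f < 1)
  }
  raw <- vapply(cores, function(j) {
    suppressWarnings(xpehh(pA, pB, j, truncEhh))
  }, numeric(1))
  data.frame(site = cores, position = pos[cores], raw = raw,
             z = if (sum(is.finite(raw)) >= 2L && sd(raw[is.finite(raw)]) > 0)
               normalizeXpehh(raw) else NA_real_)
}

#' Flag outlier windows by the k-standard-deviation rule
#'
#' Flags values more than `k` sample standard deviations from the mean,
#' the genome-wide outlier rule used to call selection signals: upper tail,
#' lower tail, or both.
#'
#' @param values Numeric vector (at least 3 finite values).
#' @param k Number of standard deviations (default 2).
#' @param side `"upper"`, `"lower"` or `"both"`.
#' @return Logical vector, `TRUE` for flagged entries (all `FALSE` when the
#'   values are constant; `NA` values are never flagged).
#' @examples
#' flagOutlierWindows(c(rep(0, 9), 10), side = "upper")
#' @export
flagOutlierWindows <- function(values, k = 2,
                               side = c("upper", "lower", "both")) {
  side <- match.arg(side)
  fin <- is.finite(values)
  if (sum(fin) < 3L)
    stop("need at least 3 finite values", call. = FALSE)
  m <- mean(values[fin])
  s <- sd(values[fin])
  if (s == 0) return(rep(FALSE, length(values)))
  up <- values > m + k * s
  lo <- values < m - k * s
  out <- switch(side, upper = up, lower = lo, both = up | lo)
  out & fin
}

#' Filter candidate adaptive variants
#'
#' Applies the shortlist rule for putatively adaptive variants: keep a
#' variant iff (1) its minor allele frequency is at least `mafMin`,
#' (2) the differentiation rule passes (default: the absolute derived
#' allele frequency difference between the outgroup column and at least one
#' target column is at least `dafDiffMin`), and (3) it is functionally
#' plausible: non-synonymous, in a UTR class, or with CADD Phred at least
#' `caddMin`.  Missing CADD scores are treated as 0 with a warning.
#'
#' @param annotations `data.frame` with at minimum a consequence column
#'   (`type`), a `cadd` column, and per-group frequency columns.
#' @param mafMin Minimum minor allele frequency (computed from the mean of
#'   the group frequency columns).
#' @param dafDiffMin Differentiation threshold.
#' @param outgroupCol Name of the outgroup frequency column.
#' @param targetCols Names of the target frequency columns.
#' @param caddMin CADD Phred threshold for the functional clause.
#' @param typeCol,caddCol Column names for consequence and CADD.
#' @return The kept rows of `annotations` (same columns; possibly empty).
#' @export
filterCandidateVariants <- function(annotations, mafMin = 0.02,
                                    dafDiffMin = 0.2,
                                    outgroupCol = "AFR",
                                    targetCols = c("EUR", "EAS"),
                                    caddMin = 10,
                                    typeCol = "type", caddCol = "cadd") {
  if (!nrow(annotations)) return(annotations)
  need <- c(typeCol, caddCol, outgroupCol, targetCols)
  if (!all(need %in% names(annotations)))
    stop("annotation table lacks columns: ",
         paste(setdiff(need, names(annotations)), collapse = ", "),
         call. = FALSE)
  cadd <- annotations[[caddCol]]
  if (anyNA(cadd)) {
    warning(sum(is.na(cadd)), " variants without CADD score treated as 0",
            call. = FALSE)
    cadd[is.na(cadd)] <- 0
  }
  freqCols <- c(outgroupCol, targetCols)
  f <- as.matrix(annotations[, freqCols])
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("frequencies must be in [0, 1]", call. = FALSE)
  overall <- rowMeans(f)
  maf <- pmin(overall, 1 - overall)
  diffOk <- apply(abs(f[, targetCols, drop = FALSE] - f[, outgroupCol]),
                  1L, max) >= dafDiffMin
  nonsyn <- grepl("nonsynonymous|missense|non-synonymous",
                  tolower(annotations[[typeCol]]))
  utr <- grepl("utr", tolower(annotations[[typeCol]]))
  functional <- nonsyn | utr | cadd >= caddMin
  annotations[maf >= mafMin & diffOk & functional, , drop = FALSE]
}
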
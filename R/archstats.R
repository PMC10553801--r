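## The archaic-sharing window scan (U, Q95) with genomewide percentile
## calibration, and the incomplete-lineage-sorting haplotype-length test.

#' U statistic of archaic sharing
#'
#' Counts the sites at which the derived allele is rare in the unadmixed
#' outgroup (frequency strictly below `w`), common in the target
#' (strictly above `x`), and present in the archaic genome at dosage
#' fraction at least `y` (`y = 1` demands a homozygous-derived archaic).
#'
#' @param outgroupFreq,targetFreq Derived-allele frequencies per site.
#' @param archaicFrac Archaic derived-allele dosage fraction per site
#'   (dosage/2 for a single diploid; the mean over individuals for a
#'   panel, missing genotypes excluded).  `NA` sites never qualify.
#' @param w,x,y Thresholds, each in `[0, 1]`.
#' @return Integer count.
#' @examples
#' uStat(c(0, .2, 0, 0), c(.6, .9, .4, .8), c(1, 1, 1, .5),
#'       w = .1, x = .5, y = 1)   # 1
#' @export
uStat <- function(outgroupFreq, targetFreq, archaicFrac,
                  w = 0.1, x = 0.5, y = 1.0) {
  checkUnit(w, "w"); checkUnit(x, "x"); checkUnit(y, "y")
  sum(outgroupFreq < w & targetFreq > x &
        !is.na(archaicFrac) & archaicFrac >= y)
}

#' Q95 statistic of archaic sharing
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' the target derived-allele frequencies over the sites that pass the
#' outgroup (`< w`) and archaic (`>= y`) conditions; undefined (`NA`)
#' when no site qualifies.
#'
#' @inheritParams uStat
#' @return The Q95 value in `[0, 1]`, or `NA` when undefined.
#' @examples
#' q95Stat(c(0, 0, 0), c(.6, .8, .9), c(1, 1, 1))   # 0.89
#' @export
q95Stat <- function(outgroupFreq, targetFreq, archaicFrac,
                    w = 0.1, y = 1.0) {
  checkUnit(w, "w"); checkUnit(y, "y")
  q <- outgroupFreq < w & !is.na(archaicFrac) & archaicFrac >= y
  if (!any(q)) return(NA_real_)
  interpQuantile(targetFreq[q], 0.95)
}

checkUnit <- function(v, nm) {
  if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
    stop("'", nm, "' must be in [0, 1]", call. = FALSE)
  invisible(v)
}

#' Windowed U/Q95 archaic-sharing scan
#'
#' Computes U and Q95 in non-overlapping windows (tiled from the panel's
#' first position rounded down to a multiple of the window size) and
#' calibrates them against their own genomewide distribution: the 99th and
#' 99.9th percentiles (linear interpolation).  Windows with zero
#' qualifying sites contribute `U = 0` to the U distribution but are
#' excluded from the Q95 distribution, whose undefined values cannot rank.
#' A window is flagged significant when its value is greater than or equal
#' to the corresponding percentile.
#'
#' @param joint A [JointPanel-class].
#' @param outgroup,target Population labels.
#' @param window Window size in bp (default 40000).
#' @param w,x,y Thresholds as in [uStat()].
#' @param individuals Archaic individuals whose dosage fractions are
#'   averaged (default: the joint panel's reference individual).
#' @return An [ArchaicScanResult-class].
#' @export
windowedArchaicScan <- function(joint, outgroup, target, window = 40000,
                                w = 0.1, x = 0.5, y = 1.0,
                                individuals = archaicReference(joint)) {
  if (window <= 0) stop("window size must be > 0", call. = FALSE)
  checkUnit(w, "w"); checkUnit(x, "x"); checkUnit(y, "y")
  panel <- modernPanel(joint)
  pos <- positions(panel)
  if (!length(pos)) stop("joint panel has no sites", call. = FALSE)
  fOut <- popFrequencies(panel, outgroup)
  fTgt <- popFrequencies(panel, target)
  D <- dosageMatrix(joint)[individuals, , drop = FALSE] / 2
  frac <- colMeans(D, na.rm = TRUE)
  frac[colSums(!is.na(D)) == 0L] <- NA_real_
  win <- tileWindows(min(pos), max(pos), window)
  n <- nrow(win)
  res <- data.frame(chrom = panel@chrom, start = win$start, end = win$end,
                    nSites = 0L, nQualifying = 0L, U = 0L,
                    Q95 = NA_real_)
  for (i in seq_len(n)) {
    j <- which(pos >= win$start[i] & pos < win$end[i])
    res$nSites[i] <- length(j)
    if (!length(j)) next
    qual <- fOut[j] < w & !is.na(frac[j]) & frac[j] >= y
    res$nQualifying[i] <- sum(qual)
    res$U[i] <- uStat(fOut[j], fTgt[j], frac[j], w, x, y)
    res$Q95[i] <- q95Stat(fOut[j], fTgt[j], frac[j], w, y)
  }
  thr <- c(u_q99 = interpQuantile(res$U, 0.99),
           u_q999 = interpQuantile(res$U, 0.999),
           q95_q99 = interpQuantile(res$Q95[!is.na(res$Q95)], 0.99),
           q95_q999 = interpQuantile(res$Q95[!is.na(res$Q95)], 0.999))
  res$uSignif99 <- res$U >= thr["u_q99"]
  res$uSignif999 <- res$U >= thr["u_q999"]
  res$q95Signif99 <- !is.na(res$Q95) & res$Q95 >= thr["q95_q99"]
  res$q95Signif999 <- !is.na(res$Q95) & res$Q95 >= thr["q95_q999"]
  new("ArchaicScanResult", windows = res, thresholds = thr,
      params = list(w = w, x = x, y = y, window = window),
      outgroup = paste(outgroup, collapse = "+"),
      target = paste(target, collapse = "+"))
}

#' Expected ILS shared-haplotype length
#'
#' The expected length of a segment shared between modern and archaic
#' humans by incomplete lineage sorting alone, from the recombination
#' clock: `L = 1 / (r * (t1 + t2) / g)` bp, with `r` the local
#' recombination rate per bp per generation, `t1`/`t2` the two split times
#' in years and `g` the generation time in years.
#'
#' @param params An [IlsParams-class] object, or the rate `r` when the
#'   remaining arguments are supplied individually.
#' @param t1,t2,g Split times (years) and generation time, used when
#'   `params` is numeric.
#' @return Expected length L in bp.
#' @examples
#' expectedIlsLength(1e-8, t1 = 5e5, t2 = 5e5, g = 25)   # 2500
#' expectedIlsLength(IlsParams())                         # ~3399
#' @export
expectedIlsLength <- function(params, t1 = NULL, t2 = NULL, g = NULL) {
  if (is(params, "IlsParams")) {
    r <- params@r; t1 <- params@t1; t2 <- params@t2; g <- params@g
  } else r <- params
  if (any(!is.finite(c(r, t1, t2, g))) || any(c(r, t1, t2, g) <= 0))
    stop("all ILS parameters must be positive", call. = FALSE)
  1 / (r * (t1 + t2) / g)
}

#' ILS survival probability of an observed haplotype length
#'
#' Probability that a segment of at least the observed length persists by
#' incomplete lineage sorting: the upper tail of a Gamma distribution with
#' shape `k` and rate `1/L` evaluated at the observed length.  For `k = 2`
#' this equals `exp(-x/L) * (1 + x/L)`.
#'
#' @param observedLength Observed shared-haplotype length in bp (>= 0).
#' @param L Expected ILS length in bp (see [expectedIlsLength()]).
#' @param k Gamma shape (default 2).
#' @return The p-value.
#' @examples
#' ilsPvalue(70614, expectedIlsLength(IlsParams()))   # ~2.07e-8
#' @export
ilsPvalue <- function(observedLength, L, k = 2) {
  if (!is.finite(observedLength) || observedLength < 0)
    stop("'observedLength' must be >= 0", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("'L' must be > 0", call. = FALSE)
  if (!is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be an integer >= 1", call. = FALSE)
  pgamma(observedLength, shape = k, rate = 1 / L, lower.tail = FALSE)
}

#' Monte-Carlo oracle for the ILS length test
#'
#' Estimates the ILS survival probability by simulation: the fraction of
#' `nDraws` sums of `k` independent exponentials with mean `L` that are at
#' least the observed length.  Used to validate [ilsPvalue()] against an
#' independent route.
#'
#' @inheritParams ilsPvalue
#' @param nDraws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed.
#' @return Estimated p-value.
#' @export
ilsMcOracle <- function(observedLength, L, nDraws = 1e5, seed = 1L) {
  if (nDraws < 1) stop("'nDraws' must be >= 1", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("'L' must be > 0", call. = FALSE)
  set.seed(seed)
  k <- 2L
  x <- rexp(nDraws, rate = 1 / L) + rexp(nDraws, rate = 1 / L)
  mean(x >= observedLength)
}
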
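## Region strings, window tiling and small shared helpers.

#' Parse a region string
#'
#' Parses `"chrom:start-end"` in the 1-based inclusive (VCF) convention and
#' returns a `GRanges` of width `end - start + 1`.
#'
#' @param region Region string, e.g. `"chr4:41977828-42048441"`.
#' @return A `GRanges` of length 1.
#' @examples
#' parseRegion("chr4:41977828-42048441")
#' @export
parseRegion <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region '", region, "'; expected chrom:start-end",
         call. = FALSE)
  s <- as.numeric(gsub(",", "", m[3]))
  e <- as.numeric(gsub(",", "", m[4]))
  if (e < s) stop("region end precedes start in '", region, "'",
                  call. = FALSE)
  GenomicRanges::GRanges(m[2], IRanges::IRanges(s, e))
}

#' Inclusive width of a region
#'
#' Length in bp of a 1-based inclusive region, the convention in which the
#' study region chr4:41,977,828-42,048,441 spans 70,614 bp.
#'
#' @param region Region string (see [parseRegion()]).
#' @return Integer width in bp.
#' @examples
#' regionWidth("chr4:41977828-42048441")
#' @export
regionWidth <- function(region) {
  GenomicRanges::width(parseRegion(region))
}

## Window starts tiling [floor(min/size)*size, max], 0-based half-open.
tileWindows <- function(minPos, maxPos, size) {
  if (size <= 0) stop("window size must be > 0", call. = FALSE)
  first <- floor(minPos / size) * size
  starts <- seq(first, maxPos, by = size)
  data.frame(start = starts, end = starts + size)
}

## Linear-interpolation percentile shared by Q95 and the genomewide
## thresholds (classical type-7 order-statistic interpolation).
interpQuantile <- function(x, p) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  unname(quantile(x, p, type = 7, names = FALSE))
}

## Per-population derived-allele frequencies for a set of panel rows.
popFrequencies <- function(panel, population) {
  rows <- which(populationLabels(panel) %in% population)
  if (!length(rows))
    stop("no haplotypes found for population '",
         paste(population, collapse = ","), "'", call. = FALSE)
  colMeans(haplotypeMatrix(panel)[rows, , drop = FALSE])
}

## Deterministic, atomic TSV writer (write to a sibling temp file, rename).
atomicWriteTsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  file.rename(tmp, path)
  invisible(path)
}
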
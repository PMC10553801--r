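## LD anchoring, archaic-aware haplotype distances, haplostrips-style
## ordering, derived-allele sharing and the minimum spanning haplotype
## network.

#' Haplotype-based linkage disequilibrium r-squared
#'
#' `r2 = D^2 / (pA (1 - pA) pB (1 - pB))` computed from phased haplotypes.
#'
#' @param panel [HaplotypePanel-class] (or 0/1 matrix).
#' @param siteI,siteJ Site indices.
#' @return The r-squared value; `NA` with a warning when either site is
#'   monomorphic.
#' @export
ldR2 <- function(panel, siteI, siteJ) {
  M <- if (is(panel, "HaplotypePanel")) haplotypeMatrix(panel) else panel
  a <- M[, siteI]
  b <- M[, siteJ]
  pA <- mean(a)
  pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warning("monomorphic site; r2 undefined", call. = FALSE)
    return(NA_real_)
  }
  D <- mean(a * b) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Select sites in high LD with an index site
#'
#' Returns the sites whose haplotype-based r-squared with the index site
#' exceeds `r2Min` in at least one of the designated populations (all
#' populations by default).  The index site is always included (r2 = 1
#' with itself).
#'
#' @param panel [HaplotypePanel-class].
#' @param indexSite Index of the anchor site (e.g. the focal SNP).
#' @param r2Min LD threshold (default 0.8, strict inequality).
#' @param populations Character vector of population labels to evaluate
#'   in; default all.
#' @return Sorted integer vector of site indices.
#' @export
selectLinkedSites <- function(panel, indexSite, r2Min = 0.8,
                              populations = NULL) {
  if (is.null(populations))
    populations <- unique(populationLabels(panel))
  hits <- indexSite
  for (pop in populations) {
    sub <- panel[pop, ]
    M <- haplotypeMatrix(sub)
    pA <- mean(M[, indexSite])
    if (pA %in% c(0, 1)) next
    r2 <- suppressWarnings(vapply(seq_len(ncol(M)), function(j)
      ldR2(M, indexSite, j), numeric(1)))
    hits <- c(hits, which(!is.na(r2) & r2 > r2Min))
  }
  sort(unique(hits))
}

#' Distance between a haplotype and an archaic diploid
#'
#' Counts differences between a haploid modern haplotype and an archaic
#' diploid genotype over a site set: a homozygous archaic mismatch adds 1,
#' a heterozygous archaic site adds 0.5 regardless of the modern allele,
#' and a missing archaic genotype adds 0 while decrementing the count of
#' comparable sites.
#'
#' @param haplotype 0/1 vector.
#' @param archaicDosage Dosage vector (0/1/2, `NA` missing) over the same
#'   sites.
#' @param sites Optional index vector restricting the comparison.
#' @return List with `distance` and `comparable` (number of non-missing
#'   sites).
#' @export
archaicDistance <- function(haplotype, archaicDosage, sites = NULL) {
  if (!is.null(sites)) {
    haplotype <- haplotype[sites]
    archaicDosage <- archaicDosage[sites]
  }
  if (!length(haplotype)) stop("empty site set", call. = FALSE)
  obs <- !is.na(archaicDosage)
  h <- haplotype[obs]
  d <- archaicDosage[obs]
  het <- d == 1L
  dist <- sum(abs(h[!het] - d[!het] / 2)) + 0.5 * sum(het)
  list(distance = dist, comparable = sum(obs))
}

#' Distances of every panel haplotype to an archaic individual
#'
#' @param joint A [JointPanel-class].
#' @param individual Archaic individual name (default the reference).
#' @param sites Optional site index restriction.
#' @return `data.frame` with `haplotype`, `population`, `distance`,
#'   `comparable`.
#' @export
archaicDistances <- function(joint, individual = archaicReference(joint),
                             sites = NULL) {
  D <- dosageMatrix(joint)[individual, ]
  M <- haplotypeMatrix(joint)
  res <- t(vapply(seq_len(nrow(M)), function(i) {
    a <- archaicDistance(M[i, ], D, sites)
    c(a$distance, a$comparable)
  }, numeric(2)))
  data.frame(haplotype = haplotypeIdsOf(joint@panel),
             population = populationLabels(joint),
             distance = res[, 1L], comparable = res[, 2L],
             stringsAsFactors = FALSE)
}

haplotypeIdsOf <- function(panel) {
  ids <- panel@metadata$haplotypeId
  if (is.null(ids) || length(ids) != nHaplotypes(panel))
    ids <- paste0(sampleIds(panel), "_",
                  rep_len(c("a", "b"), nHaplotypes(panel)))
  ids
}

#' Shared derived alleles with an archaic individual
#'
#' Counts the sites at which both the modern haplotype and the archaic
#' individual carry the derived allele: +1 when the archaic is homozygous
#' derived, +0.5 when heterozygous (consistent with [archaicDistance()]),
#' 0 when missing.
#'
#' @param haplotype 0/1 vector (polarized).
#' @param archaicDosage Derived-allele dosage vector over the same sites.
#' @param sites Optional index restriction.
#' @return The (possibly half-integer) shared-derived count.
#' @export
derivedAlleleSharing <- function(haplotype, archaicDosage, sites = NULL) {
  if (!is.null(sites)) {
    haplotype <- haplotype[sites]
    archaicDosage <- archaicDosage[sites]
  }
  der <- haplotype == 1L & !is.na(archaicDosage)
  sum(archaicDosage[der] == 2L) + 0.5 * sum(archaicDosage[der] == 1L)
}

#' Haplostrips-style ordering against an archaic reference
#'
#' Reproduces the haplostrips display logic: (1) drop sites whose maximum
#' within-population minor allele frequency is below `mafMin`; (2) cluster
#' haplotype rows (with the reference prepended as a pseudo-haplotype)
#' hierarchically on Manhattan distance with complete linkage; (3) rotate
#' dendrogram branches so that distance to the reference is non-decreasing
#' wherever the tree permits, which places the reference first at distance
#' zero.
#'
#' @param joint A [JointPanel-class] (the reference individual is
#'   homozygous at every site, so its haploid sequence is well defined).
#' @param reference Archaic reference name (default the joint panel's).
#' @param mafMin Within-population minor-allele-frequency threshold
#'   (default 0.05; sites below it in every population are removed).
#' @return A [HaploOrdering-class].
#' @export
haplostripsOrder <- function(joint, reference = archaicReference(joint),
                             mafMin = 0.05) {
  panel <- modernPanel(joint)
  M <- haplotypeMatrix(panel)
  pops <- populationLabels(panel)
  maf <- matrix(unlist(lapply(unique(pops), function(p) {
    f <- colMeans(M[pops == p, , drop = FALSE])
    pmin(f, 1 - f)
  })), nrow = ncol(M))
  keep <- which(apply(maf, 1L, max) >= mafMin)
  if (!length(keep))
    stop("no site survives the within-population MAF filter",
         call. = FALSE)
  refHap <- dosageMatrix(joint)[reference, keep] / 2L
  rows <- rbind(refHap, M[, keep, drop = FALSE])
  ids <- c(reference, haplotypeIdsOf(panel))
  popAll <- c("Archaic", pops)
  dists <- vapply(seq_len(nrow(rows)), function(i)
    archaicDistance(rows[i, ], refHap * 2L)$distance, numeric(1))
  hc <- hclust(dist(rows, method = "manhattan"), method = "complete")
  wts <- dists
  wts[1L] <- -1           # break distance ties in favour of the reference
  dend <- reorder(as.dendrogram(hc), wts, agglo.FUN = min)
  ord <- order.dendrogram(dend)
  new("HaploOrdering",
      haplotypeId = ids[ord],
      population = popAll[ord],
      distance = dists[ord],
      comparable = rep(length(keep), length(ord)),
      order = as.integer(ord - 1L),      # 0 marks the reference row
      retainedSites = as.integer(keep),
      matrix = rows[ord, , drop = FALSE])
}

#' Plot a haplostrips matrix
#'
#' Draws the ordered 0/1 matrix of a [HaploOrdering-class] (rows =
#' haplotypes, reference on top, black = derived allele).
#'
#' @param ordering A [HaploOrdering-class].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plotHaplostrips <- function(ordering, ...) {
  m <- ordering@matrix
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("white", "black"), xlab = "site",
                  ylab = "haplotype", axes = FALSE, ...)
  graphics::box()
  invisible(m)
}

#' Minimum spanning haplotype network
#'
#' Collapses identical haplotypes, tabulates their per-population
#' frequencies and connects the unique haplotypes by a minimum spanning
#' network on Hamming distances: Kruskal's algorithm processed by weight
#' class, retaining every co-minimal edge that joins two components
#' distinct at the start of its weight class.
#'
#' @param panel [HaplotypePanel-class] or 0/1 matrix.
#' @param population Optional per-row population labels (taken from the
#'   panel when omitted).
#' @return List with `edges` (`data.frame`: `from`, `to`, `distance`),
#'   `haplotypes` (unique haplotype matrix, rownames `ht1`, `ht2`, ...
#'   ordered by decreasing total count) and `frequencies` (count table,
#'   haplotypes x populations).
#' @export
haplotypeNetwork <- function(panel, population = NULL) {
  M <- if (is(panel, "HaplotypePanel")) haplotypeMatrix(panel) else panel
  if (is.null(population))
    population <- if (is(panel, "HaplotypePanel"))
      populationLabels(panel) else rep("all", nrow(M))
  if (!nrow(M)) stop("need at least one haplotype", call. = FALSE)
  key <- apply(M, 1L, paste, collapse = "")
  firstIdx <- !duplicated(key)
  uniq <- M[firstIdx, , drop = FALSE]
  ukey <- key[firstIdx]
  counts <- table(factor(key, levels = ukey), population)
  ord <- order(-rowSums(counts), seq_along(ukey))
  uniq <- uniq[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  k <- nrow(uniq)
  rownames(uniq) <- sprintf("ht%d", seq_len(k))
  rownames(counts) <- rownames(uniq)
  if (k == 1L)
    return(list(edges = data.frame(from = character(0), to = character(0),
                                   distance = numeric(0)),
                haplotypes = uniq, frequencies = counts))
  dd <- as.matrix(dist(uniq, method = "manhattan"))
  pairs <- which(upper.tri(dd), arr.ind = TRUE)
  ed <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                   w = dd[pairs])
  ed <- ed[order(ed$w, ed$i, ed$j), ]
  comp <- seq_len(k)                       # union-find by relabeling
  keepEdge <- logical(nrow(ed))
  for (w in unique(ed$w)) {
    cls <- which(ed$w == w)
    compBefore <- comp                     # components before this class
    for (e in cls) {
      if (compBefore[ed$i[e]] != compBefore[ed$j[e]]) {
        keepEdge[e] <- TRUE
        ci <- comp[ed$i[e]]
        cj <- comp[ed$j[e]]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
  }
  kept <- ed[keepEdge, ]
  list(edges = data.frame(from = rownames(uniq)[kept$i],
                          to = rownames(uniq)[kept$j],
                          distance = kept$w,
                          stringsAsFactors = FALSE),
       haplotypes = uniq, frequencies = counts)
}
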
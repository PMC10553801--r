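test_that("LD r-squared matches hand-computed values", {
  M <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  expect_equal(ldR2(M, 1, 2), 1)
  ind <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  expect_equal(ldR2(ind, 1, 2), 0)
  M3 <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L), c(0L, 0L))
  expect_equal(ldR2(M3, 1, 2), 1 / 3, tolerance = 1e-12)
  mono <- rbind(c(1L, 1L), c(1L, 0L))
  expect_warning(r <- ldR2(mono, 1, 2), "monomorphic")
  expect_true(is.na(r))
})

test_that("linked-site selection always contains the index site", {
  set.seed(5)
  M <- matrix(rbinom(20 * 8, 1, 0.5), nrow = 20)
  p <- tinyPanel(M, population = rep(c("CHB", "CEU"), each = 10))
  sel <- selectLinkedSites(p, indexSite = 3L, r2Min = 0.8)
  expect_true(3L %in% sel)
  ## a perfect proxy column is picked up
  M2 <- cbind(M, M[, 3L])
  p2 <- tinyPanel(M2, population = rep(c("CHB", "CEU"), each = 10))
  expect_true(ncol(M2) %in% selectLinkedSites(p2, 3L))
})

test_that("archaic distance applies the hom/het/missing arithmetic", {
  expect_equal(archaicDistance(c(1, 0, 1), c(2, 0, 2))$distance, 0)
  ## haplotype 10110 vs homozygous archaic 10010: one mismatch
  r <- archaicDistance(c(1, 0, 1, 1, 0), c(2, 0, 0, 2, 0))
  expect_equal(r$distance, 1)
  expect_equal(r$comparable, 5)
  ## het archaic contributes 0.5 whatever the modern allele
  expect_equal(archaicDistance(c(1), c(1))$distance, 0.5)
  expect_equal(archaicDistance(c(0), c(1))$distance, 0.5)
  ## missing contributes 0 and decrements the comparable count
  r2 <- archaicDistance(c(1, 1), c(NA, 2))
  expect_equal(r2$distance, 0)
  expect_equal(r2$comparable, 1)
  expect_error(archaicDistance(numeric(0), numeric(0)), "empty")
})

test_that("archaic distance is symmetric and metric on hom-only sites", {
  set.seed(8)
  for (i in 1:20) {
    a <- rbinom(12, 1, 0.5); b <- rbinom(12, 1, 0.5); c <- rbinom(12, 1, 0.5)
    dab <- archaicDistance(a, 2L * b)$distance
    dba <- archaicDistance(b, 2L * a)$distance
    expect_identical(dab, dba)
    dac <- archaicDistance(a, 2L * c)$distance
    dbc <- archaicDistance(b, 2L * c)$distance
    expect_lte(dac, dab + dbc)
  }
})

test_that("derived-allele sharing counts joint derived sites", {
  expect_equal(derivedAlleleSharing(c(0, 0, 0), c(2, 2, 2)), 0)
  expect_equal(derivedAlleleSharing(c(1, 1, 0, 0), c(2, 0, 2, 0)), 1)
  expect_equal(derivedAlleleSharing(c(1, 1), c(2, 1)), 1.5)
  expect_equal(derivedAlleleSharing(c(1), c(NA)), 0)
})

test_that("haplostrips ordering filters, clusters and sorts by distance", {
  ## site 4 is monomorphic within every population -> removed
  M <- rbind(h1 = c(0L, 0L, 0L, 0L),
             h2 = c(1L, 1L, 0L, 0L),
             h3 = c(0L, 0L, 1L, 0L))
  j <- tinyJoint(M, dosage = c(0L, 0L, 0L, 0L),
                 population = rep("CHB", 3))
  ord <- haplostripsOrder(j, mafMin = 0.05)
  expect_identical(length(ord@retainedSites), 3L)
  expect_false(4L %in% ord@retainedSites)
  ## reference first at distance zero, then non-decreasing (no conflicts)
  expect_identical(ord@haplotypeId[1L], "Denisova")
  expect_identical(ord@distance[1L], 0)
  modern <- ord@distance[ord@population != "Archaic"]
  expect_identical(modern, sort(modern))          # 0, 1, 2
  ## row multiset preserved and distances consistent with archaicDistance
  d <- archaicDistances(j)
  expect_setequal(ord@haplotypeId, c("Denisova", d$haplotype))
  m <- match(d$haplotype, ord@haplotypeId)
  expect_equal(d$distance[!is.na(m)], ord@distance[m[!is.na(m)]])
  ## everything filtered away is an explicit error
  jAll <- tinyJoint(matrix(0L, 3, 2), dosage = c(0L, 0L),
                    population = rep("CHB", 3))
  expect_error(haplostripsOrder(jAll), "MAF")
})

test_that("introgressed haplotypes sort next to the donor on simulated data", {
  sim <- simulateStructuredPanel(SimulationConfig(seed = 9L))
  joint <- mergeWithArchaic(sim$panel, sim$archaic)
  tr <- sim$tracts[1L, ]
  on <- which(positions(joint) >= tr$start & positions(joint) < tr$end)
  jw <- joint[, on]
  ord <- haplostripsOrder(jw, mafMin = 0.05)
  carriers <- sim$tracts$haplotype
  isCarrier <- ord@haplotypeId %in% carriers
  ## the rows immediately after the reference are carriers
  k <- length(carriers)
  expect_gt(mean(isCarrier[2:(k + 1)]), 0.95)
  ## and carrier distances are stochastically smaller (Mann-Whitney)
  dists <- archaicDistances(jw)
  grp <- dists$haplotype %in% carriers
  pv <- wilcox.test(dists$distance[grp], dists$distance[!grp],
                    alternative = "less", exact = FALSE)$p.value
  expect_lt(pv, 0.01)
})

test_that("the haplotype network collapses, counts and spans", {
  ## single unique haplotype: no edges
  net1 <- haplotypeNetwork(matrix(0L, 3, 4))
  expect_identical(nrow(net1$edges), 0L)
  expect_identical(nrow(net1$haplotypes), 1L)
  ## chain a-b-c with d(a,b)=d(b,c)=1, d(a,c)=2: two edges, no shortcut
  M <- rbind(a = c(0L, 0L), b = c(1L, 0L), c = c(1L, 1L))
  net <- haplotypeNetwork(M)
  expect_identical(nrow(net$edges), 2L)
  expect_true(all(net$edges$distance == 1))
  ## three mutually distance-1 haplotypes: all co-minimal ties retained
  M3 <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L))
  ## pairwise distances: 1, 1, 2 -- adjust to a true tie triangle
  M3 <- rbind(c(1L, 0L), c(0L, 1L), c(0L, 0L))
  dd <- as.matrix(dist(M3, method = "manhattan"))
  expect_true(all(dd[upper.tri(dd)] %in% c(1, 2)))
  ## build an exact tie triangle over 3 alleles of 2 sites
  T3 <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  net3 <- haplotypeNetwork(T3)
  expect_identical(nrow(net3$edges), 3L)  # all distance-2 ties kept
  ## per-population frequency table
  p <- tinyPanel(rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L)),
                 population = c("YRI", "CHB", "CHB"))
  netp <- haplotypeNetwork(p)
  expect_identical(as.integer(netp$frequencies["ht1", "CHB"]), 1L)
  expect_identical(as.integer(netp$frequencies["ht1", "YRI"]), 1L)
  expect_identical(sum(netp$frequencies), 3L)
})

test_that("the network contains a minimum spanning tree (igraph oracle)", {
  skip_if_not_installed("igraph")
  set.seed(33)
  M <- matrix(rbinom(9 * 12, 1, 0.4), nrow = 9)
  net <- haplotypeNetwork(M)
  k <- nrow(net$haplotypes)
  dd <- as.matrix(dist(net$haplotypes, method = "manhattan"))
  gFull <- igraph::graph_from_adjacency_matrix(dd, mode = "undirected",
                                               weighted = TRUE)
  wFull <- sum(igraph::E(igraph::mst(gFull))$weight)
  gKept <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
    vertices = data.frame(name = rownames(net$haplotypes)))
  igraph::E(gKept)$weight <- net$edges$distance
  expect_true(igraph::is_connected(gKept))
  wKept <- sum(igraph::E(igraph::mst(gKept))$weight)
  expect_equal(wKept, wFull)
})
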
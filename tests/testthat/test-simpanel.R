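test_that("invalid configurations fail naming the offending field", {
  expect_error(SimulationConfig(mu = -1), "mu")
  expect_error(SimulationConfig(tAdmixture = 30000), "tAdmixture")
  expect_error(SimulationConfig(postAdmixtureTargetFreq = 1.2),
               "postAdmixtureTargetFreq")
  expect_error(SimulationConfig(popSizes = c(outgroup = 3L, target1 = 20L,
                                             target2 = 20L, oceanian = 10L)),
               "popSizes")
  expect_error(SimulationConfig(outgroupLeak = -0.1), "outgroupLeak")
})

test_that("simulation is deterministic for a fixed seed", {
  s1 <- simulateStructuredPanel(smallConfig(seed = 42L))
  s2 <- simulateStructuredPanel(smallConfig(seed = 42L))
  expect_identical(haplotypeMatrix(s1$panel), haplotypeMatrix(s2$panel))
  expect_identical(positions(s1$panel), positions(s2$panel))
  expect_identical(s1$tracts, s2$tracts)
  expect_identical(dosageMatrix(s1$archaic), dosageMatrix(s2$archaic))
  s3 <- simulateStructuredPanel(smallConfig(seed = 43L))
  expect_false(identical(positions(s1$panel), positions(s3$panel)))
})

test_that("no mutation process means no derived alleles off tract", {
  sim <- simulateStructuredPanel(smallConfig(mu = 0, seed = 5L))
  expect_identical(nSites(sim$panel), 0L)
  expect_gt(nrow(sim$tracts), 0L)  # tract exists but carries no alleles
})

test_that("suppressed pulse yields an empty truth-tract list", {
  sim <- simulateStructuredPanel(
    smallConfig(admixProportion = 0, postAdmixtureTargetFreq = 0, seed = 2L))
  expect_identical(nrow(sim$tracts), 0L)
  sim2 <- simulateStructuredPanel(
    smallConfig(postAdmixtureTargetFreq = 0, outgroupLeak = 0, seed = 2L))
  expect_identical(nrow(sim2$tracts), 0L)
})

test_that("archaic lineages accumulate Poisson(mu*L*t) private mutations", {
  ## 200 replicate archaic lineages at mu=1e-8, t=16000, L=100kb:
  ## per-lineage expectation mu*L*t = 16
  nRep <- 100L
  counts <- numeric(nRep)
  for (i in seq_len(nRep)) {
    sim <- simulateStructuredPanel(smallConfig(
      sequenceLength = 1e5, mu = 1e-8, tArchaicSplit = 16000,
      tAdmixture = 1500, admixProportion = 0, postAdmixtureTargetFreq = 0,
      outgroupLeak = 0,
      popSizes = c(outgroup = 2L, target1 = 2L, target2 = 2L,
                   oceanian = 2L),
      seed = 1000L + i))
    D <- dosageMatrix(sim$archaic)[1L, ]
    ## lineage-averaged derived count: shared sites sit on both lineages,
    ## each private (het) site on exactly one
    counts[i] <- sum(D == 2L) + sum(D == 1L) / 2
  }
  ## per-lineage mean = shared + private = mu*L*t regardless of the
  ## within-archaic coalescence split
  expected <- 1e-8 * 1e5 * 16000
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("tract lengths are exponential with mean 1/(r*t)", {
  set.seed(99)
  draws <- sampleTractLength(1e-8, 2000, 10000L)
  expected <- 1 / (1e-8 * 2000)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se + 1)
  expect_true(all(draws >= 1))
  set.seed(7); a <- sampleTractLength(1e-8, 2000, 50L)
  set.seed(7); b <- sampleTractLength(1e-8, 2000, 50L)
  expect_identical(a, b)
  set.seed(1)
  expect_true(all(sampleTractLength(1e-3, 5000, 100L) == 1))
  expect_error(sampleTractLength(0, 2000), "recRate")
  expect_error(sampleTractLength(1e-8, -1), "tAdmixture")
})

test_that("off-tract pairwise divergence matches 2*mu*L*tModernCoalescence", {
  nRep <- 60L
  divs <- numeric(nRep)
  L <- 2e5
  tmod <- 4000
  for (i in seq_len(nRep)) {
    sim <- simulateStructuredPanel(smallConfig(
      sequenceLength = L, tModernCoalescence = tmod, admixProportion = 0,
      popSizes = c(outgroup = 2L, target1 = 2L, target2 = 2L,
                   oceanian = 2L),
      seed = 5000L + i))
    M <- haplotypeMatrix(sim$panel)
    divs[i] <- sum(M[1L, ] != M[3L, ])   # two haplotypes, no tract
  }
  expected <- 2 * 1.25e-8 * L * tmod
  se <- sd(divs) / sqrt(nRep)
  expect_lt(abs(mean(divs) - expected), 3 * se)
})

test_that("introgressed haplotypes hug the donor over their tract", {
  sim <- simulateStructuredPanel(SimulationConfig())
  expect_gt(nrow(sim$tracts), 0L)
  pos <- positions(sim$panel)
  tr <- sim$tracts[1L, ]
  on <- which(pos >= tr$start & pos < tr$end)
  expect_gt(length(on), 0L)
  ids <- sim$panel@metadata$haplotypeId
  carrierRows <- match(sim$tracts$haplotype, ids)
  M <- haplotypeMatrix(sim$panel)
  nonCarrier <- setdiff(seq_len(nrow(M)), carrierRows)
  for (h in carrierRows[c(1L, length(carrierRows))]) {
    dDonor <- sum(M[h, on] != sim$donor[on])
    dOther <- min(vapply(nonCarrier, function(o)
      sum(M[h, on] != M[o, on]), numeric(1)))
    expect_lt(dDonor, dOther)
  }
})

test_that("tract-tagging allele frequency matches the configured carrier fraction", {
  sim <- simulateStructuredPanel(SimulationConfig(seed = 11L))
  pos <- positions(sim$panel)
  tr <- sim$tracts[1L, ]
  ## archaic-derived sites inside the tract, private to the donor lineage
  on <- which(pos >= tr$start & pos < tr$end & sim$donor == 1L)
  expect_gt(length(on), 0L)
  pops <- populationLabels(sim$panel)
  fTgt <- colMeans(haplotypeMatrix(sim$panel)[pops == "target1", on,
                                              drop = FALSE])
  n <- sum(pops == "target1")
  binomSe <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(fTgt) - 0.7), 3 * binomSe)
})

test_that("fixture files round-trip bit-identically through the readers", {
  sim <- simulateStructuredPanel(smallConfig(seed = 3L))
  dir <- withr::local_tempdir()
  paths <- writeFixtureSet(sim$panel, sim$archaic, sim$tracts, dir)
  expect_true(all(file.exists(paths)))
  anc <- readAncestralTable(paths["ancestral_tsv"])
  p <- polarize(readPhasedVcf(paths["modern_vcf"], paths["panel_tsv"]), anc)
  expect_identical(positions(p), positions(sim$panel))
  expect_identical(unname(haplotypeMatrix(p)),
                   unname(haplotypeMatrix(sim$panel)))
  expect_identical(populationLabels(p), populationLabels(sim$panel))
  a <- polarize(readArchaicVcf(paths["archaic_vcf"]), anc)
  expect_identical(unname(dosageMatrix(a)),
                   unname(dosageMatrix(sim$archaic)))
  bed <- read.table(paths["tracts_bed"], sep = "\t")
  expect_identical(nrow(bed), nrow(sim$tracts))
  expect_identical(bed$V2, sim$tracts$start)
  expect_identical(bed$V3, sim$tracts$end)
})

test_that("an empty panel writes a header-only VCF", {
  sim <- simulateStructuredPanel(smallConfig(mu = 0, admixProportion = 0,
                                             seed = 4L))
  dir <- withr::local_tempdir()
  paths <- writeFixtureSet(sim$panel, sim$archaic, sim$tracts, dir)
  lines <- readLines(paths["modern_vcf"])
  expect_true(all(grepl("^#", lines)))
  p <- readPhasedVcf(paths["modern_vcf"], paths["panel_tsv"])
  expect_identical(nSites(p), 0L)
})
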
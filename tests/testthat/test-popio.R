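test_that("a hand-transcribed VCF is read into the expected matrix", {
  vcf <- writeHandVcf(withr::local_tempfile(fileext = ".vcf"))
  p <- readPhasedVcf(vcf, handPanelTable())
  expect_identical(nHaplotypes(p), 4L)
  expect_identical(positions(p), c(100L, 204L, 308L))  # 0-based
  ## hand transcription of the GT fields (rows: S1a, S1b, S2a, S2b)
  expect_identical(unname(haplotypeMatrix(p)),
                   rbind(c(0L, 0L, 1L), c(1L, 0L, 0L),
                         c(1L, 0L, 0L), c(1L, 1L, 0L)))
  expect_identical(populationLabels(p), c("YRI", "YRI", "CHB", "CHB"))
  expect_false(isPolarized(p))
  expect_identical(p@ref, c("A", "C", "G"))
})

test_that("region filtering and empty regions behave", {
  vcf <- writeHandVcf(withr::local_tempfile(fileext = ".vcf"))
  p <- readPhasedVcf(vcf, handPanelTable(), region = "chr4:100-250")
  expect_identical(nSites(p), 2L)
  empty <- readPhasedVcf(vcf, handPanelTable(), region = "chr4:900-999")
  expect_identical(nSites(empty), 0L)
  expect_identical(nHaplotypes(empty), 4L)
})

test_that("unphased and missing genotypes drop the site with a count", {
  vcf <- writeHandVcf(withr::local_tempfile(fileext = ".vcf"),
                      gt = c("0|1\t1|1", "0/0\t0|1", "1|0\t.|."))
  expect_message(p <- readPhasedVcf(vcf, handPanelTable()), "unphased")
  expect_identical(nSites(p), 1L)
  expect_identical(unname(p@metadata$readLog),
                   c(0L, 1L, 1L))  # multiallelic, unphased, missing
})

test_that("panel samples absent from the VCF raise a listing error", {
  vcf <- writeHandVcf(withr::local_tempfile(fileext = ".vcf"))
  tab <- rbind(handPanelTable(),
               data.frame(sample = "S9", population = "CEU"))
  expect_error(readPhasedVcf(vcf, tab), "S9")
})

test_that("polarization flips, keeps and drops by the ancestral allele", {
  ## 5 sites: 3 ancestral==ref, 1 ancestral==alt, 1 unknown
  M <- rbind(c(0L, 1L, 0L, 0L, 1L), c(1L, 1L, 0L, 1L, 0L),
             c(1L, 0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L, 0L))
  p <- HaplotypePanel("chr4", c(10L, 20L, 30L, 40L, 50L), M,
                      population = rep("YRI", 4), polarized = FALSE,
                      ref = c("A", "C", "G", "T", "A"),
                      alt = c("G", "T", "A", "C", "G"))
  anc <- data.frame(chrom = "chr4", pos = c(11L, 21L, 31L, 41L, 51L),
                    allele = c("A", "C", "A", "T", "."))
  pp <- polarize(p, anc)
  expect_identical(unname(polarizationReport(pp)), c(3L, 1L, 1L))
  expect_identical(nSites(pp), 4L)
  expect_true(isPolarized(pp))
  ## site 3 (ancestral == alt) flipped, site 5 (unknown) dropped
  want <- M[, 1:4]
  want[, 3L] <- 1L - want[, 3L]
  expect_identical(unname(haplotypeMatrix(pp)), want)
})

test_that("a column under ancestral==alt is bit-flipped", {
  p <- HaplotypePanel("chr4", c(10L), cbind(c(0L, 1L, 1L, 0L)),
                      population = rep("YRI", 4), polarized = FALSE,
                      ref = "A", alt = "G")
  pp <- polarize(p, data.frame(chrom = "chr4", pos = 11L, allele = "G"))
  expect_identical(unname(haplotypeMatrix(pp))[, 1L], c(1L, 0L, 0L, 1L))
  expect_identical(unname(polarizationReport(pp)), c(0L, 1L, 0L))
})

test_that("flipping the ancestral designation twice restores the panel", {
  set.seed(3)
  M <- matrix(rbinom(40, 1, 0.4), nrow = 4)
  p <- HaplotypePanel("chr4", seq_len(10L) * 10L, M,
                      population = rep("YRI", 4), polarized = FALSE,
                      ref = rep("A", 10), alt = rep("G", 10))
  flipTab <- data.frame(chrom = "chr4", pos = seq_len(10L) * 10L + 1L,
                        allele = p@alt)
  p1 <- polarize(p, flipTab)
  expect_identical(unname(polarizationReport(p1))[2L], 10L)
  flipTab2 <- data.frame(chrom = "chr4", pos = seq_len(10L) * 10L + 1L,
                         allele = p1@alt)
  p2 <- polarize(p1, flipTab2)
  expect_identical(unname(haplotypeMatrix(p2)), M)
})

test_that("merging keeps only sites homozygous in the reference archaic", {
  p <- tinyPanel(matrix(0L, 2, 5))
  ## Denisova het at site 2; Altai missing at a retained site
  arch <- ArchaicGenotypes("chrT", positions(p),
                           rbind(Denisova = c(2L, 1L, 0L, 2L, 2L),
                                 Altai = c(2L, 2L, NA, 1L, 0L)),
                           polarized = TRUE)
  j <- mergeWithArchaic(p, arch)
  expect_identical(nSites(j), 4L)
  expect_false(any(dosageMatrix(j)["Denisova", ] == 1L))
  expect_true(is.na(dosageMatrix(j)["Altai", 2L]))   # kept as missing
  expect_identical(unname(dosageMatrix(j)["Altai", 3L]), 1L) # het kept
  ## all-homozygous reference keeps every shared site
  arch2 <- ArchaicGenotypes("chrT", positions(p),
                            rbind(Denisova = c(2L, 0L, 0L, 2L, 2L)),
                            polarized = TRUE)
  expect_identical(nSites(mergeWithArchaic(p, arch2)), 5L)
  ## output sites are a subset of input sites
  expect_true(all(positions(j) %in% positions(p)))
})

test_that("merging with disjoint or unpolarized inputs errors", {
  p <- tinyPanel(matrix(0L, 2, 3))
  archOff <- ArchaicGenotypes("chrT", c(9999L, 10999L, 11999L),
                              rbind(Denisova = c(0L, 0L, 2L)),
                              polarized = TRUE)
  expect_error(mergeWithArchaic(p, archOff), "overlap")
  archRaw <- ArchaicGenotypes("chrT", positions(p),
                              rbind(Denisova = c(0L, 0L, 2L)),
                              polarized = FALSE)
  expect_error(mergeWithArchaic(p, archRaw), "polarized")
})

test_that("result tables round-trip with NA serialized as NA", {
  tabs <- list(stats = data.frame(id = c("a", "b"), value = c(1.5, NA)),
               empty = data.frame(x = numeric(0), y = character(0)))
  dir <- withr::local_tempdir()
  paths <- writeResultsTsv(tabs, dir)
  back <- read.table(paths[["stats"]], header = TRUE, sep = "\t")
  expect_identical(back$value, c(1.5, NA))
  lines <- readLines(paths[["stats"]])
  expect_match(lines[3L], "NA")
  expect_identical(readLines(paths[["empty"]]), "x\ty")
})
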
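test_that("Hudson F_ST matches hand-derived closed forms", {
  ## fixed difference
  expect_equal(hudsonFst(10, 10, 0, 10)$fst, 1)
  ## equal frequencies: numerator <= 0, clamped to 0 in reporting
  r <- hudsonFst(5, 10, 5, 10)
  expect_lte(r$perSite, 0)
  expect_identical(r$perSiteClamped, 0)
  ## 0.8 vs 0.2 with n = 10 each, evaluated by hand
  expect_equal(hudsonFst(8, 10, 2, 10)$fst, 0.4771242, tolerance = 1e-6)
  expect_error(hudsonFst(1, 1, 0, 10), "sample sizes")
})

test_that("the F_ST window value is a ratio of summed components", {
  r <- hudsonFst(c(10, 8), c(10, 10), c(0, 2), c(10, 10))
  num1 <- 1; den1 <- 1
  p1 <- 0.8; p2 <- 0.2
  num2 <- (p1 - p2)^2 - p1 * (1 - p1) / 9 - p2 * (1 - p2) / 9
  den2 <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(r$fst, (num1 + num2) / (den1 + den2))
  ## monomorphic-in-both sites are flagged undefined and excluded
  r2 <- hudsonFst(c(0, 10), c(10, 10), c(0, 0), c(10, 10))
  expect_true(is.nan(r2$perSite[1]))
  expect_equal(r2$fst, 1)
})

test_that("Fay and Wu's H matches the spectrum closed forms", {
  expect_identical(fayWuH(integer(0), 4), 0)
  expect_equal(fayWuH(3, 4), -1)
  expect_equal(fayWuH(1, 4), 1 / 3, tolerance = 1e-12)
  expect_equal(fayWuH(c(3, 1), 4), -1 + 1 / 3)
  expect_error(fayWuH(c(0, 2), 4), "polarized")
  expect_error(fayWuH(4, 4), "polarized")
})

test_that("neutral simulated windows have mean H near zero", {
  ## >= 500 independent neutral windows (independent genealogy blocks)
  hs <- numeric(0)
  for (s in 1:11) {
    sim <- simulateStructuredPanel(smallConfig(
      sequenceLength = 2e6, admixProportion = 0, seed = 200L + s))
    w <- windowedFayWuH(sim$panel, "target1", 40000)
    hs <- c(hs, w$value[!is.na(w$value)])
  }
  expect_gte(length(hs), 500L)
  se <- sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs)), 3 * se)
})

test_that("XP-EHH reproduces the worked two-panel example", {
  pos <- c(0L, 100L, 200L)
  A <- tinyPanel(matrix(0L, 4, 3), positions = pos)
  B <- tinyPanel(rbind(c(0L, 0L, 0L), c(1L, 0L, 1L),
                       c(0L, 1L, 0L), c(1L, 1L, 1L)), positions = pos)
  expect_equal(xpehh(A, B, 2L), log(2), tolerance = 1e-12)
  expect_equal(xpehh(B, A, 2L), -log(2), tolerance = 1e-12)
  ## identical panels score zero before normalization
  expect_equal(xpehh(B, B, 2L), 0)
})

test_that("XP-EHH is antisymmetric at every core of random panels", {
  set.seed(17)
  for (rep in 1:5) {
    pos <- sort(sample.int(5000L, 12L)) - 1L
    A <- tinyPanel(matrix(rbinom(8 * 12, 1, 0.5), 8), positions = pos)
    B <- tinyPanel(matrix(rbinom(8 * 12, 1, 0.5), 8), positions = pos)
    for (core in c(2L, 6L, 11L)) {
      pooled <- c(haplotypeMatrix(A)[, core], haplotypeMatrix(B)[, core])
      if (all(pooled == 0) || all(pooled == 1)) next
      ab <- suppressWarnings(xpehh(A, B, core))
      ba <- suppressWarnings(xpehh(B, A, core))
      if (is.finite(ab)) expect_equal(ab, -ba, tolerance = 1e-12)
    }
  }
})

test_that("standardized XP-EHH has mean zero and unit sd", {
  set.seed(1)
  z <- normalizeXpehh(rnorm(20, 3, 2))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(normalizeXpehh(c(1, 1, 1)), "distinct")
})

test_that("outlier flagging applies the k-standard-deviation rule", {
  v <- c(rep(0, 9), 10)
  up <- flagOutlierWindows(v, side = "upper")
  expect_identical(which(up), 10L)
  expect_false(any(flagOutlierWindows(v, side = "lower")))
  expect_identical(which(flagOutlierWindows(-v, side = "lower")), 10L)
  expect_false(any(flagOutlierWindows(rep(1, 5), side = "both")))
  expect_error(flagOutlierWindows(c(1, 2)), "3 finite")
})

test_that("the candidate filter keeps non-synonymous, UTR or high-CADD rows", {
  tab <- data.frame(
    snp = c("v1", "v2", "v3", "v4"),
    type = c("missense", "intronic", "synonymous", "3'UTR"),
    cadd = c(0.0, 12.0, 3.0, 1.4),
    AFR = c(0.1, 0.1, 0.1, 0.1),
    EUR = c(0.8, 0.8, 0.8, 0.8),
    EAS = c(0.9, 0.9, 0.9, 0.9))
  kept <- filterCandidateVariants(tab)
  expect_identical(kept$snp, c("v1", "v2", "v4"))
  ## idempotent and a subset of the input
  expect_identical(filterCandidateVariants(kept), kept)
  expect_true(all(kept$snp %in% tab$snp))
  ## empty input passes through
  expect_identical(nrow(filterCandidateVariants(tab[0, ])), 0L)
})

test_that("MAF and differentiation clauses drop rows, missing CADD warns", {
  tab <- data.frame(
    snp = c("rare", "undiff", "na_cadd"),
    type = c("missense", "missense", "intronic"),
    cadd = c(5, 5, NA),
    AFR = c(0.01, 0.5, 0.1),
    EUR = c(0.01, 0.55, 0.8),
    EAS = c(0.02, 0.6, 0.9))
  expect_warning(kept <- filterCandidateVariants(tab), "CADD")
  expect_identical(kept$snp, character(0))  # na_cadd fails functional rule
})

test_that("the bundled candidate table reproduces the 18-SNP shortlist", {
  tab <- read.table(system.file("extdata",
                                "slc30a9_candidate_annotations.tsv",
                                package = "archintro"),
                    header = TRUE, sep = "\t", quote = "")
  kept <- suppressWarnings(filterCandidateVariants(tab))
  expect_identical(nrow(kept), 18L)
  ## the focal non-synonymous variant survives despite CADD 0.001
  expect_true("rs1047626" %in% kept$snp)
  expect_lt(kept$cadd[kept$snp == "rs1047626"], 10)
})

test_that("windowed statistics tile from the rounded-down first position", {
  sim <- simulateStructuredPanel(smallConfig(seed = 21L))
  w <- windowedFst(sim$panel, "target1", "outgroup", 40000)
  expect_true(all(diff(w$start) == 40000))
  expect_identical(w$start[1] %% 40000, 0)
  expect_true(all(w$end - w$start == 40000))
  expect_identical(sum(w$partial), sum(w$end > max(positions(sim$panel))
                                       & seq_len(nrow(w)) == nrow(w)))
  wh <- windowedFayWuH(sim$panel, "outgroup", 40000)
  expect_identical(nrow(wh), nrow(w))
})
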
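test_that("carriage requires at least one alternate allele", {
  co <- toyCohort(matrix(c("0/1", "0/0", "./.", "1/1"), 4, 1))
  expect_equal(unname(perSamplePresence(co, "S01")),
               c(TRUE, FALSE, FALSE, TRUE))
})

test_that("countVariants counts carried sites and population unions", {
  gts <- rbind(c("0/1", "0/0"),
               c("1/1", "0/0"),
               c("0/0", "0/1"))
  co <- toyCohort(gts, populations = c(S01 = "P1", S02 = "P1"))
  cv <- countVariants(co)
  expect_equal(cv$samples$snp_count, c(2L, 1L))
  expect_equal(cv$populations$union[cv$populations$kind == "SNP"], 3L)
  # all-reference sample counts zero
  co0 <- toyCohort(matrix(c("0/0", "0/0"), 2, 1))
  expect_equal(countVariants(co0)$samples$snp_count, 0L)
})

test_that("an empty cohort yields an all-zero table with a warning", {
  co <- toyCohort(matrix("0/1", 1, 2))[integer(0)]
  expect_warning(cv <- countVariants(co), "no sites")
  expect_equal(cv$samples$snp_count, c(0L, 0L))
})

test_that("variantRate rounds bp-per-variant with an NA sentinel at zero", {
  expect_equal(variantRate(12.1e6, 2.5e9), 207)
  expect_equal(variantRate(1, 100), 100)
  expect_true(is.na(variantRate(0, 100)))
  expect_error(variantRate(-1, 100), "must be")
  # rounding bound: |length/count - rate| <= 0.5 whenever count > 0
  set.seed(5)
  cnt <- sample(1:1000, 200, TRUE)
  len <- sample(1e4:1e7, 200, TRUE)
  expect_true(all(abs(len / cnt - variantRate(cnt, len)) <= 0.5))
})

test_that("perChromosomeRates uses chromosome and genome lengths", {
  co <- toyCohort(matrix(rep("0/1", 10), 10, 1), pos = 1:10 * 50,
                  chrom = "chr1", chromLen = 1000L)
  r <- perChromosomeRates(co, "S01")
  snp1 <- r[r$chromosome == "chr1" & r$kind == "SNP", ]
  expect_equal(snp1$bp_per_variant, 100)
  # zero-variant kind gets the NA sentinel
  expect_true(is.na(r$bp_per_variant[r$kind == "indel" &
                                       r$chromosome == "chr1"]))
  expect_equal(r$length_bp[r$chromosome == "genome"][1], 1000)
})

test_that("binnedDensity follows the floor((pos-1)/size) convention", {
  co <- toyCohort(matrix(rep("0/1", 4), 4, 1),
                  pos = c(1L, 9999L, 10000L, 10001L), chromLen = 20000L)
  expect_equal(binnedDensity(co, "S01", "chr1", 10000), c(3L, 1L))
  # empty chromosome: all-zero bins
  co2 <- toyCohort(matrix("0/0", 1, 1), chromLen = 25000L)
  expect_equal(binnedDensity(co2, "S01", "chr1", 10000), c(0L, 0L, 0L))
  expect_error(binnedDensity(co, "S01", "chrZ", 10000), "chrZ")
})

test_that("bin sums equal chromosome counts equal sample counts", {
  res <- simulateCohort(fastConfig(301, lenPerChrom = 50000L))
  co <- res$cohort
  for (sm in cohortSamples(co)[c(1, 5)]) {
    r <- perChromosomeRates(co, sm)
    perChromTotal <- 0L
    for (ch in GenomeInfoDb::seqnames(genomeIndex(co))) {
      b <- binnedDensity(co, sm, ch)
      expect_equal(sum(b), sum(r$count[r$chromosome == ch]))
      perChromTotal <- perChromTotal + sum(b)
    }
    cv <- countVariants(co)$samples
    own <- cv[cv$sample == sm, ]
    expect_equal(perChromTotal, own$snp_count + own$indel_count)
  }
})

test_that("functional-class fractions are simplex-valued with NA sentinel", {
  cls <- c(rep("MISSENSE", 2), "NONSENSE", rep("SILENT", 7))
  co <- toyCohort(matrix("0/1", 10, 1), class = cls)
  f <- functionalClassFractions(co, "S01")
  expect_equal(c(f$missense, f$nonsense, f$silent), c(0.2, 0.1, 0.7))
  expect_equal(f$missense + f$nonsense + f$silent, 1, tolerance = 1e-9)
  coNone <- toyCohort(matrix("0/1", 3, 1), class = rep("NONE", 3))
  expect_true(is.na(functionalClassFractions(coNone, "S01")$missense))
})

test_that("the generated class contrast is recovered per population", {
  res <- simulateCohort(fastConfig(17, lenPerChrom = 100000L))
  f <- functionalClassFractions(res$cohort)
  agg <- aggregate(cbind(missense, nonsense, silent) ~ population,
                   data = f, FUN = mean)
  bw <- agg[agg$population == "BW", ]
  sm2 <- agg[agg$population == "SM2", ]
  expect_gt(bw$missense + bw$nonsense, sm2$missense + sm2$nonsense)
  expect_gt(sm2$silent, bw$silent)
})

test_that("indel length spectra partition a sample's indel count", {
  co <- toyCohort(matrix(c("0/1", "0/1"), 2, 1),
                  ref = c("A", "ATTT"), alt = c("ATG", "A"))
  sp <- indelLengthSpectrum(co, "S01")
  expect_equal(sp$insertions, data.frame(length = 2L, count = 1L))
  expect_equal(sp$deletions, data.frame(length = 3L, count = 1L))
  cv <- countVariants(co)$samples
  expect_equal(sum(sp$insertions$count) + sum(sp$deletions$count),
               cv$indel_count[1])
  empty <- indelLengthSpectrum(toyCohort(matrix("0/0", 1, 1)), "S01")
  expect_equal(nrow(empty$insertions), 0L)
})

test_that("region percentages sum to 100 with sentinel when unannotated", {
  co <- toyCohort(matrix("0/1", 4, 1),
                  ref = rep("ATT", 4), alt = rep("A", 4),
                  region = c(rep("intergenic", 3), "intron"))
  rd <- regionDistribution(co, "S01")
  expect_equal(unname(rd[c("intergenic", "intron")]), c(75, 25))
  expect_equal(sum(rd), 100, tolerance = 1e-6)
  noAnn <- toyCohort(matrix("0/1", 1, 1), ref = "ATT", alt = "A")
  expect_true(all(is.na(regionDistribution(noAnn, "S01"))))
})

test_that("BW-like simulations place no indels in UTRs", {
  res <- simulateCohort(fastConfig(23, lenPerChrom = 100000L))
  co <- res$cohort
  bw <- cohortSamples(co)[sampleInfo(co)$population == "BW"][1]
  rd <- regionDistribution(co, bw, kind = "indel")
  expect_equal(unname(rd["utr5"] + rd["utr3"]), 0)
})

test_that("recovered per-population SNP density is Poisson-consistent", {
  cfg <- fastConfig(61, lenPerChrom = 100000L, nChrom = 2L)
  res <- simulateCohort(cfg)
  L <- sum(cfg@genome$length)
  for (lab in c("SM2", "BW")) {
    lambda <- L * cfg@populations$snpDensity[
      cfg@populations$label == lab]
    n <- res$truth$realized$n_snp_sites[
      res$truth$realized$population == lab]
    expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  }
})
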
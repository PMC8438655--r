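test_that("foldedSFS bins minor-allele counts and skips monomorphic sites", {
  co <- toyCohort(rbind(c("0/1", "0/0"),
                        c("1/1", "1/1"),
                        c("0/0", "0/0")))
  sfs <- foldedSFS(co, "P1")
  expect_equal(unname(sfs$counts["1"]), 1L)
  expect_equal(sfs$segregatingSites, 1L)
  expect_equal(sfs$nHaplotypes, 4L)
})

test_that("sites with missing genotypes use the called-allele count", {
  co <- toyCohort(rbind(c("0/1", "./."),   # 1 of 2 called alleles
                        c("./.", "./.")))  # all missing: skipped
  sfs <- foldedSFS(co, "P1")
  expect_equal(sfs$segregatingSites, 1L)
  expect_equal(unname(sfs$counts["1"]), 1L)
})

test_that("the neutral generator yields a 1/i + 1/(2n-i) folded spectrum", {
  cfg <- simulationConfig(
    seed = 71,
    genome = data.frame(name = "chr1", length = 300000L),
    populations = data.frame(label = "P1", nSamples = 5L,
                             snpDensity = 1 / 60, indelDensity = 1e-5),
    lethal = NULL)
  res <- simulateCohort(cfg)
  sfs <- foldedSFS(res$cohort, "P1", kinds = "SNP")
  n <- sfs$nHaplotypes
  i <- seq_len(n %/% 2)
  w <- 1 / i + 1 / (n - i)
  w[i == n - i] <- 1 / i[i == n - i]        # the fold midpoint
  expectProp <- w / sum(w)
  total <- sum(sfs$counts)
  for (k in i) {
    mu <- total * expectProp[k]
    expect_lt(abs(sfs$counts[[k]] - mu),
              3 * sqrt(total * expectProp[k] * (1 - expectProp[k])) + 1)
  }
})

test_that("wattersonTheta is S over the harmonic number", {
  expect_equal(wattersonTheta(0, 8), 0)
  expect_equal(wattersonTheta(5, 2), 5)          # a_2 = 1
  expect_equal(wattersonTheta(95, 10), 95 / sum(1 / (1:9)))
  expect_equal(wattersonTheta(95, 10), 33.58, tolerance = 1e-3)
  expect_error(wattersonTheta(5, 1), "haplotypes")
  expect_error(wattersonTheta(-1, 4), ">= 0")
})

test_that("bucketed theta averages bucket S before dividing by a_n", {
  # two 10-kb buckets with 10 and 20 segregating sites, 4 diploids
  gts <- matrix("0/1", 30, 4)
  pos <- c(seq(100, by = 100, length.out = 10),
           seq(10100, by = 100, length.out = 20))
  co <- toyCohort(gts, pos = pos, chromLen = 20000L)
  bt <- bucketedTheta(co, "P1", bucketBp = 10000)
  a8 <- sum(1 / (1:7))
  expect_equal(bt$table$n_buckets, 2L)
  expect_equal(bt$table$mean_S, 15)
  expect_equal(bt$table$theta, 15 / a8)
  expect_equal(bt$average, 15 / a8)
})

test_that("a chromosome shorter than the bucket gives plain theta", {
  co <- toyCohort(matrix("0/1", 7, 4), chromLen = 5000L)
  bt <- bucketedTheta(co, "P1")                 # default 5e8 bp buckets
  sfs <- foldedSFS(co, "P1")
  expect_equal(bt$table$n_buckets, 1L)
  expect_equal(bt$table$theta,
               wattersonTheta(sfs$segregatingSites, sfs$nHaplotypes))
})

test_that("theta is invariant to sample order", {
  res <- simulateCohort(fastConfig(87, lenPerChrom = 40000L, nChrom = 1L))
  co <- res$cohort
  perm <- rev(seq_len(nrow(sampleInfo(co))))
  expect_equal(bucketedTheta(co, "SM2")$average,
               bucketedTheta(co[, perm], "SM2")$average)
})

test_that("the estimator recovers the generator theta", {
  a8 <- sum(1 / (1:7))
  theta <- 400
  L <- 1e6
  ratios <- vapply(1:40, function(i) {
    cfg <- simulationConfig(
      seed = 5000 + i,
      genome = data.frame(name = "w", length = as.integer(L)),
      populations = data.frame(label = "P1", nSamples = 4L,
                               snpDensity = theta * a8 / L,
                               indelDensity = 1e-6),
      lethal = NULL)
    res <- simulateCohort(cfg)
    bucketedTheta(res$cohort, "P1")$average / theta
  }, numeric(1))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("class heterozygosity divides het calls by the denominator", {
  co <- toyCohort(rbind(c("0/1", "0/0"), c("1/1", "0/1")),
                  class = c("SILENT", "MISSENSE"))
  h <- classHeterozygosity(co, classSet = "SILENT",
                           denominatorBp = 1000)
  expect_equal(h$samples$heterozygosity, c(0.001, 0))
  expect_equal(h$populations$mean, 0.0005)
  expect_error(classHeterozygosity(co, denominatorBp = 0), "positive")
  # no het calls at the class gives zero, not NA
  h2 <- classHeterozygosity(co, classSet = "NONSENSE",
                            denominatorBp = 100)
  expect_equal(h2$samples$heterozygosity, c(0, 0))
})

test_that("per-class het rates are recovered on fixed-frequency data", {
  p <- 0.5
  cfg <- simulationConfig(
    seed = 99,
    genome = data.frame(name = "chr1", length = 200000L),
    populations = data.frame(label = "P1", nSamples = 6L,
                             snpDensity = 1 / 80, indelDensity = 1e-5),
    freqLaw = list(type = "fixed", p = p),
    lethal = NULL)
  res <- simulateCohort(cfg)
  A <- alleleCalls(res$cohort)$A
  B <- alleleCalls(res$cohort)$B
  hetFrac <- mean(A != B)
  expHet <- 2 * p * (1 - p)
  n <- length(A)
  expect_lt(abs(hetFrac - expHet), 3 * sqrt(expHet * (1 - expHet) / n))
})

test_that("alleleFrequency matches hand arithmetic", {
  expect_equal(alleleFrequency(13, 24, 0), 24 / 74)
  expect_equal(alleleFrequency(0, 0, 10), 1)
  expect_equal(alleleFrequency(10, 0, 0), 0)
  expect_true(is.na(alleleFrequency(0, 0, 0)))
  expect_error(alleleFrequency(-1, 0, 0), ">= 0")
})

test_that("genotypeCountsAt tallies one site over chosen samples", {
  co <- toyCohort(rbind(c("0/1", "1/1", "0/0")), pos = 500L)
  expect_equal(genotypeCountsAt(co, "chr1", 500),
               c(nHomRef = 1L, nHet = 1L, nHomAlt = 1L))
  expect_error(genotypeCountsAt(co, "chr1", 501), "not found")
})

test_that("a simulated lethal locus is flagged with heterozygote excess", {
  res <- simulateCohort(fastConfig(13, lenPerChrom = 50000L))
  le <- res$truth$lethal
  cand <- flagLethalCandidates(res$cohort, minFreq = 0.2)
  hit <- cand[cand$chrom == le$chrom & cand$pos == le$pos, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_hom_alt, 0L)
  expect_equal(hit$n_het, le$nHet)
  expect_equal(hit$gene, "INSIG1")
})
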
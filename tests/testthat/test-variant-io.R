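test_that("classifyVariant follows the allele-length rules", {
  expect_equal(classifyVariant("A", "T"), "SNP")
  expect_equal(classifyVariant("A", "ATG"), "insertion")
  expect_equal(classifyVariant("ATTT", "A"), "deletion")
  expect_equal(classifyVariant("AT", "GC"), "other")
  expect_equal(classifyVariant("A", "TTG"), "other")  # no shared anchor
  expect_error(classifyVariant("", "T"), "non-empty")
})

test_that("classifyVariant partitions random allele pairs into one kind", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  mk <- function(n) vapply(sample(1:4, n, TRUE), function(l)
    paste(sample(bases, l, TRUE), collapse = ""), character(1))
  ref <- mk(500)
  alt <- mk(500)
  kind <- classifyVariant(ref, alt)
  expect_true(all(kind %in% c("SNP", "insertion", "deletion", "other")))
  expect_length(kind, 500)
})

test_that("readGenomeIndex handles .fai and chrom.sizes dialects", {
  fai <- tempfile(fileext = ".fai")
  writeLines(c("chr1\t1000000\t6\t70\t71", "chr2\t500000\t1014298\t70\t71"),
             fai)
  si <- readGenomeIndex(fai)
  expect_equal(GenomeInfoDb::seqnames(si), c("chr1", "chr2"))
  expect_equal(unname(GenomeInfoDb::seqlengths(si)), c(1000000L, 500000L))

  cs <- tempfile(fileext = ".sizes")
  writeLines("chrX 500000", cs)
  si2 <- readGenomeIndex(cs)
  expect_equal(GenomeInfoDb::seqnames(si2), "chrX")
  expect_equal(unname(GenomeInfoDb::seqlengths(si2)), 500000L)

  bad <- tempfile()
  writeLines(c("chr1\tabc"), bad)
  expect_error(readGenomeIndex(bad), "non-numeric")
  dup <- tempfile()
  writeLines(c("chr1 10", "chr1 20"), dup)
  expect_error(readGenomeIndex(dup), "duplicate")
})

writeToyVcf <- function(path, records,
                        samples = c("S1", "S2"),
                        contigs = "##contig=<ID=chr1,length=100000>") {
  hdr <- c("##fileformat=VCFv4.2", contigs,
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"m\">",
            c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
}

test_that("a toy VCF round-trips genotypes and annotations", {
  vcf <- tempfile(fileext = ".vcf")
  writeToyVcf(vcf, c(
    "chr1\t100\t.\tA\tT\t.\t.\tQD=25;ANN=T|missense_variant|MODERATE|GENE1|GENE1\tGT\t0/1\t0/0",
    "chr1\t200\t.\tG\tGAA\t.\t.\tQD=12\tGT\t1/1\t./.",
    "chr1\t300\t.\tC\tA,T\t.\t.\tQD=8\tGT\t1/2\t0/2"))
  co <- readVcfCohort(vcf, data.frame(sample = c("S1", "S2"),
                                      population = c("P1", "P2")))
  expect_equal(nSites(co), 3L)
  s <- variantSites(co)
  expect_equal(s$pos, c(100L, 200L, 300L))
  expect_equal(s$kind, c("SNP", "insertion", "SNP"))
  expect_equal(s$indelLength, c(NA_integer_, 2L, NA_integer_))
  # annotations: present on record 1, absent elsewhere
  expect_equal(s$class, c("MISSENSE", "NONE", "NONE"))
  expect_equal(s$gene[1], "GENE1")
  expect_true(all(is.na(s$region[2:3])))
  # genotypes preserved, multi-allelic kept as one record
  gt <- alleleCalls(co)
  expect_equal(gt$A[, "S1"], c(0L, 1L, 1L))
  expect_equal(gt$B[, "S1"], c(1L, 1L, 2L))
  expect_true(is.na(gt$A[2, "S2"]))
  expect_equal(lengths(s$alt), c(1L, 1L, 2L))
  # missing metric is absent, not zero
  expect_true(all(is.na(s$FS)))
  expect_equal(s$QD, c(25, 12, 8))
})

test_that("a VCF sample missing from the sample map is a config error", {
  vcf <- tempfile(fileext = ".vcf")
  writeToyVcf(vcf, "chr1\t100\t.\tA\tT\t.\t.\tQD=25\tGT\t0/1\t0/0")
  expect_error(
    readVcfCohort(vcf, data.frame(sample = "S1", population = "P1")),
    "absent from sample map")
})

test_that("parseAnnField maps effect terms to classes and regions", {
  p <- parseAnnField(c(
    "T|missense_variant|MODERATE|G1|G1",
    "T|stop_gained|HIGH|G2|G2",
    "T|synonymous_variant|LOW|G3|G3",
    "T|stop_retained_variant|LOW|G3b|G3b",
    "T|intron_variant|MODIFIER|G4|G4",
    "T|intergenic_region|MODIFIER||",
    "T|5_prime_UTR_variant|MODIFIER|G5|G5",
    "T|splice_donor_variant&intron_variant|HIGH|G6|G6",
    "T|some_unknown_term|MODIFIER|G7|G7",
    NA))
  expect_equal(p$class,
               c("MISSENSE", "NONSENSE", "SILENT", "SILENT", "NONE",
                 "NONE", "NONE", "NONE", "NONE", NA))
  expect_equal(p$region,
               c("exon", "exon", "exon", "exon", "intron", "intergenic",
                 "utr5", "splice_donor", "other", NA))
  # several entries: the first drives the summary
  multi <- parseAnnField(
    "T|stop_gained|HIGH|G1|G1,T|intron_variant|MODIFIER|G2|G2")
  expect_equal(multi$class, "NONSENSE")
  expect_equal(nrow(multi$entries[[1]]), 2L)
})

test_that("generator output re-read from disk matches the in-memory truth", {
  dir <- file.path(tempdir(), "cohort-roundtrip")
  res <- simulateCohort(fastConfig(42, lenPerChrom = 30000L), dir = dir)
  co <- readVcfCohort(res$paths$vcf, res$paths$sampleMap, res$paths$fai)
  orig <- res$cohort
  expect_equal(nSites(co), nSites(orig))
  so <- variantSites(orig)
  sr <- variantSites(co)
  expect_equal(sr$chrom, so$chrom)
  expect_equal(sr$pos, so$pos)
  expect_equal(sr$ref, so$ref)
  expect_equal(as.list(sr$alt), as.list(so$alt))
  expect_equal(sr$kind, so$kind)
  expect_equal(sr$class, so$class)
  expect_equal(sr$region, so$region)
  expect_equal(sr$QD, so$QD, tolerance = 1e-6)
  # genotypes as unordered allele pairs
  go <- alleleCalls(orig)
  gr <- alleleCalls(co)
  expect_equal(pmin(gr$A, gr$B), pmin(go$A, go$B))
  expect_equal(pmax(gr$A, gr$B), pmax(go$A, go$B))
  # fai lengths agree with the config
  si <- readGenomeIndex(res$paths$fai)
  expect_equal(unname(GenomeInfoDb::seqlengths(si)), rep(30000L, 2))
  # truth site table is record-for-record consistent with the VCF
  expect_equal(res$truth$sites$pos, sr$pos)
})

test_that("the same seed yields a byte-identical VCF", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  r1 <- simulateCohort(fastConfig(99, lenPerChrom = 20000L, nChrom = 1L),
                       dir = d1)
  r2 <- simulateCohort(fastConfig(99, lenPerChrom = 20000L, nChrom = 1L),
                       dir = d2)
  expect_identical(readLines(r1$paths$vcf), readLines(r2$paths$vcf))
})
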
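#' Per-sample variant carriage
#'
#' A sample carries a site when its genotype contains at least one
#' non-reference allele; a missing genotype never counts as carriage.
#'
#' @param cohort a [VariantCohort-class].
#' @param sample optional sample name(s); default all samples.
#' @return logical matrix (sites x samples), or a vector for a single
#'   sample.
#' @export
perSamplePresence <- function(cohort, sample = NULL) {
  .assertCohort(cohort)
  A <- cohort@alleleA
  B <- cohort@alleleB
  M <- (!is.na(A) & A > 0L) | (!is.na(B) & B > 0L)
  if (is.null(sample)) return(M)
  .assertSample(cohort, sample)
  M[, sample, drop = length(sample) == 1L]
}

#' Count SNPs and indels per sample and per population
#'
#' Counts sites (not alleles) carried by each sample, split into SNPs
#' and indels (insertions + deletions), plus per-population mean, min,
#' max and the union count (sites carried by at least one sample of
#' the population).
#'
#' @param cohort a [VariantCohort-class].
#' @return list with data.frames `samples` (sample, population,
#'   snp_count, indel_count) and `populations` (population, kind, mean,
#'   min, max, union).
#' @export
countVariants <- function(cohort) {
  .assertCohort(cohort)
  if (nSites(cohort) == 0L)
    warning("cohort has no sites; returning all-zero counts")
  pres <- perSamplePresence(cohort)
  isSnp <- cohort@sites$kind == "SNP"
  isIndel <- cohort@sites$kind %in% c("insertion", "deletion")
  snp <- colSums(pres & isSnp)
  ind <- colSums(pres & isIndel)
  samples <- data.frame(sample = cohort@sampleMap$sample,
                        population = cohort@sampleMap$population,
                        snp_count = as.integer(snp),
                        indel_count = as.integer(ind),
                        row.names = NULL)
  pops <- unique(cohort@sampleMap$population)
  popRows <- do.call(rbind, lapply(pops, function(p) {
    ps <- cohort@sampleMap$sample[cohort@sampleMap$population == p]
    sub <- pres[, ps, drop = FALSE]
    anyCarr <- rowSums(sub) > 0L
    do.call(rbind, lapply(list(c("SNP", "snp_count"),
                               c("indel", "indel_count")), function(k) {
      cts <- samples[samples$population == p, k[2]]
      un <- sum(anyCarr & (if (k[1] == "SNP") isSnp else isIndel))
      data.frame(population = p, kind = k[1], mean = mean(cts),
                 min = min(cts), max = max(cts), union = as.integer(un))
    }))
  }))
  list(samples = samples, populations = popRows)
}

#' Variant rate in bp per variant
#'
#' `lengthBp / count`, rounded to the nearest integer (ties away from
#' zero). A zero count yields `NA` (undefined), not an error.
#'
#' @param count non-negative variant count(s).
#' @param lengthBp positive sequence length(s) in bp.
#' @return numeric vector of bp-per-variant rates.
#' @examples
#' variantRate(12.1e6, 2.5e9)  # 207 bp per SNP
#' @export
variantRate <- function(count, lengthBp) {
  if (any(count < 0) || any(lengthBp <= 0))
    stop("count must be >= 0 and lengthBp > 0", call. = FALSE)
  out <- .roundHalfAway(lengthBp / count)
  out[count == 0] <- NA_real_
  out
}

#' Per-chromosome variant rates for one sample
#'
#' One row per chromosome and kind (SNP / indel), plus a genome-wide
#' row (`chromosome = "genome"`) using the summed indexed chromosome
#' lengths. Chromosomes with zero variants of a kind get an `NA` rate.
#'
#' @param cohort a [VariantCohort-class] with a genome index.
#' @param sample sample name.
#' @return data.frame (sample, chromosome, kind, count, length_bp,
#'   bp_per_variant).
#' @export
perChromosomeRates <- function(cohort, sample) {
  .assertCohort(cohort)
  .assertSample(cohort, sample)
  if (is.null(cohort@genome))
    stop("cohort has no genome index", call. = FALSE)
  sl <- seqlengths(cohort@genome)
  pres <- perSamplePresence(cohort, sample)
  s <- cohort@sites
  rows <- do.call(rbind, lapply(names(sl), function(ch) {
    onCh <- s$chrom == ch & pres
    nS <- sum(onCh & s$kind == "SNP")
    nI <- sum(onCh & s$kind %in% c("insertion", "deletion"))
    data.frame(sample = sample, chromosome = ch, kind = c("SNP", "indel"),
               count = c(nS, nI), length_bp = as.numeric(sl[[ch]]))
  }))
  tot <- sum(as.numeric(sl))
  genomeRows <- do.call(rbind, lapply(c("SNP", "indel"), function(k)
    data.frame(sample = sample, chromosome = "genome", kind = k,
               count = sum(rows$count[rows$kind == k]), length_bp = tot)))
  out <- rbind(rows, genomeRows)
  out$bp_per_variant <- variantRate(out$count, out$length_bp)
  out
}

#' Binned variant density along a chromosome
#'
#' Counts one sample's carried variants in consecutive fixed-size bins:
#' bin index = `floor((pos - 1) / binSize)`, with
#' `ceiling(length / binSize)` bins in total.
#'
#' @param cohort a [VariantCohort-class] with a genome index.
#' @param sample sample name.
#' @param chrom chromosome name (must be in the genome index).
#' @param binSize bin width in bp (default 10 kb).
#' @param kinds which variant kinds to count (default all).
#' @return integer vector of per-bin counts.
#' @export
binnedDensity <- function(cohort, sample, chrom, binSize = 10000,
                          kinds = .KIND_LEVELS) {
  .assertCohort(cohort)
  .assertSample(cohort, sample)
  stopifnot(binSize >= 1)
  if (is.null(cohort@genome))
    stop("cohort has no genome index", call. = FALSE)
  sl <- seqlengths(cohort@genome)
  if (!chrom %in% names(sl))
    stop("chromosome '", chrom, "' not in genome index", call. = FALSE)
  nBins <- ceiling(sl[[chrom]] / binSize)
  pres <- perSamplePresence(cohort, sample)
  sel <- cohort@sites$chrom == chrom & pres &
    cohort@sites$kind %in% kinds
  bin <- (cohort@sites$pos[sel] - 1L) %/% as.integer(binSize) + 1L
  tabulate(bin, nbins = nBins)
}

#' Functional-class fractions of classified SNPs
#'
#' Fractions of missense, nonsense and silent among the SNPs a sample
#' carries whose class is not `NONE`. When the sample carries no
#' classified SNP the fractions are `NA` (undefined).
#'
#' @param cohort a [VariantCohort-class].
#' @param sample optional sample name(s); default all.
#' @return data.frame (sample, population, n_classified, missense,
#'   nonsense, silent); fractions sum to 1.
#' @export
functionalClassFractions <- function(cohort, sample = NULL) {
  .assertCohort(cohort)
  if (is.null(sample)) sample <- cohortSamples(cohort)
  .assertSample(cohort, sample)
  pres <- perSamplePresence(cohort)
  isCl <- cohort@sites$kind == "SNP" & cohort@sites$class != "NONE"
  out <- do.call(rbind, lapply(sample, function(sm) {
    sel <- pres[, sm] & isCl
    n <- sum(sel)
    if (n == 0) {
      fr <- c(NA_real_, NA_real_, NA_real_)
    } else {
      cl <- factor(cohort@sites$class[sel],
                   levels = c("MISSENSE", "NONSENSE", "SILENT"))
      fr <- as.vector(table(cl)) / n
    }
    data.frame(sample = sm,
               population = cohort@sampleMap$population[
                 match(sm, cohort@sampleMap$sample)],
               n_classified = n, missense = fr[1], nonsense = fr[2],
               silent = fr[3])
  }))
  rownames(out) <- NULL
  out
}

#' Indel length spectrum for one sample
#'
#' Histograms of insertion and deletion lengths (bp) over the indels
#' the sample carries; the total mass of each histogram equals the
#' sample's indel count of that kind.
#'
#' @param cohort a [VariantCohort-class].
#' @param sample sample name.
#' @return list with data.frames `insertions` and `deletions`, each
#'   with columns `length` and `count`.
#' @export
indelLengthSpectrum <- function(cohort, sample) {
  .assertCohort(cohort)
  .assertSample(cohort, sample)
  pres <- perSamplePresence(cohort, sample)
  one <- function(kind) {
    sel <- pres & cohort@sites$kind == kind
    len <- cohort@sites$indelLength[sel]
    if (!length(len))
      return(data.frame(length = integer(0), count = integer(0)))
    tb <- table(len)
    data.frame(length = as.integer(names(tb)), count = as.integer(tb))
  }
  list(insertions = one("insertion"), deletions = one("deletion"))
}

#' Gene-region distribution of a sample's variants
#'
#' Percentage of the sample's carried variants of a kind falling in
#' each annotated gene region. Unannotated (`NA` region) records are
#' excluded; the percentages sum to 100.
#'
#' @param cohort a [VariantCohort-class].
#' @param sample sample name.
#' @param kind `"indel"` (default, = insertions + deletions) or `"SNP"`.
#' @return named numeric vector of percentages over all region levels,
#'   or `NA`-valued when the sample has no annotated record of the kind.
#' @export
regionDistribution <- function(cohort, sample, kind = c("indel", "SNP")) {
  .assertCohort(cohort)
  .assertSample(cohort, sample)
  kind <- match.arg(kind)
  kinds <- if (kind == "indel") c("insertion", "deletion") else "SNP"
  pres <- perSamplePresence(cohort, sample)
  sel <- pres & cohort@sites$kind %in% kinds &
    !is.na(cohort@sites$region)
  if (!sum(sel))
    return(setNames(rep(NA_real_, length(.REGION_LEVELS)), .REGION_LEVELS))
  reg <- factor(cohort@sites$region[sel], levels = .REGION_LEVELS)
  setNames(100 * as.vector(table(reg)) / sum(sel), .REGION_LEVELS)
}
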
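# population-level genotype tallies at biallelic sites
# returns per-site alt-allele count, called-allele count, and a
# biallelic indicator, over the samples of one population
.popSiteStats <- function(cohort, popSamples) {
  A <- cohort@alleleA[, popSamples, drop = FALSE]
  B <- cohort@alleleB[, popSamples, drop = FALSE]
  called <- rowSums(!is.na(A)) + rowSums(!is.na(B))
  altCount <- rowSums(A == 1L, na.rm = TRUE) + rowSums(B == 1L, na.rm = TRUE)
  otherAlt <- rowSums(!is.na(A) & A > 1L) + rowSums(!is.na(B) & B > 1L)
  list(called = called, altCount = altCount,
       biallelic = lengths(cohort@sites$alt) == 1L & otherAlt == 0L)
}

.popSamplesOf <- function(cohort, population) {
  ps <- cohort@sampleMap$sample[cohort@sampleMap$population == population]
  if (!length(ps))
    stop("population '", population, "' has no samples", call. = FALSE)
  ps
}

#' Folded site frequency spectrum
#'
#' For each biallelic site with at least one called genotype in the
#' window, the bin of its minor-allele count among called alleles is
#' incremented. Sites monomorphic within the population (including
#' all-missing sites) do not segregate and contribute to no bin.
#'
#' @param cohort a [VariantCohort-class].
#' @param population population label.
#' @param chrom,start,end optional window restriction (1-based,
#'   inclusive); the window must lie on an indexed chromosome.
#' @param kinds variant kinds included (default all).
#' @return list: `counts` (named vector over minor-allele counts
#'   `1..floor(n/2)`), `nHaplotypes` (2 x population size),
#'   `segregatingSites`.
#' @export
foldedSFS <- function(cohort, population, chrom = NULL, start = NULL,
                      end = NULL, kinds = .KIND_LEVELS) {
  .assertCohort(cohort)
  ps <- .popSamplesOf(cohort, population)
  sel <- cohort@sites$kind %in% kinds
  if (!is.null(chrom)) {
    if (!is.null(cohort@genome)) {
      sl <- seqlengths(cohort@genome)
      if (!chrom %in% names(sl))
        stop("chromosome '", chrom, "' not in genome index", call. = FALSE)
      if (!is.null(end) && end > sl[[chrom]])
        stop("window beyond chromosome length", call. = FALSE)
    }
    sel <- sel & cohort@sites$chrom == chrom
    if (!is.null(start)) sel <- sel & cohort@sites$pos >= start
    if (!is.null(end)) sel <- sel & cohort@sites$pos <= end
  }
  st <- .popSiteStats(cohort, ps)
  nHap <- 2L * length(ps)
  use <- sel & st$biallelic & st$called > 0L &
    st$altCount > 0L & st$altCount < st$called
  minor <- pmin(st$altCount[use], st$called[use] - st$altCount[use])
  nBins <- max(1L, nHap %/% 2L)
  counts <- tabulate(minor, nbins = nBins)
  list(counts = setNames(counts, seq_len(nBins)),
       nHaplotypes = nHap, segregatingSites = sum(use))
}

#' Watterson's estimator of theta
#'
#' `theta = S / a_n` with `a_n` the (n-1)-th harmonic number over `n`
#' haplotypes and `S` the number of segregating sites.
#'
#' @param S segregating-site count (>= 0).
#' @param nHaplotypes number of haplotypes (>= 2).
#' @return theta (>= 0; 0 iff `S` is 0).
#' @examples
#' wattersonTheta(95, 10)  # 95 / 2.828968
#' @export
wattersonTheta <- function(S, nHaplotypes) {
  if (any(S < 0)) stop("S must be >= 0", call. = FALSE)
  if (nHaplotypes < 2) stop("need at least 2 haplotypes", call. = FALSE)
  S / .wattersonA(nHaplotypes)
}

#' Bucketed Watterson theta per chromosome
#'
#' Each chromosome is split into `ceiling(length / bucketBp)` buckets;
#' the segregating-site count of each bucket is taken from the folded
#' spectrum of the population, the bucket counts are averaged per
#' chromosome, and theta is the averaged count divided by `a_n` with
#' `n = 2 x population size` haplotypes. The per-chromosome table is
#' returned with the average, minimum and maximum across chromosomes.
#'
#' @param cohort a [VariantCohort-class] with a genome index.
#' @param population population label.
#' @param bucketBp bucket size in bp (default 5e8).
#' @param kinds variant kinds counted as segregating (default SNPs).
#' @return list: `table` (population, chromosome, n_buckets, mean_S,
#'   theta), `average`, `min`, `max`, `minChromosome`, `maxChromosome`,
#'   `nHaplotypes`.
#' @export
bucketedTheta <- function(cohort, population, bucketBp = 5e8,
                          kinds = "SNP") {
  .assertCohort(cohort)
  if (is.null(cohort@genome))
    stop("cohort has no genome index", call. = FALSE)
  ps <- .popSamplesOf(cohort, population)
  nHap <- 2L * length(ps)
  a <- .wattersonA(nHap)
  st <- .popSiteStats(cohort, ps)
  seg <- cohort@sites$kind %in% kinds & st$biallelic &
    st$altCount > 0L & st$altCount < st$called
  sl <- seqlengths(cohort@genome)
  tab <- do.call(rbind, lapply(names(sl), function(ch) {
    nB <- as.integer(ceiling(sl[[ch]] / bucketBp))
    onCh <- seg & cohort@sites$chrom == ch
    bucket <- (cohort@sites$pos[onCh] - 1) %/% bucketBp + 1
    S <- tabulate(bucket, nbins = nB)
    meanS <- mean(S)
    data.frame(population = population, chromosome = ch, n_buckets = nB,
               mean_S = meanS, theta = meanS / a)
  }))
  list(table = tab, average = mean(tab$theta), min = min(tab$theta),
       max = max(tab$theta),
       minChromosome = tab$chromosome[which.min(tab$theta)],
       maxChromosome = tab$chromosome[which.max(tab$theta)],
       nHaplotypes = nHap)
}

#' Functional-class heterozygosity
#'
#' Per sample: the number of heterozygous genotype calls at SNP sites
#' whose functional class is in `classSet`, divided by a per-bp
#' denominator. The denominator defaults to the number of classified
#' (class != NONE) SNP sites in the cohort — the assessed coding
#' positions the VCF knows about — and should be supplied explicitly
#' when a better coding-length estimate exists.
#'
#' @param cohort a [VariantCohort-class].
#' @param classSet subset of `c("MISSENSE","NONSENSE","SILENT")`.
#' @param denominatorBp positive denominator in bp, or `NULL` for the
#'   default above.
#' @return list: `samples` (sample, population, het_count,
#'   heterozygosity), `populations` (population, mean, sd),
#'   `denominatorBp`.
#' @export
classHeterozygosity <- function(cohort,
                                classSet = c("MISSENSE", "NONSENSE"),
                                denominatorBp = NULL) {
  .assertCohort(cohort)
  stopifnot(all(classSet %in% c("MISSENSE", "NONSENSE", "SILENT")))
  if (is.null(denominatorBp))
    denominatorBp <- sum(cohort@sites$kind == "SNP" &
                           cohort@sites$class != "NONE")
  if (!is.numeric(denominatorBp) || denominatorBp <= 0)
    stop("denominatorBp must be positive", call. = FALSE)
  A <- cohort@alleleA
  B <- cohort@alleleB
  het <- !is.na(A) & !is.na(B) & A != B
  atClass <- cohort@sites$kind == "SNP" & cohort@sites$class %in% classSet
  cnt <- colSums(het & atClass)
  samples <- data.frame(sample = cohort@sampleMap$sample,
                        population = cohort@sampleMap$population,
                        het_count = as.integer(cnt),
                        heterozygosity = cnt / denominatorBp,
                        row.names = NULL)
  pops <- do.call(rbind, lapply(unique(samples$population), function(p) {
    h <- samples$heterozygosity[samples$population == p]
    data.frame(population = p, mean = mean(h), sd = sd(h))
  }))
  list(samples = samples, populations = pops,
       denominatorBp = denominatorBp)
}

#' Alternate-allele frequency from genotype counts
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts.
#' @return `(2 nHomAlt + nHet) / (2 total)`, or `NA` when the total is
#'   zero.
#' @examples
#' alleleFrequency(13, 24, 0)  # 24/74
#' @export
alleleFrequency <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (any(counts < 0)) stop("genotype counts must be >= 0", call. = FALSE)
  total <- nHomRef + nHet + nHomAlt
  if (total == 0) return(NA_real_)
  (2 * nHomAlt + nHet) / (2 * total)
}

#' Genotype counts at one site
#'
#' Tallies hom-ref / het / hom-alt genotypes (any alternate allele
#' counts as alt) at a `chrom:pos` site over the given samples.
#'
#' @param cohort a [VariantCohort-class].
#' @param chrom,pos site coordinates.
#' @param samples optional sample subset; default all.
#' @return named integer vector (nHomRef, nHet, nHomAlt); missing
#'   genotypes are excluded.
#' @export
genotypeCountsAt <- function(cohort, chrom, pos, samples = NULL) {
  .assertCohort(cohort)
  i <- which(cohort@sites$chrom == chrom & cohort@sites$pos == pos)
  if (length(i) != 1L)
    stop("site ", chrom, ":", pos, " not found", call. = FALSE)
  if (is.null(samples)) samples <- cohortSamples(cohort)
  a <- cohort@alleleA[i, samples]
  b <- cohort@alleleB[i, samples]
  ok <- !is.na(a) & !is.na(b)
  nAlt <- (a[ok] > 0) + (b[ok] > 0)
  c(nHomRef = sum(nAlt == 0), nHet = sum(nAlt == 1),
    nHomAlt = sum(nAlt == 2))
}

#' Flag candidate recessive-lethal loci
#'
#' Sites whose alternate allele is common (frequency >= `minFreq`) yet
#' never observed in homozygous state are candidates for recessive
#' lethality; each is tested for heterozygote excess with the
#' one-sided exact test.
#'
#' @param cohort a [VariantCohort-class].
#' @param minFreq minimum alternate-allele frequency (default 0.2).
#' @return data.frame (chrom, pos, gene, n_hom_ref, n_het, n_hom_alt,
#'   allele_freq, p_het_excess), possibly with zero rows.
#' @export
flagLethalCandidates <- function(cohort, minFreq = 0.2) {
  .assertCohort(cohort)
  A <- cohort@alleleA
  B <- cohort@alleleB
  ok <- !is.na(A) & !is.na(B)
  altA <- ok & A > 0L
  altB <- ok & B > 0L
  nAltAllele <- rowSums(altA) + rowSums(altB)
  nCalled <- rowSums(ok)
  nHomAlt <- rowSums(altA & altB)
  freq <- ifelse(nCalled > 0, nAltAllele / (2 * nCalled), NA_real_)
  idx <- which(!is.na(freq) & freq >= minFreq & nHomAlt == 0L &
                 nCalled > 0L)
  out <- do.call(rbind, lapply(idx, function(i) {
    het <- sum(xor(altA[i, ], altB[i, ]))
    homRef <- nCalled[i] - het
    p <- hweExactTest(homRef, het, 0L, alternative = "excess")$p.value
    data.frame(chrom = cohort@sites$chrom[i], pos = cohort@sites$pos[i],
               gene = cohort@sites$gene[i], n_hom_ref = homRef,
               n_het = het, n_hom_alt = 0L, allele_freq = freq[i],
               p_het_excess = p)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      gene = character(0), n_hom_ref = integer(0),
                      n_het = integer(0), n_hom_alt = integer(0),
                      allele_freq = numeric(0), p_het_excess = numeric(0))
  out
}
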
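.BASES <- c("A", "C", "G", "T")

.defaultRegionPropsSnp <- function(labels) {
  p <- c(intergenic = 0.60, intron = 0.34, exon = 0, utr5 = 0.002,
         utr3 = 0.003, upstream = 0.025, downstream = 0.028,
         splice_donor = 0.001, splice_acceptor = 0.001, other = 0)
  matrix(rep(p, each = length(labels)), nrow = length(labels),
         dimnames = list(labels, names(p)))
}

.defaultRegionPropsIndel <- function(labels) {
  base <- rbind(
    SM2like = c(intergenic = 0.575, intron = 0.355, exon = 0.012,
                utr5 = 0.003, utr3 = 0.004, upstream = 0.025,
                downstream = 0.024, splice_donor = 0.001,
                splice_acceptor = 0.001, other = 0),
    BWlike  = c(intergenic = 0.580, intron = 0.360, exon = 0.008,
                utr5 = 0, utr3 = 0, upstream = 0.025,
                downstream = 0.025, splice_donor = 0.001,
                splice_acceptor = 0.001, other = 0))
  out <- base[rep_len(1:2, length(labels)), , drop = FALSE]
  rownames(out) <- labels
  out
}

#' Study conditions for the synthetic two-population cohort
#'
#' Builds a validated [SimulationConfig-class]. The defaults emulate a
#' two-stock deer-mouse colony cohort at desk scale: a 5-chromosome
#' 1-Mb toy genome; a high-diversity population (`SM2`, 4 samples, one
#' SNP per 55 bp, one indel per 311 bp) against a lower-diversity one
#' (`BW`, 6 samples, one SNP per 207 bp, one indel per 1157 bp) — a
#' roughly 4x density contrast; a neutral-like allele-frequency law;
#' population-specific missense/nonsense/silent proportions (silent
#' prevails in the high-diversity stock, missense+nonsense in the
#' other); indel lengths with geometric decay plus a deletion-length
#' bump at 180 bp; zero UTR indels in the BW-like stock; and one
#' recessive-lethal locus segregating with zero homozygous-mutant
#' individuals.
#'
#' @param seed integer RNG seed.
#' @param genome data.frame with `name`, `length` columns.
#' @param populations data.frame with `label`, `nSamples`,
#'   `snpDensity`, `indelDensity` (densities per bp, in (0, 0.1)).
#' @param freqLaw `list(type = "neutral")` draws each site's
#'   derived-allele count `j` in `1..2n-1` with weight `1/j` and places
#'   the `j` alternate alleles uniformly among the `2n` haplotype slots
#'   (the Hardy-Weinberg conditional law, with folded expectation
#'   proportional to `1/i + 1/(2n-i)`); `list(type = "fixed", p = x)`
#'   draws genotypes Binomial(2, x) per sample.
#' @param classProps matrix (population x missense/nonsense/silent).
#' @param codingFraction named fraction of SNPs given a coding class.
#' @param regionPropsSnp,regionPropsIndel matrices (population x
#'   region) for unclassified SNPs and for indels.
#' @param indelLaw list `p` (geometric parameter on lengths 1, 2, ...),
#'   `delBumpCenter`, `delBumpSd`, `delBumpMass` (deletion-length bump).
#' @param lethal `list(chrom, pos, freq, gene)` or `NULL`.
#' @param missingRate per-genotype missingness rate.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(
    seed = 1L,
    genome = data.frame(name = paste0("chr", 1:5),
                        length = rep(200000L, 5)),
    populations = data.frame(
      label = c("SM2", "BW"), nSamples = c(4L, 6L),
      snpDensity = c(1 / 55, 1 / 207),
      indelDensity = c(1 / 311, 1 / 1157)),
    freqLaw = list(type = "neutral"),
    classProps = NULL, codingFraction = NULL,
    regionPropsSnp = NULL, regionPropsIndel = NULL,
    indelLaw = list(p = 0.35, delBumpCenter = 180, delBumpSd = 5,
                    delBumpMass = 0.01),
    lethal = list(chrom = genome$name[1], pos = 5000L, freq = 0.32,
                  gene = "INSIG1"),
    missingRate = 0) {
  labels <- populations$label
  if (is.null(classProps)) {
    classProps <- rbind(c(0.25, 0.03, 0.72), c(0.36, 0.04, 0.60))
    classProps <- classProps[rep_len(1:2, length(labels)), , drop = FALSE]
    dimnames(classProps) <- list(labels,
                                 c("missense", "nonsense", "silent"))
  }
  if (is.null(codingFraction))
    codingFraction <- setNames(rep(0.02, length(labels)), labels)
  if (is.null(regionPropsSnp))
    regionPropsSnp <- .defaultRegionPropsSnp(labels)
  if (is.null(regionPropsIndel))
    regionPropsIndel <- .defaultRegionPropsIndel(labels)
  new("SimulationConfig", seed = as.integer(seed),
      genome = data.frame(name = as.character(genome$name),
                          length = as.integer(genome$length)),
      populations = populations, freqLaw = freqLaw,
      classProps = classProps, codingFraction = codingFraction,
      regionPropsSnp = regionPropsSnp,
      regionPropsIndel = regionPropsIndel,
      indelLaw = indelLaw, lethal = lethal,
      missingRate = missingRate)
}

#' Draw indel lengths from a geometric law with an optional bump
#'
#' Lengths are i.i.d. from a mixture: with probability
#' `1 - bumpMass` geometric on 1, 2, ... (success probability `p`,
#' mean `1/p`), otherwise a discretized normal bump centered at
#' `bumpCenter` (floored at 1 bp).
#'
#' @param n number of draws.
#' @param law list with `p` and optionally `bumpCenter` (`delBumpCenter`
#'   also accepted), `bumpSd` and `bumpMass`.
#' @return integer vector of `n` lengths (>= 1).
#' @export
drawIndelLengths <- function(n, law) {
  stopifnot(is.numeric(law$p), law$p > 0, law$p <= 1)
  if (n == 0) return(integer(0))
  center <- law$bumpCenter %||% law$delBumpCenter
  sdv <- law$bumpSd %||% law$delBumpSd %||% 5
  mass <- law$bumpMass %||% law$delBumpMass %||% 0
  fromBump <- if (!is.null(center) && mass > 0) runif(n) < mass
              else rep(FALSE, n)
  len <- integer(n)
  len[!fromBump] <- 1L + rgeom(sum(!fromBump), law$p)
  if (any(fromBump))
    len[fromBump] <- pmax(1L, as.integer(round(
      rnorm(sum(fromBump), center, sdv))))
  len
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genotypes for a recessive-lethal locus
#'
#' Draws `nSamples` diploid genotypes from Hardy-Weinberg proportions
#' conditioned on containing no homozygous-mutant individual. `freq`
#' is the target allele frequency *after* conditioning — the frequency
#' an assay of the living animals would observe. Because the no-homozygote
#' event factorizes over individuals, the conditional law is an
#' independent heterozygote indicator per sample with
#' `P(het) = 2 freq` (equivalently, underlying unconditional HWE
#' frequency `freq / (1 - freq)`), so the expected heterozygote count
#' is `2 freq x nSamples`. Frequencies at or above 0.5 are infeasible
#' under the constraint and rejected.
#'
#' @param freq target post-conditioning allele frequency, in (0, 0.5).
#' @param nSamples number of individuals.
#' @return list: `genotypes` (0 = hom-ref, 1 = het), `realizedFreq`,
#'   `nHet`.
#' @export
injectLethalLocus <- function(freq, nSamples) {
  if (!(freq > 0 && freq < 0.5))
    stop("lethal-locus freq must be in (0, 0.5): no-homozygote ",
         "genotypes cannot realize higher frequencies", call. = FALSE)
  stopifnot(nSamples >= 1)
  g <- rbinom(nSamples, 1L, 2 * freq)
  list(genotypes = g, realizedFreq = sum(g) / (2 * nSamples),
       nHet = sum(g == 1L))
}

# neutral-like law: derived count j ~ 1/j over 1..(nHap-1), alleles
# placed uniformly among haplotype slots; returns 0/1 matrix
# (sites x nHap)
.neutralHaplotypes <- function(nSite, nHap) {
  j <- sample.int(nHap - 1L, nSite, replace = TRUE,
                  prob = 1 / seq_len(nHap - 1L))
  R <- matrix(runif(nSite * nHap), nSite, nHap)
  alt <- matrix(0L, nSite, nHap)
  for (c in seq_len(nHap)) {
    rk <- rowSums(R < R[, c])        # rank 0..nHap-1, ties a.s. absent
    alt[, c] <- as.integer(rk < j)
  }
  alt
}

.randomSeq <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

.randomString <- function(lens) {
  vapply(lens, function(l) paste(sample(.BASES, l, replace = TRUE),
                                 collapse = ""), character(1))
}

#' Simulate a two-population variant cohort
#'
#' Generates a desk-scale cohort under a [SimulationConfig-class]:
#' per-chromosome site counts are Poisson(density x length) per
#' population, positions are distinct and sorted (and disjoint across
#' populations — each polymorphic site belongs to one source
#' population, the other being reference there), allele frequencies
#' follow the configured law, genotypes are Hardy-Weinberg at that
#' frequency, ANN annotations encode the configured class/region
#' draws, site metrics are drawn in filter-passing ranges, and the
#' optional lethal locus is drawn conditional on zero
#' homozygous-mutant genotypes across the whole cohort. Deterministic
#' under the seed: the same config yields a byte-identical VCF.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory, or `NULL` for an in-memory cohort (no
#'   files, no reference sequence).
#' @return list: `cohort` (a [VariantCohort-class]), `truth` (config
#'   echo, per-site origin/frequency table, realized per-population
#'   counts, lethal-locus realization), and `paths` (VCF, FASTA, fai,
#'   sample map, truth JSON; `NULL` in-memory).
#' @export
simulateCohort <- function(config, dir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, .simulateCohortImpl(config, dir))
}

.simulateCohortImpl <- function(config, dir) {
  genome <- config@genome
  pops <- config@populations
  nPop <- nrow(pops)
  sampleMap <- do.call(rbind, lapply(seq_len(nPop), function(p)
    data.frame(sample = sprintf("%s_%02d", pops$label[p],
                                seq_len(pops$nSamples[p])),
               population = pops$label[p])))
  nSamp <- nrow(sampleMap)
  popCols <- lapply(pops$label,
                    function(l) which(sampleMap$population == l))
  names(popCols) <- pops$label

  seqs <- NULL
  if (!is.null(dir)) {
    seqs <- setNames(vapply(genome$length, .randomSeq, character(1)),
                     genome$name)
  }

  siteList <- list()
  gA <- list()
  gB <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$name[ci]
    L <- genome$length[ci]
    nSnp <- rpois(nPop, L * pops$snpDensity)
    nInd <- rpois(nPop, L * pops$indelDensity)
    nTot <- sum(nSnp) + sum(nInd)
    if (nTot == 0) next
    if (nTot > L)
      stop("densities imply more sites than base pairs on ", ch,
           call. = FALSE)
    posAll <- sample.int(L, nTot)       # distinct across populations
    offset <- 0L
    for (p in seq_len(nPop)) {
      lab <- pops$label[p]
      n <- nSnp[p] + nInd[p]
      if (n == 0) next
      pos <- posAll[offset + seq_len(n)]
      offset <- offset + n
      kind <- sample(rep(c("SNP", "indel"), c(nSnp[p], nInd[p])))
      isIndel <- kind == "indel"
      isDel <- isIndel & runif(n) < 0.5
      isDel[isIndel & pos >= L] <- FALSE     # no room to delete at the end
      isIns <- isIndel & !isDel
      len <- rep(NA_integer_, n)
      law <- config@indelLaw
      len[isIns] <- drawIndelLengths(sum(isIns),
                                     list(p = law$p))
      len[isDel] <- drawIndelLengths(sum(isDel), law)
      len[isDel] <- pmin(len[isDel], L - pos[isDel])
      kind[isIns] <- "insertion"
      kind[isDel] <- "deletion"

      refBase <- if (!is.null(seqs)) substring(seqs[[ch]], pos, pos)
                 else sample(.BASES, n, replace = TRUE)
      ref <- refBase
      alt <- refBase
      isSnp <- kind == "SNP"
      if (any(isSnp)) {
        idx <- match(refBase[isSnp], .BASES)
        alt[isSnp] <- .BASES[(idx - 1L +
                                sample.int(3L, sum(isSnp),
                                           replace = TRUE)) %% 4L + 1L]
      }
      if (any(isIns))
        alt[isIns] <- paste0(refBase[isIns], .randomString(len[isIns]))
      if (any(isDel)) {
        ref[isDel] <- if (!is.null(seqs))
          substring(seqs[[ch]], pos[isDel], pos[isDel] + len[isDel])
        else paste0(refBase[isDel], .randomString(len[isDel]))
        alt[isDel] <- refBase[isDel]
      }

      cls <- rep("NONE", n)
      region <- rep(NA_character_, n)
      gene <- rep(NA_character_, n)
      coding <- isSnp & runif(n) < config@codingFraction[[lab]]
      if (any(coding)) {
        cls[coding] <- sample(c("MISSENSE", "NONSENSE", "SILENT"),
                              sum(coding), replace = TRUE,
                              prob = config@classProps[lab, ])
        region[coding] <- "exon"
        gene[coding] <- sprintf("GENE%05d",
                                sample.int(20000L, sum(coding),
                                           replace = TRUE))
      }
      plain <- isSnp & !coding
      if (any(plain))
        region[plain] <- sample(colnames(config@regionPropsSnp),
                                sum(plain), replace = TRUE,
                                prob = config@regionPropsSnp[lab, ])
      if (any(isIndel))
        region[isIndel] <- sample(colnames(config@regionPropsIndel),
                                  sum(isIndel), replace = TRUE,
                                  prob = config@regionPropsIndel[lab, ])

      ns <- pops$nSamples[p]
      nHap <- 2L * ns
      if (identical(config@freqLaw$type, "fixed")) {
        g <- matrix(rbinom(n * ns, 2L, config@freqLaw$p), n, ns)
        a <- (g >= 1L) + 0L
        b <- (g == 2L) + 0L
        altFreq <- rowSums(g) / nHap
      } else {
        hap <- .neutralHaplotypes(n, nHap)
        a <- hap[, seq(1L, nHap, by = 2L), drop = FALSE]
        b <- hap[, seq(2L, nHap, by = 2L), drop = FALSE]
        altFreq <- rowSums(hap) / nHap
      }

      siteList[[length(siteList) + 1L]] <- data.frame(
        chrom = ch, pos = pos, ref = ref, alt = alt, kind = kind,
        indelLength = len, class = cls, region = region, gene = gene,
        population = lab, popAltFreq = altFreq,
        stringsAsFactors = FALSE)
      gA[[length(gA) + 1L]] <- a
      gB[[length(gB) + 1L]] <- b
    }
  }

  allSites <- do.call(rbind, siteList)
  nAll <- nrow(allSites)
  A <- matrix(0L, nAll, nSamp)
  B <- matrix(0L, nAll, nSamp)
  row0 <- 0L
  for (k in seq_along(siteList)) {
    rows <- row0 + seq_len(nrow(siteList[[k]]))
    cols <- popCols[[siteList[[k]]$population[1]]]
    A[rows, cols] <- gA[[k]]
    B[rows, cols] <- gB[[k]]
    row0 <- row0 + nrow(siteList[[k]])
  }

  lethalTruth <- NULL
  if (!is.null(config@lethal)) {
    le <- config@lethal
    pos <- as.integer(le$pos)
    taken <- allSites$pos[allSites$chrom == le$chrom]
    while (pos %in% taken) pos <- pos + 1L
    refBase <- if (!is.null(seqs)) substring(seqs[[le$chrom]], pos, pos)
               else sample(.BASES, 1)
    altBase <- .BASES[(match(refBase, .BASES) - 1L + sample.int(3L, 1)) %%
                        4L + 1L]
    drawn <- injectLethalLocus(le$freq, nSamp)
    allSites <- rbind(allSites, data.frame(
      chrom = le$chrom, pos = pos, ref = refBase, alt = altBase,
      kind = "SNP", indelLength = NA_integer_, class = "NONSENSE",
      region = "exon", gene = le$gene %||% "LETHAL",
      population = "shared", popAltFreq = drawn$realizedFreq,
      stringsAsFactors = FALSE))
    A <- rbind(A, matrix(0L, 1, nSamp))
    B <- rbind(B, matrix(drawn$genotypes, 1, nSamp))
    lethalTruth <- c(drawn, list(chrom = le$chrom, pos = pos,
                                 targetFreq = le$freq))
  }

  ord <- order(match(allSites$chrom, genome$name), allSites$pos)
  allSites <- allSites[ord, , drop = FALSE]
  A <- A[ord, , drop = FALSE]
  B <- B[ord, , drop = FALSE]
  nAll <- nrow(allSites)

  if (config@missingRate > 0) {
    mask <- matrix(runif(nAll * nSamp) < config@missingRate, nAll, nSamp)
    A[mask] <- NA_integer_
    B[mask] <- NA_integer_
  }

  metrics <- data.frame(
    QD = round(runif(nAll, 8, 35), 3),
    FS = round(runif(nAll, 0.5, 10), 3),
    MQ = round(runif(nAll, 55, 60), 3),
    MQRankSum = round(runif(nAll, -2, 2), 3),
    ReadPosRankSum = round(runif(nAll, -2, 2), 3),
    SOR = round(runif(nAll, 0.3, 2.5), 3))

  sites <- DataFrame(chrom = allSites$chrom, pos = allSites$pos,
                     ref = allSites$ref,
                     alt = CharacterList(as.list(allSites$alt)),
                     kind = allSites$kind,
                     indelLength = allSites$indelLength,
                     metrics,
                     class = allSites$class, region = allSites$region,
                     gene = allSites$gene)
  seqinfo <- Seqinfo(seqnames = genome$name,
                     seqlengths = genome$length)
  cohort <- VariantCohort(sites, A, B, sampleMap, seqinfo)

  realized <- do.call(rbind, lapply(pops$label, function(lab) {
    sel <- allSites$population == lab
    data.frame(population = lab,
               n_snp_sites = sum(sel & allSites$kind == "SNP"),
               n_indel_sites = sum(sel & allSites$kind != "SNP"),
               expected_snp_sites = sum(genome$length) *
                 pops$snpDensity[pops$label == lab],
               expected_indel_sites = sum(genome$length) *
                 pops$indelDensity[pops$label == lab])
  }))
  truth <- list(seed = config@seed,
                genome = genome,
                populations = pops,
                freqLaw = config@freqLaw,
                sites = allSites,
                realized = realized,
                lethal = lethalTruth)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "genome.fa")
    dna <- DNAStringSet(seqs)
    names(dna) <- genome$name
    writeXStringSet(dna, fasta, width = 70L)
    fai <- Rsamtools::indexFa(fasta)
    vcf <- file.path(dir, "cohort.vcf")
    writeCohortVcf(cohort, vcf)
    sm <- file.path(dir, "samples.tsv")
    write.table(sampleMap, sm, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    truthPath <- file.path(dir, "truth.json")
    write_json(truth[setdiff(names(truth), "sites")], truthPath,
               auto_unbox = TRUE, digits = NA, dataframe = "columns",
               null = "null")
    paths <- list(vcf = vcf, fasta = fasta, fai = as.character(fai),
                  sampleMap = sm, truth = truthPath)
  }
  list(cohort = cohort, truth = truth, paths = paths)
}
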
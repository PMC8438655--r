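.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort and write its artifacts with a manifest
#'
#' Thin wrapper over [simulateCohort()] that always writes files and
#' adds `manifest.json` with the config echo and md5 checksums of every
#' artifact (hash-stable: two runs with the same config produce the
#' same manifest).
#'
#' @param config a [SimulationConfig-class] (default
#'   [simulationConfig()]).
#' @param dir output directory.
#' @return the [simulateCohort()] result, with `paths$manifest` added.
#' @export
runSimulate <- function(config = simulationConfig(), dir) {
  res <- simulateCohort(config, dir = dir)
  files <- unlist(res$paths)
  manifest <- list(
    tool = "PopVarProfile",
    version = as.character(packageVersion("PopVarProfile")),
    seed = config@seed,
    genome = config@genome,
    populations = config@populations,
    artifacts = data.frame(file = basename(files),
                           md5 = unname(md5sum(files))))
  path <- file.path(dir, "manifest.json")
  write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  res$paths$manifest <- path
  res
}

#' Profile a cohort VCF end to end
#'
#' Runs every pipeline stage on a called multi-sample VCF: hard-filter
#' evaluation (PASS-only by default), per-sample/per-population counts,
#' per-chromosome variant rates, binned densities, functional-class
#' fractions, indel length spectra, gene-region distributions, bucketed
#' Watterson theta per population, functional-class heterozygosity,
#' recessive-lethal candidate flagging with exact HWE tests, and
#' SNP/indel sharing matrices with average-linkage dendrograms. All
#' tables are written as TSV plus one JSON report embedding the run
#' configuration; reports contain no timestamps, so identical inputs
#' and config give identical reports.
#'
#' @param vcf path to the VCF (or an existing [VariantCohort-class]).
#' @param genome path to `.fai`/chrom.sizes (or a `Seqinfo`); optional
#'   when `vcf` is a cohort carrying one.
#' @param sampleMap path to the two-column sample map (or data.frame).
#' @param outDir output directory, or `NULL` to skip writing.
#' @param passOnly drop sites failing the hard filter first (default
#'   `TRUE`).
#' @param bucketBp theta bucket size in bp (default 5e8).
#' @param binSize density bin width in bp (default 1e4).
#' @param hetClasses,hetDenominatorBp see [classHeterozygosity()].
#' @param lethalMinFreq see [flagLethalCandidates()].
#' @return (invisibly) list of all result tables plus `config`.
#' @export
runProfile <- function(vcf, genome = NULL, sampleMap = NULL,
                       outDir = NULL, passOnly = TRUE, bucketBp = 5e8,
                       binSize = 1e4,
                       hetClasses = c("MISSENSE", "NONSENSE"),
                       hetDenominatorBp = NULL, lethalMinFreq = 0.2) {
  cohort <- if (is(vcf, "VariantCohort")) vcf
            else readVcfCohort(vcf, sampleMap, genome)
  config <- list(
    vcf = if (is.character(vcf)) vcf else "<in-memory>",
    genome = if (is.character(genome)) genome else NULL,
    sampleMap = if (is.character(sampleMap)) sampleMap else NULL,
    passOnly = passOnly, bucketBp = bucketBp, binSize = binSize,
    hetClasses = hetClasses, hetDenominatorBp = hetDenominatorBp,
    lethalMinFreq = lethalMinFreq,
    version = as.character(packageVersion("PopVarProfile")))
  filt <- evaluateHardFilter(cohort)
  nFail <- sum(!filt$pass)
  if (passOnly) cohort <- cohort[filt$pass]
  if (nSites(cohort) == 0L)
    warning("no sites to profile; report will be zeroed")

  counts <- countVariants(cohort)
  samples <- cohortSamples(cohort)
  pops <- unique(sampleInfo(cohort)$population)
  hasGenome <- !is.null(genomeIndex(cohort))

  rates <- if (hasGenome)
    do.call(rbind, lapply(samples, function(s)
      perChromosomeRates(cohort, s))) else NULL
  bins <- if (hasGenome) do.call(rbind, lapply(samples, function(s) {
    do.call(rbind, lapply(names(seqlengths(genomeIndex(cohort))),
                          function(ch) {
      b <- binnedDensity(cohort, s, ch, binSize = binSize)
      data.frame(sample = s, chromosome = ch, bin = seq_along(b),
                 count = b)
    }))
  })) else NULL

  annotated <- any(cohort@sites$class != "NONE") ||
    any(!is.na(cohort@sites$region))
  classes <- regions <- het <- NULL
  if (annotated) {
    classes <- functionalClassFractions(cohort)
    regions <- do.call(rbind, lapply(samples, function(s) {
      rd <- regionDistribution(cohort, s, kind = "indel")
      data.frame(sample = s, region = names(rd), percent = unname(rd))
    }))
    het <- classHeterozygosity(cohort, classSet = hetClasses,
                               denominatorBp = hetDenominatorBp)
  } else {
    warning("no ANN annotations: class/region/heterozygosity sections ",
            "unavailable")
  }
  spectra <- do.call(rbind, lapply(samples, function(s) {
    sp <- indelLengthSpectrum(cohort, s)
    rbind(
      if (nrow(sp$insertions))
        data.frame(sample = s, kind = "insertion", sp$insertions),
      if (nrow(sp$deletions))
        data.frame(sample = s, kind = "deletion", sp$deletions))
  }))
  theta <- if (hasGenome) lapply(setNames(pops, pops), function(p)
    bucketedTheta(cohort, p, bucketBp = bucketBp)) else NULL
  hwe <- flagLethalCandidates(cohort, minFreq = lethalMinFreq)
  shares <- dendros <- NULL
  if (length(samples) >= 2 && nSites(cohort) > 0) {
    shares <- lapply(setNames(c("SNP", "indel"), c("SNP", "indel")),
                     function(k) shareMatrix(cohort, kind = k))
    # degenerate inputs (e.g. a kind with no sites) cannot be clustered
    dendros <- lapply(shares, function(s)
      if (all(is.finite(shareValues(s)))) clusterSamples(s) else NULL)
  }

  out <- list(config = config, cohort = cohort, filter = filt,
              counts = counts, rates = rates, bins = bins,
              classes = classes, spectra = spectra, regions = regions,
              theta = theta, heterozygosity = het, hweCandidates = hwe,
              shares = shares, dendrograms = dendros)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    .writeTsv(counts$samples, file.path(outDir, "counts.tsv"))
    .writeTsv(counts$populations,
              file.path(outDir, "counts_population.tsv"))
    if (!is.null(rates)) .writeTsv(rates, file.path(outDir, "rates.tsv"))
    if (!is.null(bins)) .writeTsv(bins, file.path(outDir, "bins.tsv"))
    if (!is.null(classes))
      .writeTsv(classes, file.path(outDir, "classes.tsv"))
    if (!is.null(spectra))
      .writeTsv(spectra, file.path(outDir, "spectra.tsv"))
    if (!is.null(regions))
      .writeTsv(regions, file.path(outDir, "regions.tsv"))
    if (!is.null(theta))
      .writeTsv(do.call(rbind, lapply(theta, `[[`, "table")),
                file.path(outDir, "theta.tsv"))
    if (!is.null(het)) {
      .writeTsv(het$samples, file.path(outDir, "het.tsv"))
      .writeTsv(het$populations, file.path(outDir, "het_population.tsv"))
    }
    .writeTsv(hwe, file.path(outDir, "hwe.tsv"))
    if (!is.null(shares)) {
      for (k in names(shares)) {
        suffix <- tolower(k)
        .writeTsv(as.data.frame(shareValues(shares[[k]], "counts")),
                  file.path(outDir, paste0("share_counts_", suffix,
                                           ".tsv")))
        .writeTsv(as.data.frame(shareValues(shares[[k]], "normalized")),
                  file.path(outDir, paste0("share_normalized_", suffix,
                                           ".tsv")))
        if (!is.null(dendros[[k]]))
          writeLines(dendros[[k]]$newick,
                     file.path(outDir, paste0("dendrogram_", suffix,
                                              ".nwk")))
      }
    }
    jsonReport <- list(
      config = config, n_sites_failed_filter = nFail,
      counts = counts,
      classes_available = annotated,
      heterozygosity = if (!is.null(het))
        c(het["populations"], denominatorBp = het$denominatorBp),
      theta = if (!is.null(theta))
        lapply(theta, function(t)
          t[c("average", "min", "max", "minChromosome",
              "maxChromosome", "nHaplotypes")]),
      hwe_candidates = hwe,
      dendrograms = if (!is.null(dendros))
        lapply(dendros, function(d) if (is.null(d)) NULL else d$newick))
    write_json(jsonReport, file.path(outDir, "report.json"),
               auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out)
}

#' Exact HWE test from three genotype counts
#'
#' Command-style helper printing the exact conditional test (two-sided
#' and one-sided heterozygote excess), the Hardy-Weinberg heterozygote
#' expectation, and the exploratory 2x2 Fisher variant.
#'
#' @inheritParams hweExactTest
#' @param quiet suppress printing.
#' @return (invisibly) list with `exact`, `excess`, `fisher`,
#'   `alleleFrequency`, `expectedHet`.
#' @export
runHwe <- function(nHomRef, nHet, nHomAlt, quiet = FALSE) {
  if (nHomRef + nHet + nHomAlt == 0)
    stop("all-zero genotype table", call. = FALSE)
  exact <- hweExactTest(nHomRef, nHet, nHomAlt)
  excess <- hweExactTest(nHomRef, nHet, nHomAlt, alternative = "excess")
  fisher <- hweFisherCrossCheck(nHomRef, nHet, nHomAlt)
  af <- alleleFrequency(nHomRef, nHet, nHomAlt)
  if (!quiet) {
    cat(sprintf("genotypes %d/%d/%d  alt allele frequency %.4f\n",
                nHomRef, nHet, nHomAlt, af))
    cat(sprintf("expected heterozygotes %.3f, observed %d (%s)\n",
                unname(exact$estimate), nHet, exact$direction))
    cat(sprintf("exact HWE test: two-sided p = %.6g, ", exact$p.value))
    cat(sprintf("het-excess p = %.6g\n", excess$p.value))
    cat(sprintf("Fisher 2x2 cross-check: p = %.6g\n", fisher$p.value))
  }
  invisible(list(exact = exact, excess = excess, fisher = fisher,
                 alleleFrequency = af,
                 expectedHet = unname(exact$estimate)))
}
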
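# Build a small VariantCohort from genotype strings ("0/1", "./.", ...)
# without touching any file; defaults give biallelic A>T SNPs on chr1.
toyCohort <- function(gts, populations = NULL, pos = NULL, ref = NULL,
                      alt = NULL, class = NULL, region = NULL,
                      gene = NULL, chrom = "chr1", chromLen = 1e6L,
                      metrics = NULL, withGenome = TRUE) {
  gts <- as.matrix(gts)
  n <- nrow(gts)
  samples <- colnames(gts)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(gts)))
  if (is.null(populations))
    populations <- setNames(rep("P1", length(samples)), samples)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  splitGt <- function(g, which) {
    out <- suppressWarnings(as.integer(vapply(
      strsplit(g, "[/|]"), `[`, character(1), which)))
    out
  }
  A <- matrix(splitGt(as.character(gts), 1L), nrow = n)
  B <- matrix(splitGt(as.character(gts), 2L), nrow = n)
  chrom <- rep_len(chrom, n)
  kind <- classifyVariant(ref, alt)
  sites <- S4Vectors::DataFrame(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    alt = IRanges::CharacterList(as.list(alt)), kind = kind,
    indelLength = ifelse(kind %in% c("insertion", "deletion"),
                         abs(nchar(alt) - nchar(ref)), NA_integer_))
  if (!is.null(metrics)) for (m in names(metrics)) sites[[m]] <- metrics[[m]]
  if (!is.null(class)) sites$class <- class
  if (!is.null(region)) sites$region <- region
  if (!is.null(gene)) sites$gene <- gene
  genome <- if (withGenome)
    GenomeInfoDb::Seqinfo(seqnames = unique(chrom),
                          seqlengths = rep(chromLen,
                                           length(unique(chrom))))
  else NULL
  VariantCohort(sites, A, B,
                data.frame(sample = samples,
                           population = unname(populations[samples])),
                genome)
}

# small two-population config for fast simulations
fastConfig <- function(seed, lenPerChrom = 100000L, nChrom = 2L, ...) {
  simulationConfig(
    seed = seed,
    genome = data.frame(name = paste0("chr", seq_len(nChrom)),
                        length = rep(lenPerChrom, nChrom)),
    ...)
}
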
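#' @importClassesFrom GenomeInfoDb Seqinfo
setClassUnion("SeqinfoOrNULL", c("Seqinfo", "NULL"))

# canonical factor levels used throughout
.CLASS_LEVELS <- c("MISSENSE", "NONSENSE", "SILENT", "NONE")
.REGION_LEVELS <- c("intergenic", "intron", "exon", "utr5", "utr3",
                    "upstream", "downstream", "splice_donor",
                    "splice_acceptor", "other")
.KIND_LEVELS <- c("SNP", "insertion", "deletion", "other")
.METRIC_NAMES <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")

#' VariantCohort: a multi-sample variant table with genotypes
#'
#' Central container of the package. Holds one row per VCF site
#' (multi-allelic sites stay single rows), two parallel integer
#' matrices of per-sample allele indices (0 = reference, `NA` =
#' missing), a sample-to-population map, and optionally the genome
#' index (a [GenomeInfoDb::Seqinfo]) the coordinates live on.
#'
#' @slot sites a [S4Vectors::DataFrame] with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (a [IRanges::CharacterList], one or more
#'   alternate alleles), `kind` (`"SNP"`, `"insertion"`, `"deletion"`,
#'   `"other"`), `indelLength`, the six GATK site metrics (`QD`, `FS`,
#'   `MQ`, `MQRankSum`, `ReadPosRankSum`, `SOR`; `NA` = absent), and
#'   the parsed annotation summary `class`, `region`, `gene`.
#' @slot alleleA,alleleB integer matrices (sites x samples) holding the
#'   two allele indices of each diploid genotype; `NA` for missing.
#' @slot sampleMap data.frame with columns `sample`, `population`.
#' @slot genome a `Seqinfo` with chromosome names/lengths, or `NULL`.
#'
#' @seealso [readVcfCohort()], [simulateCohort()], [variantSites()],
#'   [sampleInfo()], [genomeIndex()]
#' @exportClass VariantCohort
setClass("VariantCohort",
  slots = c(sites = "DataFrame",
            alleleA = "matrix",
            alleleB = "matrix",
            sampleMap = "data.frame",
            genome = "SeqinfoOrNULL"))

setValidity("VariantCohort", function(object) {
  s <- object@sites
  n <- nrow(s)
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "kind")
  if (!all(need %in% colnames(s)))
    return(paste("sites must contain columns:", paste(need, collapse = ", ")))
  if (nrow(object@alleleA) != n || nrow(object@alleleB) != n)
    msg <- c(msg, "allele matrices must have one row per site")
  if (!identical(colnames(object@alleleA), object@sampleMap$sample) ||
      !identical(colnames(object@alleleB), object@sampleMap$sample))
    msg <- c(msg, "allele matrix columns must match sampleMap$sample")
  if (anyDuplicated(object@sampleMap$sample))
    msg <- c(msg, "duplicate sample names")
  if (n > 0) {
    if (any(s$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    if (any(nchar(s$ref) == 0L)) msg <- c(msg, "empty REF allele")
    if (!all(s$kind %in% .KIND_LEVELS))
      msg <- c(msg, "invalid variant kind")
    nAlt <- lengths(s$alt)
    if (any(nAlt == 0L)) msg <- c(msg, "site without ALT allele")
    mx <- pmax(suppressWarnings(apply(object@alleleA, 1, max, na.rm = TRUE)),
               suppressWarnings(apply(object@alleleB, 1, max, na.rm = TRUE)))
    mx[!is.finite(mx)] <- 0
    if (any(mx > nAlt))
      msg <- c(msg, "genotype allele index exceeds number of ALT alleles")
    if (!is.null(object@genome)) {
      sl <- seqlengths(object@genome)
      if (!all(s$chrom %in% names(sl)))
        msg <- c(msg, "site chromosome missing from genome index")
      else if (any(s$pos > sl[s$chrom]))
        msg <- c(msg, "position beyond chromosome length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantCohort
#'
#' @param sites site table (see [VariantCohort-class]); missing optional
#'   columns (metrics, `class`, `region`, `gene`, `indelLength`) are
#'   filled with `NA`.
#' @param alleleA,alleleB integer matrices of allele indices.
#' @param sampleMap data.frame with `sample` and `population` columns.
#' @param genome optional `Seqinfo` (or `NULL`).
#' @return a validated [VariantCohort-class] object.
#' @export
VariantCohort <- function(sites, alleleA, alleleB, sampleMap, genome = NULL) {
  sites <- DataFrame(sites)
  n <- nrow(sites)
  if (!is(sites$alt, "CharacterList"))
    sites$alt <- CharacterList(as.list(sites$alt))
  for (m in .METRIC_NAMES)
    if (is.null(sites[[m]])) sites[[m]] <- rep(NA_real_, n)
  if (is.null(sites$class)) sites$class <- rep("NONE", n)
  if (is.null(sites$region)) sites$region <- rep(NA_character_, n)
  if (is.null(sites$gene)) sites$gene <- rep(NA_character_, n)
  if (is.null(sites$indelLength)) sites$indelLength <- rep(NA_integer_, n)
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  sampleMap <- data.frame(sample = as.character(sampleMap$sample),
                          population = as.character(sampleMap$population),
                          stringsAsFactors = FALSE)
  colnames(alleleA) <- sampleMap$sample
  colnames(alleleB) <- sampleMap$sample
  new("VariantCohort", sites = sites, alleleA = alleleA, alleleB = alleleB,
      sampleMap = sampleMap, genome = genome)
}

#' @describeIn VariantCohort-class number of variant sites
#' @param x,object a `VariantCohort`
#' @export
nSites <- function(x) nrow(.assertCohort(x)@sites)

#' Accessors for VariantCohort
#'
#' `variantSites()` returns the site table, `sampleInfo()` the
#' sample-to-population map, `cohortSamples()` the sample names,
#' `genomeIndex()` the `Seqinfo` (or `NULL`), and `alleleCalls()` the
#' two allele-index matrices.
#'
#' @param x a [VariantCohort-class]
#' @return see individual descriptions.
#' @export
variantSites <- function(x) .assertCohort(x)@sites

#' @rdname variantSites
#' @export
sampleInfo <- function(x) .assertCohort(x)@sampleMap

#' @rdname variantSites
#' @export
cohortSamples <- function(x) .assertCohort(x)@sampleMap$sample

#' @rdname variantSites
#' @export
genomeIndex <- function(x) .assertCohort(x)@genome

#' @rdname variantSites
#' @export
alleleCalls <- function(x) {
  .assertCohort(x)
  list(A = x@alleleA, B = x@alleleB)
}

setMethod("show", "VariantCohort", function(object) {
  k <- table(factor(object@sites$kind, levels = .KIND_LEVELS))
  cat("VariantCohort with", nrow(object@sites), "sites and",
      nrow(object@sampleMap), "samples\n")
  cat("  kinds:", paste(names(k), k, sep = "=", collapse = " "), "\n")
  cat("  populations:",
      paste(names(table(object@sampleMap$population)),
            table(object@sampleMap$population), sep = "=", collapse = " "),
      "\n")
  if (!is.null(object@genome))
    cat("  genome:", length(seqlengths(object@genome)), "chromosomes,",
        sum(as.numeric(seqlengths(object@genome))), "bp\n")
})

#' @describeIn VariantCohort-class subset sites (`i`) and/or samples (`j`)
#' @param i,j,...,drop site / sample subscripts (standard matrix rules)
#' @export
setMethod("[", "VariantCohort", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@sites))
  if (missing(j)) j <- seq_len(nrow(x@sampleMap))
  if (is.character(j)) j <- match(j, x@sampleMap$sample)
  new("VariantCohort",
      sites = x@sites[i, , drop = FALSE],
      alleleA = x@alleleA[i, j, drop = FALSE],
      alleleB = x@alleleB[i, j, drop = FALSE],
      sampleMap = x@sampleMap[j, , drop = FALSE],
      genome = x@genome)
})

#' ShareMatrix: pairwise matched-polymorphism counts
#'
#' Square matrix of matched polymorphism counts between samples
#' (diagonal = each sample's own count) together with the normalized
#' share matrix and the per-population normalization constants.
#'
#' @slot counts integer matrix of matched counts, samples x samples.
#' @slot normalized numeric matrix of normalized shares.
#' @slot kind `"SNP"` or `"indel"`.
#' @slot normConstants named numeric, mean count per population.
#' @slot populations named character, population of each sample.
#' @seealso [shareMatrix()], [clusterSamples()]
#' @exportClass ShareMatrix
setClass("ShareMatrix",
  slots = c(counts = "matrix", normalized = "matrix", kind = "character",
            normConstants = "numeric", populations = "character"))

setValidity("ShareMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), dim(object@normalized)))
    msg <- c(msg, "counts and normalized must have identical dimensions")
  if (!isSymmetric(unname(object@counts)))
    msg <- c(msg, "matched counts must be symmetric")
  if (any(object@counts < 0)) msg <- c(msg, "negative matched count")
  if (!identical(colnames(object@counts), names(object@populations)))
    msg <- c(msg, "population labels must be named by sample")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ShareMatrix", function(object) {
  cat("ShareMatrix (", object@kind, ") over ", ncol(object@counts),
      " samples\n", sep = "")
  cat("  normalization constants:",
      paste(names(object@normConstants),
            signif(object@normConstants, 5), sep = "=", collapse = " "), "\n")
})

#' @rdname ShareMatrix-class
#' @param x a `ShareMatrix`
#' @param what `"counts"` or `"normalized"`
#' @return the requested matrix.
#' @export
shareValues <- function(x, what = c("normalized", "counts")) {
  stopifnot(is(x, "ShareMatrix"))
  slot(x, match.arg(what))
}

#' SimulationConfig: study conditions for the synthetic cohort generator
#'
#' Created by [simulationConfig()]; see that page for the meaning and
#' defaults of every field.
#'
#' @slot seed integer RNG seed.
#' @slot genome data.frame `name`, `length` (bp).
#' @slot populations data.frame `label`, `nSamples`, `snpDensity`,
#'   `indelDensity` (per bp).
#' @slot freqLaw list: `type` (`"neutral"` or `"fixed"`), `p` (fixed law).
#' @slot classProps matrix (population x missense/nonsense/silent).
#' @slot codingFraction named numeric, fraction of SNPs given a coding class.
#' @slot regionPropsSnp,regionPropsIndel matrices (population x region).
#' @slot indelLaw list: `p`, `delBumpCenter`, `delBumpSd`, `delBumpMass`.
#' @slot lethal list (`chrom`, `pos`, `freq`, `gene`) or `NULL`.
#' @slot missingRate numeric genotype missingness rate.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(seed = "integer", genome = "data.frame",
            populations = "data.frame", freqLaw = "list",
            classProps = "matrix", codingFraction = "numeric",
            regionPropsSnp = "matrix", regionPropsIndel = "matrix",
            indelLaw = "list", lethal = "ANY", missingRate = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  g <- object@genome
  if (anyDuplicated(g$name)) msg <- c(msg, "duplicate chromosome names")
  if (any(g$length <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
  p <- object@populations
  dens <- c(p$snpDensity, p$indelDensity)
  if (any(dens <= 0 | dens >= 0.1))
    msg <- c(msg, "densities must lie in (0, 0.1) sites/bp")
  if (any(abs(rowSums(object@classProps) - 1) > 1e-6))
    msg <- c(msg, "class proportions must sum to 1 per population")
  if (any(abs(rowSums(object@regionPropsSnp) - 1) > 1e-6) ||
      any(abs(rowSums(object@regionPropsIndel) - 1) > 1e-6))
    msg <- c(msg, "region proportions must sum to 1 per population")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (!is.null(object@lethal)) {
    le <- object@lethal
    if (!(le$freq > 0 && le$freq < 0.5))
      msg <- c(msg, "lethal-locus allele frequency must be in (0, 0.5)")
    if (!le$chrom %in% g$name)
      msg <- c(msg, "lethal-locus chromosome not in genome")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", nrow(object@genome), " chromosomes, ",
      sum(object@genome$length), " bp\n", sep = "")
  for (i in seq_len(nrow(object@populations)))
    with(object@populations[i, ],
         cat(sprintf("  %s: %d samples, 1 SNP/%.0f bp, 1 indel/%.0f bp\n",
                     label, nSamples, 1 / snpDensity, 1 / indelDensity)))
  if (!is.null(object@lethal))
    cat(sprintf("  lethal locus at %s:%d (target freq %.2f)\n",
                object@lethal$chrom, object@lethal$pos, object@lethal$freq))
})
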
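#' Classify a variant by its REF/ALT allele lengths
#'
#' Single-base REF and ALT gives a SNP; a longer ALT sharing the
#' leading anchor base with REF is an insertion; a longer REF is a
#' deletion; anything else (equal multi-base lengths, or a longer ALT
#' without a shared anchor) is `"other"`.
#'
#' @param ref,alt character vectors of allele strings (recycled to a
#'   common length).
#' @return character vector in `c("SNP","insertion","deletion","other")`.
#' @examples
#' classifyVariant("A", "T")      # SNP
#' classifyVariant("A", "ATG")    # insertion (length 2)
#' classifyVariant("ATTT", "A")   # deletion (length 3)
#' @export
classifyVariant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (any(is.na(ref) | is.na(alt) | nchar(ref) == 0L | nchar(alt) == 0L))
    stop("alleles must be non-empty strings", call. = FALSE)
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- rep("other", n)
  out[nr == 1L & na == 1L] <- "SNP"
  out[na > nr & substr(alt, 1L, 1L) == substr(ref, 1L, 1L)] <- "insertion"
  out[na < nr] <- "deletion"
  out
}

# indel length in bp (NA for SNP/other)
.indelLength <- function(ref, alt, kind) {
  d <- abs(nchar(alt) - nchar(ref))
  ifelse(kind %in% c("insertion", "deletion"), as.integer(d), NA_integer_)
}

#' Read a genome index
#'
#' Reads chromosome names and lengths from a FASTA index (`.fai`, five
#' or more tab-separated columns) or a `chrom.sizes` file (two
#' whitespace-separated columns); the dialect is auto-detected from the
#' column count. Order is preserved.
#'
#' @param path path to the index file.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
readGenomeIndex <- function(path) {
  tab <- tryCatch(
    read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse genome index '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2)
    stop("genome index must have at least 2 columns", call. = FALSE)
  name <- tab[[1]]
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(is.na(len)))
    stop("non-numeric chromosome length in '", path, "'", call. = FALSE)
  if (anyDuplicated(name))
    stop("duplicate chromosome name in '", path, "'", call. = FALSE)
  if (any(len <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  Seqinfo(seqnames = name, seqlengths = as.integer(len))
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample`, `population`); a header row equal to the
#' column names is tolerated and skipped.
#'
#' @param path path to the TSV.
#' @return data.frame with `sample` and `population` columns.
#' @export
readSampleMap <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) != 2)
    stop("sample map must have exactly two columns", call. = FALSE)
  if (identical(tolower(unlist(tab[1, ])), c("sample", "population")))
    tab <- tab[-1, , drop = FALSE]
  out <- data.frame(sample = tab[[1]], population = tab[[2]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample))
    stop("duplicate sample in sample map", call. = FALSE)
  out
}

# "0/1", "0|1", "./." -> two integer columns (NA = missing)
.parseGT <- function(gt) {
  a <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1", gt)
  b <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\2", gt)
  haploid <- !grepl("[/|]", gt)
  a[haploid] <- gt[haploid]
  b[haploid] <- gt[haploid]
  bad <- !grepl("^[0-9.]+$", a) | !grepl("^[0-9.]+$", b)
  if (any(bad & !is.na(gt)))
    stop("malformed genotype string: ", gt[which(bad)[1]], call. = FALSE)
  suppress <- function(x) suppressWarnings(as.integer(x))
  list(A = suppress(a), B = suppress(b))
}

#' Read a multi-sample VCF into a VariantCohort
#'
#' Parses a VCF 4.x file (plain or bgzipped) through
#' [VariantAnnotation::readVcf()]. Multi-allelic sites are kept as
#' single records. The six GATK site metrics are taken from INFO where
#' declared (`NA` when absent, never zero), and ANN annotations are
#' parsed into a per-site functional class, gene region and gene name
#' via [parseAnnField()].
#'
#' @param path path to the VCF.
#' @param sampleMap data.frame (`sample`, `population`) or path to a
#'   two-column TSV. Every VCF sample must be mapped.
#' @param genome optional `Seqinfo` / path to `.fai` or chrom.sizes;
#'   when given, positions are validated against it.
#' @return a [VariantCohort-class].
#' @export
readVcfCohort <- function(path, sampleMap, genome = NULL) {
  if (is.character(sampleMap)) sampleMap <- readSampleMap(sampleMap)
  if (is.character(genome)) genome <- readGenomeIndex(genome)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "cohort"),
    error = function(e) stop("cannot parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  vcfSamples <- colnames(vcf)
  missingMap <- setdiff(vcfSamples, sampleMap$sample)
  if (length(missingMap))
    stop("VCF sample(s) absent from sample map: ",
         paste(missingMap, collapse = ", "), call. = FALSE)
  sampleMap <- sampleMap[match(vcfSamples, sampleMap$sample), , drop = FALSE]

  n <- nrow(vcf)
  chrom <- as.character(seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- CharacterList(lapply(VariantAnnotation::alt(vcf), as.character))
  firstAlt <- vapply(alt, `[`, character(1), 1L)
  kind <- classifyVariant(ref, firstAlt)
  info <- VariantAnnotation::info(vcf)
  metrics <- lapply(.METRIC_NAMES, function(m) {
    v <- info[[m]]
    if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
  })
  names(metrics) <- .METRIC_NAMES
  annRaw <- if (!is.null(info$ANN)) {
    vapply(info$ANN, function(x)
      if (length(x)) paste(x, collapse = ",") else NA_character_,
      character(1))
  } else rep(NA_character_, n)
  annParsed <- parseAnnField(annRaw)
  cls <- annParsed$class
  cls[is.na(cls)] <- "NONE"

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  parsed <- .parseGT(as.character(gt))
  A <- matrix(parsed$A, nrow = n, dimnames = list(NULL, vcfSamples))
  B <- matrix(parsed$B, nrow = n, dimnames = list(NULL, vcfSamples))

  sites <- DataFrame(chrom = chrom, pos = as.integer(pos), ref = ref,
                     alt = alt, kind = kind,
                     indelLength = .indelLength(ref, firstAlt, kind),
                     QD = metrics$QD, FS = metrics$FS, MQ = metrics$MQ,
                     MQRankSum = metrics$MQRankSum,
                     ReadPosRankSum = metrics$ReadPosRankSum,
                     SOR = metrics$SOR,
                     class = cls, region = annParsed$region,
                     gene = annParsed$gene)
  VariantCohort(sites, A, B, sampleMap, genome)
}

#' Write a VariantCohort as a VCF 4.2 file
#'
#' Emits a deterministic plain-text VCF: site metrics are written with
#' up to six significant digits (omitted when `NA`), and the per-site
#' class/region/gene summary is serialized as a single snpEff-style ANN
#' entry per ALT allele. Genotypes are written unphased with the two
#' allele indices in sorted order.
#'
#' @param cohort a [VariantCohort-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(cohort, path) {
  .assertCohort(cohort)
  s <- cohort@sites
  hdr <- c("##fileformat=VCFv4.2",
           "##source=PopVarProfile")
  if (!is.null(cohort@genome)) {
    sl <- seqlengths(cohort@genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl), sl))
  }
  hdr <- c(hdr,
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            .METRIC_NAMES, .METRIC_NAMES),
    paste0("##INFO=<ID=ANN,Number=.,Type=String,",
           "Description=\"Functional annotations\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", cohort@sampleMap$sample), collapse = "\t"))
  n <- nrow(s)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  metricStr <- vapply(seq_len(n), function(i) {
    vals <- vapply(.METRIC_NAMES, function(m) s[[m]][i], numeric(1))
    keep <- !is.na(vals)
    if (!any(keep)) return("")
    paste(sprintf("%s=%.6g", .METRIC_NAMES[keep], vals[keep]),
          collapse = ";")
  }, character(1))
  annStr <- vapply(seq_len(n), function(i) {
    cls <- s$class[i]
    reg <- s$region[i]
    if (is.na(reg) && identical(cls, "NONE")) return("")
    term <- if (cls %in% names(.CLASS_TERM)) .CLASS_TERM[[cls]]
            else .REGION_TERM[[if (is.na(reg)) "other" else reg]]
    gene <- if (is.na(s$gene[i])) "" else s$gene[i]
    alts <- s$alt[[i]]
    paste0("ANN=", paste(sprintf("%s|%s|%s|%s|%s|transcript|%s.t1||",
                                 alts, term, .CLASS_IMPACT[[cls]], gene,
                                 gene, gene), collapse = ","))
  }, character(1))
  info <- ifelse(nzchar(metricStr) & nzchar(annStr),
                 paste(metricStr, annStr, sep = ";"),
                 paste0(metricStr, annStr))
  info[!nzchar(info)] <- "."
  A <- cohort@alleleA
  B <- cohort@alleleB
  lo <- pmin(A, B)
  hi <- pmax(A, B)
  gtMat <- matrix(paste(lo, hi, sep = "/"), nrow = n)
  gtMat[is.na(lo) | is.na(hi)] <- "./."
  body <- paste(s$chrom, s$pos, ".", s$ref,
                vapply(s$alt, paste, character(1), collapse = ","),
                ".", ".", info, "GT",
                apply(gtMat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
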
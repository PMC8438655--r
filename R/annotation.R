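# snpEff-style ANN effect-term mapping.
#
# An ANN INFO value holds comma-separated entries of pipe-separated
# fields: Allele|Annotation|Impact|Gene_Name|Gene_ID|... . Only the
# annotation (effect) term, used for both the functional class and the
# gene region, and the gene name are consumed here. Where a record has
# several entries the first one (most severe by ANN ordering
# convention) drives class/region tallies.

.ANN_CLASS <- c(
  missense_variant      = "MISSENSE",
  stop_gained           = "NONSENSE",
  synonymous_variant    = "SILENT",
  stop_retained_variant = "SILENT")

.ANN_REGION <- c(
  missense_variant               = "exon",
  stop_gained                    = "exon",
  synonymous_variant             = "exon",
  stop_retained_variant          = "exon",
  frameshift_variant             = "exon",
  conservative_inframe_insertion = "exon",
  conservative_inframe_deletion  = "exon",
  disruptive_inframe_insertion   = "exon",
  disruptive_inframe_deletion    = "exon",
  intron_variant                 = "intron",
  intergenic_region              = "intergenic",
  "5_prime_UTR_variant"          = "utr5",
  "3_prime_UTR_variant"          = "utr3",
  upstream_gene_variant          = "upstream",
  downstream_gene_variant        = "downstream",
  splice_donor_variant           = "splice_donor",
  splice_acceptor_variant        = "splice_acceptor")

# inverse map used by the generator when writing ANN strings
.REGION_TERM <- c(
  intergenic = "intergenic_region", intron = "intron_variant",
  exon = "frameshift_variant", utr5 = "5_prime_UTR_variant",
  utr3 = "3_prime_UTR_variant", upstream = "upstream_gene_variant",
  downstream = "downstream_gene_variant",
  splice_donor = "splice_donor_variant",
  splice_acceptor = "splice_acceptor_variant", other = "sequence_feature")

.CLASS_TERM <- c(MISSENSE = "missense_variant", NONSENSE = "stop_gained",
                 SILENT = "synonymous_variant")

.CLASS_IMPACT <- c(MISSENSE = "MODERATE", NONSENSE = "HIGH",
                   SILENT = "LOW", NONE = "MODIFIER")

#' Parse an ANN annotation string
#'
#' Maps the effect term of each comma-separated ANN entry to a
#' functional class (`MISSENSE`, `NONSENSE`, `SILENT`, `NONE`) and a
#' gene region (`intergenic`, `intron`, `exon`, `utr5`, `utr3`,
#' `upstream`, `downstream`, `splice_donor`, `splice_acceptor`,
#' `other`). Compound terms joined by `&` are resolved by their first
#' term. Unrecognized class terms map to `NONE`; unrecognized region
#' terms map to `other`.
#'
#' @param ann character vector of raw ANN values (`NA` allowed).
#' @return a data.frame with one row per input: `class`, `region`,
#'   `gene` of the *first* entry, plus a list column `entries` with the
#'   per-entry parse.
#' @export
parseAnnField <- function(ann) {
  one <- function(a) {
    if (is.na(a) || !nzchar(a))
      return(data.frame(class = NA_character_, region = NA_character_,
                        gene = NA_character_))
    entries <- strsplit(a, ",", fixed = TRUE)[[1]]
    fields <- strsplit(entries, "|", fixed = TRUE)
    term <- vapply(fields, function(f)
      strsplit(f[2], "&", fixed = TRUE)[[1]][1], character(1))
    gene <- vapply(fields, function(f)
      if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_,
      character(1))
    cls <- unname(.ANN_CLASS[term])
    cls[is.na(cls)] <- "NONE"
    reg <- unname(.ANN_REGION[term])
    reg[is.na(reg)] <- "other"
    data.frame(class = cls, region = reg, gene = gene)
  }
  parsed <- lapply(ann, one)
  out <- do.call(rbind, lapply(parsed, function(p) p[1, , drop = FALSE]))
  rownames(out) <- NULL
  out$entries <- parsed
  out
}
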
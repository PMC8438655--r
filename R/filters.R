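# GATK-style hard-filter expressions on site metrics.
#
# SNPs fail when any of
#   QD < 2.0 | FS > 60.0 | MQ < 40.0 | MQRankSum < -12.5 |
#   ReadPosRankSum < -8.0 | SOR > 3.0
# holds; indels (and "other" records, by documented decision) when any of
#   QD < 2.0 | FS > 200.0 | ReadPosRankSum < -20.0 | SOR > 10.0
# holds. An absent metric never triggers its clause.

.SNP_CLAUSES <- list(
  "QD<2.0"              = function(m) m$QD < 2.0,
  "FS>60.0"             = function(m) m$FS > 60.0,
  "MQ<40.0"             = function(m) m$MQ < 40.0,
  "MQRankSum<-12.5"     = function(m) m$MQRankSum < -12.5,
  "ReadPosRankSum<-8.0" = function(m) m$ReadPosRankSum < -8.0,
  "SOR>3.0"             = function(m) m$SOR > 3.0)

.INDEL_CLAUSES <- list(
  "QD<2.0"               = function(m) m$QD < 2.0,
  "FS>200.0"             = function(m) m$FS > 200.0,
  "ReadPosRankSum<-20.0" = function(m) m$ReadPosRankSum < -20.0,
  "SOR>10.0"             = function(m) m$SOR > 10.0)

#' Evaluate the hard-filter expressions on every site
#'
#' Applies the kind-appropriate filter expression (SNP vs indel; kind
#' `"other"` is filtered under the indel expression) to each site's
#' metrics. A record fails iff any clause is true; an absent (`NA`)
#' metric makes its clause false.
#'
#' @param cohort a [VariantCohort-class].
#' @return a [S4Vectors::DataFrame] with logical `pass` and a
#'   [IRanges::CharacterList] `failed` naming each true clause.
#' @seealso [applyHardFilter()]
#' @export
evaluateHardFilter <- function(cohort) {
  .assertCohort(cohort)
  s <- cohort@sites
  n <- nrow(s)
  m <- as.list(s[, .METRIC_NAMES, drop = FALSE])
  isSnp <- s$kind == "SNP"
  failed <- vector("list", n)
  for (i in seq_len(n)) failed[[i]] <- character(0)
  for (set in list(list(idx = isSnp, clauses = .SNP_CLAUSES),
                   list(idx = !isSnp, clauses = .INDEL_CLAUSES))) {
    for (nm in names(set$clauses)) {
      hit <- set$clauses[[nm]](m)
      hit[is.na(hit)] <- FALSE
      hit <- hit & set$idx
      for (i in which(hit)) failed[[i]] <- c(failed[[i]], nm)
    }
  }
  DataFrame(pass = lengths(failed) == 0L, failed = CharacterList(failed))
}

#' Remove sites failing the hard filter
#'
#' @param cohort a [VariantCohort-class].
#' @return the cohort restricted to passing sites.
#' @export
applyHardFilter <- function(cohort) {
  cohort[evaluateHardFilter(cohort)$pass]
}
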
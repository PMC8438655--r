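# carriage matrix for one alternate-allele index (sites x samples)
.carriageByAlt <- function(cohort, k) {
  (!is.na(cohort@alleleA) & cohort@alleleA == k) |
    (!is.na(cohort@alleleB) & cohort@alleleB == k)
}

#' Matched polymorphisms between two samples
#'
#' Number of sites of the given kind where both samples carry at least
#' one copy of the *same* alternate allele. `matchCount(i, i)` is the
#' sample's own count.
#'
#' @param cohort a [VariantCohort-class].
#' @param sampleI,sampleJ sample names.
#' @param kind `"SNP"` (default) or `"indel"`.
#' @return integer matched-site count.
#' @export
matchCount <- function(cohort, sampleI, sampleJ, kind = c("SNP", "indel")) {
  .assertCohort(cohort)
  .assertSample(cohort, c(sampleI, sampleJ))
  kind <- match.arg(kind)
  kinds <- if (kind == "indel") c("insertion", "deletion") else "SNP"
  sel <- cohort@sites$kind %in% kinds
  gather <- function(sm) {
    a <- cohort@alleleA[sel, sm]
    b <- cohort@alleleB[sel, sm]
    a[is.na(a)] <- 0L
    b[is.na(b)] <- 0L
    cbind(a, b)
  }
  gi <- gather(sampleI)
  gj <- gather(sampleJ)
  shared <- (gi[, 1] > 0 & (gi[, 1] == gj[, 1] | gi[, 1] == gj[, 2])) |
            (gi[, 2] > 0 & (gi[, 2] == gj[, 1] | gi[, 2] == gj[, 2]))
  sum(shared)
}

#' Normalize a matched count
#'
#' @param match matched-site count(s).
#' @param normConstant positive normalization constant (a population
#'   mean count).
#' @return `match / normConstant`.
#' @export
normalizedShare <- function(match, normConstant) {
  if (any(normConstant <= 0))
    stop("normalization constant must be > 0", call. = FALSE)
  match / normConstant
}

#' Pairwise polymorphism-sharing matrix
#'
#' Matched counts for every sample pair (shared carriage of the same
#' alternate allele), normalized within populations by that
#' population's mean count and across populations by the geometric
#' mean of the two population means (`crossRule = "geometric"`; the
#' alternatives use the overall mean or leave cross pairs
#' unnormalized as `NA`).
#'
#' @param cohort a [VariantCohort-class] with >= 2 samples.
#' @param kind `"SNP"` (default) or `"indel"`.
#' @param crossRule cross-population normalization rule.
#' @return a [ShareMatrix-class].
#' @export
shareMatrix <- function(cohort, kind = c("SNP", "indel"),
                        crossRule = c("geometric", "overall", "none")) {
  .assertCohort(cohort)
  kind <- match.arg(kind)
  crossRule <- match.arg(crossRule)
  if (nrow(cohort@sampleMap) < 2)
    stop("need at least two samples", call. = FALSE)
  kinds <- if (kind == "indel") c("insertion", "deletion") else "SNP"
  sub <- cohort[cohort@sites$kind %in% kinds]
  nAltMax <- if (nSites(sub)) max(lengths(sub@sites$alt)) else 1L
  samples <- sub@sampleMap$sample
  M <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  # inclusion-exclusion over alternate-allele subsets: a site matches a
  # pair when they share carriage of at least one alt allele
  carr <- lapply(seq_len(nAltMax), function(k) {
    ck <- .carriageByAlt(sub, k)
    storage.mode(ck) <- "numeric"
    ck
  })
  for (sz in seq_len(nAltMax)) {
    for (combo in asplit(utils::combn(nAltMax, sz), 2)) {
      conj <- Reduce(`*`, carr[combo])
      M <- M + (-1)^(sz + 1) * crossprod(conj)
    }
  }
  pops <- setNames(sub@sampleMap$population, samples)
  own <- diag(M)
  popMeans <- vapply(unique(pops), function(p) mean(own[pops == p]),
                     numeric(1))
  if (any(popMeans == 0))
    warning("population with zero mean count; normalized shares ",
            "undefined for its pairs")
  onePop <- table(pops)
  if (any(onePop == 1))
    warning("single-sample population(s): ",
            paste(names(onePop)[onePop == 1], collapse = ", "))
  N <- matrix(NA_real_, length(samples), length(samples),
              dimnames = dimnames(M))
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    pi <- pops[i]; pj <- pops[j]
    const <- if (pi == pj) popMeans[[pi]]
      else switch(crossRule,
                  geometric = sqrt(popMeans[[pi]] * popMeans[[pj]]),
                  overall = mean(own),
                  none = NA_real_)
    if (!is.na(const) && const > 0) N[i, j] <- M[i, j] / const
  }
  new("ShareMatrix", counts = M, normalized = N, kind = kind,
      normConstants = popMeans, populations = pops)
}

#' Cluster samples from a sharing matrix
#'
#' Agglomerative average-linkage clustering on the distance
#' `1 - normalized share` (clamped at zero). Samples are pre-sorted by
#' name so ties break deterministically regardless of input order.
#'
#' @param share a [ShareMatrix-class], or a symmetric normalized-share
#'   matrix with sample dimnames.
#' @return list: `hclust` (the merge tree), `phylo` (an [ape::as.phylo]
#'   rooted tree), `newick` (Newick string with branch lengths).
#' @export
clusterSamples <- function(share) {
  N <- if (is(share, "ShareMatrix")) share@normalized else as.matrix(share)
  if (any(!is.finite(N)))
    stop("non-finite distances; use a complete normalized matrix",
         call. = FALSE)
  ord <- order(colnames(N))
  N <- N[ord, ord]
  D <- 1 - N
  D[D < 0] <- 0
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph))
}

#' Top bipartition of a sample dendrogram
#'
#' @param cluster result of [clusterSamples()] (or an `hclust`).
#' @return named integer membership vector from cutting the tree into
#'   two clusters.
#' @export
topBipartition <- function(cluster) {
  hc <- if (inherits(cluster, "hclust")) cluster else cluster$hclust
  cutree(hc, k = 2)
}
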
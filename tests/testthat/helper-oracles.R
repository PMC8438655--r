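# Independent brute-force oracle for the exact conditional HWE test:
# direct log-gamma evaluation of n! 2^h / (nAA! h! naa!) over every
# heterozygote count compatible with the allele counts, normalized.
hweOracleDist <- function(n, nRare) {
  nCommon <- 2 * n - nRare
  h <- seq(nRare %% 2, nRare, by = 2)
  logw <- lfactorial(n) - lfactorial((nRare - h) / 2) - lfactorial(h) -
    lfactorial((nCommon - h) / 2) + h * log(2)
  w <- exp(logw - max(logw))
  data.frame(h = h, prob = w / sum(w))
}

hweOracleP <- function(nHomRef, nHet, nHomAlt,
                       alternative = "two.sided") {
  n <- nHomRef + nHet + nHomAlt
  nAlt <- 2 * nHomAlt + nHet
  nRare <- min(nAlt, 2 * n - nAlt)
  if (nRare == 0) return(1)
  d <- hweOracleDist(n, nRare)
  pObs <- d$prob[d$h == nHet]
  switch(alternative,
         two.sided = min(1, sum(d$prob[d$prob <= pObs * (1 + 1e-9)])),
         excess = min(1, sum(d$prob[d$h >= nHet])),
         deficit = min(1, sum(d$prob[d$h <= nHet])))
}

# naive clause-by-clause re-evaluation of the hard filter on a single
# metric vector (independent of the vectorized implementation)
naiveHardFilter <- function(kind, m) {
  clause <- function(val, op, thr) {
    if (is.na(val)) return(FALSE)
    if (op == "<") val < thr else val > thr
  }
  if (kind == "SNP") {
    fails <- c(clause(m[["QD"]], "<", 2), clause(m[["FS"]], ">", 60),
               clause(m[["MQ"]], "<", 40),
               clause(m[["MQRankSum"]], "<", -12.5),
               clause(m[["ReadPosRankSum"]], "<", -8),
               clause(m[["SOR"]], ">", 3))
  } else {
    fails <- c(clause(m[["QD"]], "<", 2), clause(m[["FS"]], ">", 200),
               clause(m[["ReadPosRankSum"]], "<", -20),
               clause(m[["SOR"]], ">", 10))
  }
  !any(fails)
}
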
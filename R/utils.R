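# internal numerics shared across modules

# Watterson's a_n: (n-1)-th harmonic number over n haplotypes
.wattersonA <- function(nHaplotypes) {
  stopifnot(nHaplotypes >= 2)
  sum(1 / seq_len(nHaplotypes - 1))
}

# nearest integer, ties away from zero (rates are reported this way)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# run `expr` under a locally seeded RNG stream, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assertCohort <- function(x) {
  if (!is(x, "VariantCohort"))
    stop("expected a VariantCohort object", call. = FALSE)
  invisible(x)
}

.assertSample <- function(cohort, sample) {
  bad <- setdiff(sample, cohortSamples(cohort))
  if (length(bad))
    stop("unknown sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(sample)
}
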
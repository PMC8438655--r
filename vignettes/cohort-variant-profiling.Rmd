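---
title: "Profiling genomic variation in small captive cohorts"
author: "PopVarProfile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling genomic variation in small captive cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopVarProfile)
```

## Scope and model

PopVarProfile is a downstream toolkit for jointly called multi-sample
VCFs from small, closed, genetically diverse cohorts — the motivating
case being captive outbred deer-mouse (*Peromyscus maniculatus*)
colony stocks, where two subspecies stocks (a *bairdii*-type "BW" and
a *sonoriensis*-type "SM2") differ roughly four-fold in polymorphism
density against a single reference genome. The pipeline starts from a
called VCF: alignment, duplicate marking, recalibration, variant
calling and effect prediction are out of scope. What the package owns
is everything downstream:

* **Hard-filter evaluation.** The GATK-style site-metric expressions —
  for SNPs `QD < 2.0 || FS > 60.0 || MQ < 40.0 || MQRankSum < -12.5 ||
  ReadPosRankSum < -8.0 || SOR > 3.0`, for indels `QD < 2.0 ||
  FS > 200.0 || ReadPosRankSum < -20.0 || SOR > 10.0` — re-implemented
  as a transparent evaluator that names each violated clause. A record
  fails iff *any* clause of the kind-appropriate expression holds. An
  absent metric (e.g. `MQRankSum` is undefined at sites with no
  heterozygote) never triggers its clause, mirroring how annotation
  tools leave these fields unset; records of kind `other` (equal-length
  multi-base substitutions) are judged under the indel expression.
* **Descriptive summaries.** Per-sample SNP/indel counts (a sample
  counts a site when it *carries* at least one alternate allele — a
  missing genotype never counts), bp-per-variant rates per chromosome
  and genome-wide, 10-kb binned densities, functional-class fractions
  (missense / nonsense / silent) among classified SNPs, indel length
  spectra, and gene-region distributions.
* **Diversity statistics.** Folded site-frequency spectra (the
  ancestral state of colony polymorphisms is unknown, so spectra are
  folded on the minor allele), Watterson's estimator
  `theta = S / a_n`, `a_n = sum(1/i, i = 1..n-1)` over `n` haplotypes,
  computed in genomic buckets, functional-class heterozygosity, and an
  exact conditional Hardy-Weinberg test aimed at recessive-lethal
  candidate loci.
* **Polymorphism sharing.** Pairwise matched-polymorphism counts,
  their normalization by population mean counts, and average-linkage
  clustering of the samples.
* **A synthetic cohort generator** that emulates the statistical
  structure above so that every stage is testable without any external
  download, together with a machine-readable truth set.

## Conventions and key decisions

**Coordinates and records.** Positions are 1-based inclusive as in
VCF. Multi-allelic sites stay single records; carriage of *any*
alternate allele makes a sample a carrier of the site, while the
sharing statistics require carriage of the *same* alternate allele.
Counts are of sites, not alleles. Variant kinds are decided from
allele lengths: equal single-base alleles are SNPs; a longer ALT
sharing its leading anchor base with REF is an insertion; a longer REF
is a deletion; anything else is `other`.

**ANN parsing.** Effect annotations are consumed, not computed. The
effect term of each entry maps through a fixed table
(`missense_variant -> MISSENSE`, `stop_gained -> NONSENSE`,
`synonymous_variant` / `stop_retained_variant -> SILENT`, everything
else `NONE`) and to one of ten gene regions (intergenic, intron, exon,
5'/3' UTR, upstream, downstream, splice donor/acceptor, other). Where
a record has several entries the first — most severe, by ANN ordering
convention — drives the per-site class and region, because the
summaries report one class per SNP.

**PASS-only by default.** Whether published per-sample counts use
filtered or unfiltered records is generally unstated; `runProfile()`
exposes `passOnly` and defaults to `TRUE` (counts from records that
survive the hard filter), which is the conservative reading.

**Rates.** `variantRate()` returns `length_bp / count` rounded to the
nearest integer, ties away from zero; a zero count yields `NA` rather
than an error, so empty chromosomes stay visible in the tables. The
genome-wide rate uses the sum of indexed chromosome lengths, not a
rounded headline genome size.

**Bucketed theta.** Each chromosome is split into
`ceiling(length / bucketBp)` buckets (default 5e8 bp, the scale used
for whole-genome SFS estimation of mammalian chromosomes; at desk
scale a chromosome is a single bucket and bucketed theta reduces to
plain theta). Per-bucket segregating-site counts are averaged per
chromosome before dividing by `a_n`. `n` is `2 x` population size;
at sites with missing genotypes segregation is judged on the called
alleles only. Theta works on hard genotype calls — a
genotype-likelihood treatment of low-coverage uncertainty is out of
scope.

**Heterozygosity denominator.** Published per-class heterozygosities
of order 1e-3 imply a per-bp denominator whose exact definition is
rarely stated. `classHeterozygosity()` therefore takes an explicit
`denominatorBp`; its default — the number of classified coding SNP
sites in the VCF — is the only coding-extent estimate available from
the VCF alone and is echoed in the output so reports are always
interpretable. Supply the true assessed coding length when you have
one.

**Exact HWE test.** Conditional on the observed allele counts, the
heterozygote count `h` has probability proportional to
`n! 2^h / (n_AA! h! n_aa!)`. The implementation evaluates this by the
standard upward recurrence in log space; the two-sided p-value sums
configurations no more probable than the observed one (with a 1e-9
relative tie tolerance), and one-sided versions sum the appropriate
tail. For the canonical recessive-lethal genotype table 13/24/0
(n = 37, allele frequency 0.324, expected heterozygotes 16.2) the
two-sided exact test gives p ≈ 0.006 and the one-sided heterozygote
excess test p ≈ 0.0034. Colony screens sometimes quote a "Fisher's
exact test" of HWE without stating its construction, and ad hoc 2x2
constructions give noticeably different values (the bundled
`hweFisherCrossCheck()`, observed vs expected homozygote-mutant
presence, gives p ≈ 0.11 on the same table); the package reports the
exact conditional test as the primary statistic and the 2x2 variant
only as an explicitly labelled cross-check, forcing neither to match
any particular published number.

**Sharing and clustering.** "Matched" means shared carriage of the
same alternate allele at the same site — the weakest matching
consistent with counting shared polymorphisms between sample
pairings; genotype equality would be stricter than the quantity of
interest. Within-population pairs are normalized by that population's
mean count; for cross-population pairs no published convention
exists, so the geometric mean of the two population means is the
default, with `overall` and `none` as configurable alternatives.
These normalized shares are ratios of counts, not Pearson
correlations, although figures of this kind are often labelled
"correlation". Clustering uses distance `1 - normalized share`
(clamped at zero) with average linkage; samples are pre-sorted by
name so ties break deterministically regardless of input order, and
the tree is exported as Newick with branch lengths.

## The synthetic generator: what it emulates, and what it does not

`simulationConfig()` fixes the study conditions; its defaults are the
two-stock colony structure at desk scale:

* genome: five 200-kb chromosomes (1 Mb total) — large enough for
  binning, bucketing and Poisson statistics, small enough that the
  full test suite runs in minutes;
* populations: `SM2` with 4 samples, one SNP per 55 bp and one indel
  per 311 bp; `BW` with 6 samples, one SNP per 207 bp and one indel
  per 1157 bp (the observed ~4x contrast, with the observed sample
  sizes);
* allele-frequency law: neutral-like. Each site draws a derived-allele
  count `j` in `1..2n-1` with weight `1/j` and places the `j`
  alternate alleles uniformly among the `2n` haplotype slots. This is
  exactly the Hardy-Weinberg conditional (exchangeable) law, the
  folded spectrum has expectation proportional to `1/i + 1/(2n-i)`,
  and every emitted site segregates, so a window of length `L` at SNP
  density `theta * a_n / L` has `E[S] = theta * a_n` — a closed-form
  anchor used by the estimator-recovery tests. A `fixed` law
  (Binomial(2, p) genotypes per sample) is available for
  heterozygosity calibrations;
* class proportions: silent prevails in SM2 (25/3/72% of classified
  SNPs) while missense+nonsense run higher in BW (36/4/60%); 2% of
  SNPs receive a coding class;
* region laws: indels concentrate in intergenic and intronic
  sequence, with *zero* UTR mass in BW (as observed in that stock)
  and a small UTR mass in SM2;
* indel lengths: geometric with `p = 0.35` plus a deletion-length
  bump at 180 +/- 5 bp carrying 1% of deletion mass — the transient
  deletion peak seen in real spectra;
* one recessive-lethal locus (`INSIG1`-like, exonic nonsense) with
  post-conditioning allele frequency 0.32 across the cohort. Because
  "no homozygous mutant" factorizes over individuals, the conditional
  Hardy-Weinberg law is an independent Bernoulli(`2 freq`) het
  indicator per sample (underlying unconditional frequency
  `freq / (1 - freq)`), giving the expected ~24 heterozygotes among
  37 assayed individuals; frequencies >= 0.5 are infeasible under the
  constraint and are rejected at validation.

Per chromosome, per-population site counts are Poisson(density x
length); positions are drawn distinct and *disjoint across
populations*, so each polymorphic site belongs to one source
population and the other is homozygous reference there. This yields
the block-structured sharing that drives the dendrogram separation
and keeps per-population densities exactly Poisson — at the cost of
excluding ancestrally shared polymorphism between stocks, which real
subspecies pairs do have. Site metrics are drawn inside
filter-passing ranges, reference bases come from the emitted FASTA
(uniform random sequence), and the same seed yields a byte-identical
VCF.

Deliberate non-goals of the generator: no linkage or coalescent
correlation between sites (every statistic in the pipeline is
site-wise), no sequencing-error or depth model, no BAM-level
artifacts, no cross-population shared sites. Consequently, passing
tests demonstrate correctness of the *computations* under a clean
neutral-like model — they do not validate robustness to calling
artifacts, LD, or reference bias in real data (the low-diversity
stock being the reference donor visibly inflates the other stock's
apparent density in real cohorts; the generator reproduces the
contrast, not its cause).

## Numerical choices

* Rate rounding: nearest integer, ties away from zero; `|L/count -
  rate| <= 0.5` whenever `count > 0`.
* Bins: bin index `floor((pos - 1)/binSize)`,
  `ceiling(length/binSize)` bins; bin sums equal chromosome counts
  exactly.
* HWE distribution by log-space recurrence, normalized with
  log-sum-exp; equality with direct log-gamma enumeration is held to
  1e-12 over every genotype table with n <= 50.
* Degenerate inputs: empty cohorts profile to zeroed tables with
  warnings; chromosomes with zero variants get `NA` rates (never
  exceptions); monomorphic genotype tables give HWE p = 1 by
  convention; all-missing sites are skipped by the SFS; a share
  matrix with an undefined normalization (zero mean count) refuses
  clustering rather than inventing distances.
* Problem sizes in the checks are the package's own calibration:
  theta recovery uses 200 one-Mb windows with 8 haplotypes
  (`theta = 400`), lethal detection 500 conditional tables at n = 37,
  clustering separation 100 seeded cohorts of 4 + 6 samples on two
  100-kb chromosomes, and the indel law 50,000 draws.

## Known limitations

Heterozygosity comparisons across cohorts are only as good as the
shared denominator definition; the default VCF-derived denominator is
internally consistent but not comparable across differently annotated
VCFs. The sharing normalization for cross-population pairs is a
package choice, not an established convention. Theta from hard
genotype calls understates uncertainty at low coverage. The exact HWE
test assumes a biallelic locus; multi-allelic candidate loci are
collapsed to alt-carriage before testing.
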
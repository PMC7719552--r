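---
title: "Detecting parent-of-origin expression in reciprocal crosses"
author: "poeseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parent-of-origin expression in reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poeseq)
```

## The design and why it identifies imprinting

Haplodiploidy makes parent-of-origin inference unusually clean: the
drone father is haploid, so he transmits a single known allele at every
site, and a queen restricted to homozygous-alternate calls likewise
transmits a single known allele.  Crossing two subspecies in both
directions (A♀×B♂ and B♀×A♂) separates two explanations for allelic
imbalance that are confounded in a single cross:

* **parent-of-origin (imprinting-like) bias** — the same parental side
  (maternal or paternal) is favoured in *both* directions;
* **lineage (subspecies) bias** — the same genetic background is
  favoured, so the maternal proportion *flips* between directions.

Each family contributes an initial and a reciprocal colony; two
replicate families give four colonies.  Eight workers per colony (two
dominant reproductives, two subordinate reproductives, two nurses, two
foragers), each with a head and an abdomen library, yield 64 libraries,
32 per reproductive status.

## From variants to allelic counts

1. **Variant filters** (`filter_snps`): quality ≥ 20, coverage ≥ 5
   reads, ≥ 2 alternate-allele observations.  Queens are additionally
   restricted to homozygous-alternate genotypes
   (`select_queen_homalt`) — a heterozygous queen transmits an unknown
   allele and can never define an informative site.
2. **Informative SNPs** (`unique_snps`): positional set subtraction in
   both directions; a site is informative when exactly one parent
   carries the alternate allele.
3. **Alternate genomes** (`apply_snps`): single-base substitution of
   each parent's unique alleles into the reference; lengths preserved,
   idempotent.
4. **Read assignment** (`assign_reads`): exact zero-mismatch matching
   of each read against both parental genomes.  Because the genomes
   differ exactly at informative sites, a read covering one matches a
   single genome; reads matching both carry no information and are
   discarded, as are multi-locus (repeat-like) matches.  This is a
   desk-scale surrogate for a spliced aligner run with zero mismatches
   allowed: it reproduces the decisive property (a SNP-covering read
   matches exactly one parent) without external aligners, at the cost
   of ignoring splicing and base qualities — acceptable here because
   the simulator generates unspliced, error-free reads.
5. **Count filters**: SNPs with zero maternal reads in at least one
   library are removed everywhere (`drop_zero_maternal_snps`) — the
   guard against a queen site miscalled homozygous whose missing allele
   matches the drone, which would inflate paternal counts.  The gene
   universe (`gene_universe`) keeps genes with ≥ 2 surviving SNPs and
   data in every family × direction cell.  Zero paternal gene totals
   become 1 (`substitute_paternal_zero`) to avoid complete separation
   in the logistic fit; this substitution is deliberately asymmetric,
   the maternal side being handled by the SNP-level guard.

A read spanning several SNPs of one gene counts once in the gene-level
totals by default (`dedup = TRUE` in `count_by_snp`): the per-gene
model treats reads as independent trials, and counting one molecule per
covered SNP would inflate the effective sample size.  The per-SNP table
still records the read at every covered SNP, and `dedup = FALSE`
reproduces strict per-SNP aggregation, since it is not documented
whether the original per-SNP counting deduplicated reads before
modelling.

## The per-gene model

For gene counts $(m_i, p_i)$ over libraries $i$, we fit a binomial GLM
with logit link by IRLS (through `stats::glm`), with quasi-likelihood
inference:

$$\operatorname{logit} \Pr(\text{maternal})_i
  = \beta_0 + \beta_{\text{direction}} + \beta_{\text{family}}
  \ (+\ \beta_{\text{status}}),$$

* **Sum-to-zero (effects) coding.**  With effects coding the intercept
  is the grand-mean logit across factor levels, so its test is exactly
  "does this gene deviate from the expected 0.5 allelic proportion?".
  Treatment coding would instead test the proportion at the reference
  levels of direction and family, which is not the scientific question.
* **Overdispersion.**  Allelic counts are overdispersed relative to
  binomial sampling (shared regulatory state within a worker, technical
  effects).  The Pearson dispersion $\hat\varphi = X^2/\text{df}$
  scales the standard errors; the test statistic
  $\beta_0/(\mathrm{SE}_0\sqrt{\hat\varphi})$ is referred to a
  $t$ distribution on the residual degrees of freedom — standard
  quasi-likelihood practice at small df, slightly conservative relative
  to a normal reference.  No dispersion floor is applied: the estimate
  is used as-is, and in the degenerate perfect-fit case
  ($\hat\varphi = 0$) a zero coefficient is assigned p = 1, a non-zero
  one p = 0.
* **Per-status analyses.**  Reproductive and sterile workers are
  analysed separately by default (factors: direction, family), because
  the biology of worker reproduction makes distinct per-status gene
  lists the primary output; a joint fit with status as a third factor
  (`status = "joint"`) is provided since the model specification also
  admits it.  BH correction is applied within each analysis across its
  own gene universe.

## Classification

A gene is labelled from three ingredients: the BH-adjusted intercept
p-value $q$, the **conservative mean maternal proportion**, and
consistency checks.

The conservative proportion averages per-library proportions
hierarchically — libraries within tissue, tissues within worker type,
worker types within colony, colonies with equal weight — so a colony
or tissue with more surviving libraries cannot dominate the average.

* **MATERNAL**: $q < 0.05$, mean proportion $> 0.6$, and all four
  colony means $> 0.5$;
* **PATERNAL**: mirrored below 0.4 and 0.5;
* **LINEAGE_A / LINEAGE_B**: $q < 0.05$ and, after recoding the
  maternal proportion to the lineage-A allele proportion (identity in
  the initial cross, complement in the reciprocal), both direction
  means beyond the same 0.6/0.4 thresholds;
* **BIALLELIC** otherwise.

The per-colony gate operationalises "same direction of deviation in
both crosses of both families"; its exact original form is not
documented, and same-side colony means are the weakest rule that still
guarantees the bias is not driven by a single colony or direction.  The
parent and lineage conditions are mutually exclusive by construction: a
gene whose four colonies all sit above 0.5 cannot show the direction
flip that defines lineage bias.

## The synthetic-data generator

`simulate_allelic_counts` draws, per gene and library, a total allelic
depth from a negative binomial (mean `nb_mean` scaled by a log-normal
library size factor and, for designated genes, a reproductive-status
fold change; variance $\mu + \theta\mu^2$), then a maternal count from
a beta-binomial with intraclass correlation $\rho$, and finally splits
counts over the gene's SNPs by an equal-probability multinomial.
Class coding: maternal genes keep their true proportion in both
directions; lineage genes use it when their subspecies is the maternal
line and its complement otherwise; biallelic and lineage genes have
true parental proportion 0.5.  `simulate_sequences` produces the same
structure at sequence level — reference contig, non-overlapping genes,
parental VCF-style records (with planted decoys: queen heterozygous
sites, low-quality calls, sites shared by both parents), haplotypes,
and error-free fixed-length reads with per-read truth.

Defaults, chosen once as realistic desk-scale study conditions:

| parameter | default | note |
|---|---|---|
| families × directions × workers × tissues | 2 × 2 × 8 × 2 | the 64-library design, 32 per status |
| `mean_allelic_depth` (`nb_mean`) | 50 reads/gene/library | no reference value exists for per-gene allelic depth; 50 gives per-colony proportions stable enough for the consistency gate while keeping simulations fast |
| `nb_dispersion` | 0.2 | typical bulk RNA-seq biological CV² |
| `overdispersion_rho` | 0.05 | allelic intraclass correlation; inflates binomial variance ~3.5× at depth 50 |
| `maternal_prop_imprinted` | 0.9 | strong but incomplete imprinting |
| `frac_maternal/paternal/lineage` | 0.05 each | sparse true signal; remainder biallelic |
| `status_log2fc` | 2 | DE effect size for the simplified DE stage |

The generator emulates the statistical structure the inference relies
on (reciprocal design, overdispersion, depth variation, direction
flips) but **not**: sequencing error (reads are error-free, since the
zero-mismatch aligner would merely discard erroneous reads), splicing,
mapping bias toward the reference allele, PCR duplicates, lane
effects, or linkage between SNPs of a gene (the multinomial split is
exchangeable).  Passing recovery tests therefore demonstrates the
correctness of the inference machinery under the stated model, not
robustness to alignment artifacts in real data.

Worker type and tissue have no simulated effect on allelic proportion —
the downstream averaging treats them as nuisance strata — and age and
weight are standard-normal nuisance covariates consumed only by the DE
stage.  All randomness derives from one root seed with deterministic
per-gene substreams, so identical configurations reproduce identical
artifacts and any single gene can be regenerated in isolation.

### Where the zero-maternal guard runs

The SNP-level zero-maternal filter exists to counter genotyping error.
The count-level simulator has no genotyping error, and at desk-scale
depth (tens of reads per gene) the filter would mostly remove genuinely
paternal-biased genes, since a strongly paternal gene legitimately
produces maternal zeros.  `run_all` therefore applies the guard on the
read-level path (where the data passed through genotype calls) and
skips it on the count-level path.  At the sequencing depths of real
experiments (millions of reads per library) the distinction is
immaterial.

## The simplified differential-expression stage

`de_test` is deliberately *not* a DESeq2 re-implementation: it uses
median-of-ratios size factors, a per-gene method-of-moments NB
dispersion, and a Wald test on the status coefficient with family,
direction, age and weight as covariates, after removing genes with
fewer than 10 total counts, per tissue (tissues are analysed by
stratification, matching separate per-tissue analyses, rather than as
a model factor).  There is no dispersion shrinkage, no independent
filtering and no regularised transform, so count-level DE results from
pipelines with those refinements will not be numerically reproduced;
the stage exists to produce honest per-tissue gene lists for the
overlap statistics.

## Set statistics

Enrichment and overlap tests are upper-tail hypergeometric
probabilities (`stats::phyper`, computed in log-space internally by R),
BH-corrected across terms.  Background sets follow the analysis
scheme: POE genes against all genes observed in both tissues; maternal
or paternal subsets against all POE genes; up-regulated genes against
all DE genes of the tissue.  The 2×2 independence test uses the Yates
continuity correction — the convention under which a small imbalance
such as 89/74 vs 93/77 yields a statistic of exactly 0 — and the
goodness-of-fit test compares two category counts to a 50/50 split.
Reciprocal-best-hit ortholog mapping consumes precomputed tabular hit
files (best hit per query by lowest e-value, ties by score then subject
id, gated at e ≤ 10⁻³; pairs kept only when mutual), and never runs an
aligner itself.

## Numerical choices and degenerate inputs

* GLM convergence: deviance tolerance 10⁻¹², 100 iterations;
  non-converged genes are excluded from the universe with a message
  rather than reported with unreliable p-values.
* Unsorted variant input is sorted internally with a warning rather
  than rejected; indels and out-of-range positions are hard errors.
* Multi-allelic VCF rows are split into per-alternate records on read.
* Ambiguous reads (multiple exact matches) and reads containing
  non-ACGT characters are discarded, mirroring unique-mapping
  behaviour; the assignment audit preserves the invariant
  assigned + discarded = input.
* RBH tie-break (score, then lexicographic subject) makes the mapping
  invariant to input row order.
* Library-level proportions from zero-total libraries are dropped from
  the conservative average; a colony with no data at all is an error
  naming the colony.

## Problem sizes used by the test suite

The suite exercises the statistical claims at sizes chosen to finish in
a few minutes on one CPU while keeping Monte Carlo error well inside
the asserted margins: null calibration on 2 × 1,000 genes (ρ = 0 and
0.05), recovery on 20 × 500 genes at depth 50 with 10% maternal, 10%
paternal and 5% lineage truth, GLM-vs-IRLS oracle agreement on 100
random instances at 10⁻⁸ (coefficients) and 10⁻⁶ (p-values), and
exhaustive combinatorial oracles for the hypergeometric tails at
N ≤ 30.  The acceptance script (`scripts/acceptance.R`) re-runs the
same computations from scratch under a caller-supplied seed.

## Known limitations

* Exact matching is unspliced; real transcriptomes need a spliced
  zero-mismatch alignment upstream, after which the counting and
  inference stages apply unchanged to the resulting per-SNP counts.
* The universe rule conditions on observing a gene in all four
  colonies, so genes expressed in only some colonies are never tested.
* The paternal-zero substitution biases extreme maternal proportions
  slightly toward 0.5; with ≥ 2 SNPs and 32 libraries per analysis the
  effect is negligible, but it is visible at very low depth.
* Lineage calls share the intercept q-value with parent calls; a gene
  with a perfectly symmetric direction flip has β₀ ≈ 0 and will be
  reported biallelic even though its direction coefficient is large.
  This matches the conservative aim — such genes are *not*
  parent-of-origin biased — but means lineage labels are a by-product,
  not a calibrated test for subspecies bias.
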
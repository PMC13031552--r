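---
title: "Estimating inherited disease burden from ancestry-stratified allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating inherited disease burden from ancestry-stratified allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneburden)
```

## The problem

Large sequencing aggregates publish, per variant and per genetic ancestry,
an alternate allele count (AC) and a called allele number (AN). Combined
with a curated list of disease genes — each with an inheritance mode, a
disease mechanism and one or more ICD-10-style phenotype groups — and a
tiered classification of each variant's pathogenicity, these summaries
support a gene-centric, genotype-first estimate of how much Mendelian
disease predisposition a population carries: how often an individual
carries a pathogenic allele, how often a genotype compatible with disease
occurs, and how this varies across ancestries and disease groups.

`geneburden` implements that estimation pipeline end to end, and pairs it
with a synthetic-data generator so every stage can be exercised and
validated without access to the (very large) cohort downloads.

## The model

All per-gene quantities derive from the **cumulative allele frequency**

$$\mathrm{CAF} = \sum_j \mathrm{AF}_j = \sum_j \mathrm{AC}_j/\mathrm{AN}_j$$

over the gene's qualifying variants, assuming independent assortment. Under
Hardy–Weinberg equilibrium:

* **Carrier frequency** $\mathrm{CrF} = 2\,\mathrm{CAF}\,(1-\mathrm{CAF})$ —
  the fraction of individuals heterozygous for exactly one qualifying
  allele. It is symmetric about $\mathrm{CAF}=0.5$ with maximum $0.5$.
* **Biallelic frequency** $\mathrm{HomF} = \mathrm{CAF}^2$ — homozygotes
  plus compound heterozygotes in trans. For a pair of distinct alleles the
  trans term is $2\,\mathrm{AF}_i\,\mathrm{AF}_{ii}$; summed over all pairs
  plus the per-allele squares it reconstitutes $\mathrm{CAF}^2$ exactly.
* **Genetic prevalence (GP)** dispatches on inheritance: CrF for AD and
  AD/AR genes, HomF for AR genes,
  $\mathrm{CAF}(\mathrm{CAF}+1)/2$ for X-linked recessive (hemizygous males
  plus biallelic females at a 50:50 sex ratio), and
  $(1-\mathrm{CAF})\mathrm{CAF} + \mathrm{CAF}(\mathrm{CAF}+1)/2$ for
  X-linked dominant (adding heterozygous females).
* **Non-carrier likelihood** $\prod_i (1-\mathrm{CrF}_i)$ over genes.
* A reported epidemiological prevalence $rP$ implies a carrier frequency
  $r\mathrm{CrF} = 2\sqrt{rP}(1-\sqrt{rP})$, the exact inverse of the AR
  model; calculated and reported values are compared by ordinary least
  squares on the log scale.

**Counting rules.** Cumulative CrF counts each gene once regardless of
inheritance. Cumulative GP (and disease-group GP) counts one term per
inheritance *phenotype entry*: a gene with both a dominant and a recessive
phenotype contributes $2\,\mathrm{CAF}(1-\mathrm{CAF}) + \mathrm{CAF}^2$.
In the per-gene table the same AD/AR gene is reported with GP = CrF — the
most frequent single disease-compatible genotype class. Both behaviours are
implemented where they apply (`genetic_prevalence()` versus
`gp_cumulative_contribution()`); the tension between them is inherent to
the counting convention, and we surface rather than reconcile it.

**Carrier frequency for X-linked genes** uses the unchanged diploid formula.
The hemizygote excess enters only through the GP forms; this is a
documented approximation that keeps one carrier definition across the
genome.

## Pipeline rules

* **QC**: only `PASS` variants are kept; an (AC, AN) pair is usable in an
  ancestry only when $\mathrm{AN}/\mathrm{AN}_{max}$ strictly exceeds
  `min_call_fraction` (default 0.5). The denominator is the maximum
  possible called alleles — twice the cohort size for autosomes and a
  supplied value for chrX, since the cohort's sex composition is not
  inferable from summaries. A variant failing coverage in one ancestry
  still contributes to others. We read "covered in more than half of the
  individuals" as a called-allele fraction; the exact denominator choice is
  exposed as configuration because summary releases differ in what they
  report.
* **Tier sets**: three nested variant sets — P; P+LP; P+LP+VUS-H — from a
  seven-tier classification (P, LP, VUS-H, VUS-M, VUS-L, LB, B). All burden
  metrics are non-decreasing as the tier set widens.
* **Gene curation**: non-protein-coding genes and genes with undefined,
  mitochondrial, digenic or Y-linked inheritance are removed from every
  source; OMIM-style sources additionally drop repeat-expansion-only genes
  and genes without an established mechanism. Exclusions are logged, never
  silent: retained + excluded always equals the input.
* **Source merging**: union by symbol. Conflicting inheritance resolves to
  the more inclusive mode (AD vs AR, or either vs AD/AR, becomes AD/AR);
  irreconcilable conflicts keep the OMIM mode, and mechanism conflicts keep
  the OMIM mechanism flagged for review. The sources disagree rarely but
  really, so the rule must be explicit and logged.
* **Cohort averaging**: per (gene, shared ancestry) the two cohort CAFs are
  averaged arithmetically, and CrF/GP are *recomputed* from the averaged
  CAF — they are nonlinear in CAF and must not be averaged themselves. A
  gene missing from one cohort is averaged against zero by default
  (absence of evidence at passing sites) and logged; an
  observed-cohorts-only mean is available by flag.
* **Aggregation**: disease-group prevalences sum member-gene GP under the
  cumulative counting rule and are non-mutually exclusive (a gene in five
  groups contributes fully to all five). Cross-ancestry means are
  unweighted — each ancestry counts equally, by design, since the goal is a
  population-genetics summary rather than a world-population expectation.
  Absolute counts are the opposite: a global count is always the
  population-weighted sum of per-ancestry counts, never a mean prevalence
  times the total.
* **Screening**: a gene is a carrier-screening candidate in an ancestry
  when CrF strictly exceeds 1/200 (the couple-screening threshold);
  per-ancestry sets, their union and their intersection are reported.
* **Secondary findings**: burden over the flagged actionable genes, with
  per-gene reportable-variant restrictions honoured (e.g. a single
  reportable variant for the hemochromatosis gene), cumulated per ancestry
  and per actionable phenotype group.
* **Constraint**: genes are flagged constrained at LOEUF < 0.6,
  missense Z > 3.09, synonymous Z > 3.71 (all strict), and single- versus
  multi-group genes are contrasted with a two-sided Mann–Whitney rank-sum
  test — a deliberate choice of a distribution-free test for skewed,
  bounded constraint metrics.

## The synthetic-data generator

`synthetic_spec()` fixes the study conditions the generator emulates:

* inheritance mix 28.1% AD, 53.3% AR, 13.0% AD/AR, 4.5% XLR, 1.1% XLD —
  the breakdown of curated clinical panels;
* tier mix P 0.5%, LP 2.4%, VUS-H 1.8%, VUS-M 3.0%, VUS-L 68.1%, LB 23.6%,
  B 0.6% — the observed classification shares, so only ~4.7% of generated
  variants enter the widest burden tier set;
* allele frequencies log-uniform on $[10^{-6}, 10^{-2}]$ with 0.5% common
  outliers up to 0.3 — rare-disease alleles span orders of magnitude, with
  occasional common founder or low-penetrance alleles;
* Poisson(30) variants per gene (desk scale; population catalogs carry
  orders of magnitude more, which changes runtimes, not structure);
* cohorts of 100,000 individuals per ancestry (AN$_{max}$ = 200,000), with
  2% of (variant, ancestry) pairs planted at 40% coverage to exercise the
  QC filter;
* disease-group multiplicity 40% / 32% / 28% for one / two / more groups
  (capped at five here; real panels reach nine).

AC is drawn binomially from (AN, true AF); `noiseless = TRUE` sets
AN = AN$_{max}$, disables planted failures and makes AC deterministic on
the emitted rational grid, so the entire pipeline becomes an exact identity
on the recorded ground truth — the strongest possible wiring check. All
generators are bit-reproducible under the spec seed.

What the generator does **not** model: linkage disequilibrium, inbreeding,
assortative mating, selection, penetrance, and ancestry-specific allele
frequency differences (true AFs are shared across ancestries). Passing
recovery tests therefore demonstrates correctness of the estimation
arithmetic under the model's own assumptions, not robustness to the
population-genetic forces that make real cohorts deviate from
Hardy–Weinberg expectations.

## The genotype-level oracle

`simulate_genotypes()` is the brute-force check of the closed forms. It
simulates at the **haplotype** level: each haplotype carries variant $j$
independently with probability $\mathrm{AF}_j$ and is pathogenic if it
carries at least one qualifying allele; diploids have two haplotypes,
X-linked males one. This matters: simulating per-variant diploid genotypes
instead would count cis double-heterozygotes as biallelic, giving pairwise
rates of $4\,\mathrm{AF}^2$ — twice the trans (compound-het) term the
model intends — and would systematically fail the comparison. With a single
variant the haplotype carriage probability equals CAF exactly; with many
rare variants it is $1-\prod_j(1-\mathrm{AF}_j)$, within $O(\sum_{i<j}
\mathrm{AF}_i\mathrm{AF}_j)$ of CAF, far inside the 4-standard-error
tolerance used at $10^6$ individuals.

## Numerical choices

* All frequency arithmetic is double precision; algebraic identities are
  tested at $10^{-12}$–$10^{-14}$, stochastic checks at 4 binomial SEs.
* Raw CAF sums above 1 are capped at 1 with a warning — the independence
  assumption, not the data, is at fault there.
* `invert_carrier_frequency()` always takes the minor root
  ($\mathrm{CAF} \le 0.5$): reported carrier frequencies live in the
  minor-allele regime.
* "1 in x" rendering rounds half-up at display precision; stored fractions
  are never rounded. Gene-style strings use integers below 1000 and K/M
  suffixes above (one decimal while the scaled value is below 10, trailing
  `.0` dropped); group-style strings use two decimals below 10. Parsing is
  the exact inverse at display precision.
* Ranking ties break lexicographically by symbol; report generation is a
  pure function of its inputs, so reruns are byte-identical.

## Problem sizes

The bundled analyses and tests run at desk scale: 25–500 genes, Poisson(30)
variants per gene, nine ancestries, $10^6$ simulated individuals for the
oracle, and 500 genes for the binomial-sampling recovery experiment at
AN = 200,000 — sizes chosen so the full validation suite completes in
minutes while every statistical claim remains testable at its stated
tolerance. Real cohort summaries (tens of millions of variants) change
memory and runtime, not code paths.

## Known limitations

* Hardy–Weinberg and independent assortment are assumptions, not
  guarantees; inbreeding, founder structure and LD all violate them in
  real populations, in directions this package does not model.
* Penetrance is not modelled: a "disease-compatible genotype" is a
  genotype-level statement, and genes driven by low-penetrance common
  alleles will show genetic prevalences far above clinical prevalence.
* Compound-heterozygote estimates assume trans phase, which summary AC/AN
  data cannot resolve.
* Expected variant counts per individual are sums of per-gene carrier
  probabilities; interpreting $\sum_i \mathrm{CrF}_i$ as a count of carried
  variants is exact only in expectation and only gene-by-gene.
* chrX AN$_{max}$ must be supplied by the user; summaries rarely publish
  per-ancestry sex ratios.
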
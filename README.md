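# geneburden

Gene-centric estimation of inherited disease burden from
ancestry-stratified allele-frequency summaries.

## What it does, and for whom

Population sequencing aggregates publish per-variant, per-ancestry allele
counts (AC) and allele numbers (AN). For geneticists and genetic
epidemiologists, `geneburden` turns those summaries — together with a
curated disease-gene list (inheritance mode, disease mechanism, ICD-10
disease groups) and a tiered pathogenicity classification of each variant —
into population burden estimates:

- per-gene **cumulative allele frequency** (CAF = Σ AC/AN over qualifying
  variants), for three nested variant tiers: P, P+LP, P+LP+VUS-H;
- **carrier frequency** under Hardy–Weinberg equilibrium,
  CrF = 2·CAF·(1 − CAF);
- **genetic prevalence** by inheritance dispatch: CrF for AD and AD/AR
  genes, CAF² for AR genes (homozygotes plus trans compound heterozygotes,
  pairwise 2·AF_i·AF_ii), CAF·(CAF+1)/2 for X-linked recessive and
  (1 − CAF)·CAF + CAF·(CAF+1)/2 for X-linked dominant;
- cumulative per-individual burden (Σ CrF; Σ GP with one term per
  inheritance phenotype entry), the non-carrier likelihood Π(1 − CrF_i),
  disease-group prevalence tables, top-gene rankings, carrier-screening
  candidate sets (CrF > 1/200), secondary-findings reports with per-gene
  reportable-variant restrictions, and absolute affected counts via
  population-weighted scaling;
- comparison against reported epidemiological prevalences through
  rCrF = 2·√rP·(1 − √rP) and a log–log regression.

A synthetic-data generator emits cohort-style variant and gene tables with
known ground truth, and a haplotype-level genotype simulator provides a
brute-force check of every closed-form formula. See the methods vignette
(`vignettes/inherited-burden-methods.Rmd`) for the model, assumptions and
design decisions.

## Worked example

Combining two carrier-frequency estimates for one gene — say 1 in 21 for
hypomorphic and 1 in 27 for fully disease-causing alleles — means inverting
the Hardy–Weinberg carrier formula to the allele scale, summing, and
reapplying:

```r
library(geneburden)
caf <- invert_carrier_frequency(1/21) + invert_carrier_frequency(1/27)
caf                                   # 0.04328
carrier_frequency(caf)                # 0.08281
format_one_in(carrier_frequency(caf), "gene")
#> "1 in 12"
```

A small synthetic end-to-end run:

```r
sp <- synthetic_spec(n_genes = 50, seed = 42, ancestries = c("afr", "nfe"))
gs <- generate_gene_set(sp)
vt <- generate_variant_table(gs$genes, sp)
qc <- filter_variants_qc(vt$variants, an_max = 2 * sp$cohort_sizes)
b  <- compute_gene_burden(qc$variants, gs$genes, "PLP")
head(b[order(-b$CrF), ], 3)
#>   gene     inheritance ancestry tier_set n_variants     CAF    CrF     GP
#> 1 GENE0001 AD_AR       afr      PLP               3 0.00901 0.0179 0.0179
#> 2 GENE0001 AD_AR       nfe      PLP               3 0.00878 0.0174 0.0174
#> 3 GENE0013 AD_AR       nfe      PLP               1 0.00877 0.0174 0.0174
cumulative_crf(b[b$ancestry == "afr", ])   # 0.1187 carried P+LP variants
cumulative_gp(b[b$ancestry == "afr", ])    # 0.0793 disease-compatible genotypes
```

The top gene is AD/AR, so its per-gene prevalence equals its carrier
frequency (one pathogenic allele suffices for the dominant phenotype);
the cumulative GP additionally counts its recessive CAF² term. The
numbered scripts under `analysis/` run the same pipeline at larger scale —
simulation, two-cohort burden and concordance, full report, and validation
experiments — writing their tables under `results/`.

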
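#!/usr/bin/env Rscript
# Step 1 — simulate two cohort-style variant catalogs with known ground
# truth. Cohort A and cohort B share the same genes and true allele
# frequencies enter each cohort's AC/AN draws independently, mimicking two
# sequencing efforts over the same populations.

suppressPackageStartupMessages(library(geneburden))

outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec_a <- synthetic_spec(n_genes = 500, seed = 20260901)
gs <- generate_gene_set(spec_a)

vt_a <- generate_variant_table(gs$genes, spec_a)
# cohort B: same underlying truth, independent sampling noise
set.seed(20260902)
vt_b <- vt_a
for (a in spec_a$ancestries) {
  an <- vt_b$variants[[paste0("AN_", a)]]
  vt_b$variants[[paste0("AC_", a)]] <-
    stats::rbinom(nrow(vt_b$variants), an, vt_a$truth_af$true_AF)
}

write_gene_annotations(gs$genes, file.path(outdir, "genes.tsv"))
write_variant_table(vt_a$variants, file.path(outdir, "variants_cohortA.tsv"))
write_variant_table(vt_b$variants, file.path(outdir, "variants_cohortB.tsv"))
readr::write_tsv(vt_a$truth_caf, file.path(outdir, "truth_caf.tsv"))

cat("Simulated", nrow(gs$genes), "genes;",
    nrow(vt_a$variants), "variants per cohort;",
    length(spec_a$ancestries), "ancestries.\n")
cat("Tier counts (cohort A):\n")
print(table(vt_a$variants$tier))
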
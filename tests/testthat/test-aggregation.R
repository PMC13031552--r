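burden_fixture <- function() {
  # one AR gene with AFs 0.01 and 0.02 in afr; different values in nfe
  tab <- make_variant_table(c("1:1:A:G", "1:2:C:T"), c("G1", "G1"),
                            c("P", "LP"))
  tab <- set_acan(tab, "afr", ac = c(10, 20), an = c(1000, 1000))
  tab <- set_acan(tab, "nfe", ac = c(5, 5), an = c(1000, 1000))
  tab
}

test_that("per-gene burden chains CAF, CrF and GP", {
  b <- compute_gene_burden(burden_fixture(), make_gene_table("G1"), "PLP")
  afr <- b[b$ancestry == "afr", ]
  expect_equal(afr$CAF, 0.03)
  expect_equal(afr$CrF, 2 * 0.03 * 0.97)
  expect_equal(afr$GP, 9e-4)
  expect_equal(afr$n_variants, 2L)
})

test_that("genes without passing variants get zero burden", {
  b <- compute_gene_burden(burden_fixture(), make_gene_table(c("G1", "G9")),
                           "PLP")
  g9 <- b[b$gene == "G9", ]
  expect_equal(g9$CAF, c(0, 0))
  expect_equal(g9$GP, c(0, 0))
})

test_that("burden is monotone when the tier set widens", {
  genes <- make_gene_table("G1")
  tab <- burden_fixture()
  b_p <- compute_gene_burden(tab, genes, "P")
  b_plp <- compute_gene_burden(tab, genes, "PLP")
  expect_true(all(b_plp$CAF >= b_p$CAF))
  expect_true(all(b_plp$GP >= b_p$GP))
})

test_that("variants of unknown genes are skipped with a warning", {
  tab <- burden_fixture()
  expect_warning(b <- compute_gene_burden(tab, make_gene_table("G2"), "PLP"),
                 "absent from the gene set")
  expect_equal(unique(b$CAF), 0)
})

test_that("cohort averaging means CAF and recomputes CrF and GP", {
  genes <- make_gene_table("G1")
  mk <- function(caf) tibble::tibble(
    gene = "G1", inheritance = "AR", ancestry = "afr", tier_set = "PLP",
    n_variants = 1L, CAF = caf, CrF = carrier_frequency(caf),
    GP = genetic_prevalence(caf, "AR"))
  out <- average_cohorts(mk(0.01), mk(0.03), "afr")
  expect_equal(out$burden$CAF, 0.02)
  expect_equal(out$burden$CrF, 2 * 0.02 * 0.98)
  expect_equal(out$burden$GP, 4e-4)
  # identical cohorts: identity
  same <- average_cohorts(mk(0.01), mk(0.01), "afr")
  expect_equal(same$burden$CAF, 0.01)
  expect_error(average_cohorts(mk(0.01), mk(0.01), "eas"), "missing")
})

test_that("a gene absent from one cohort is averaged against zero and logged", {
  a <- tibble::tibble(gene = c("G1", "G2"), inheritance = "AR",
                      ancestry = "afr", tier_set = "PLP", n_variants = 1L,
                      CAF = c(0.02, 0.04),
                      CrF = carrier_frequency(c(0.02, 0.04)),
                      GP = genetic_prevalence(c(0.02, 0.04), "AR"))
  b <- a[1, ]
  out <- average_cohorts(a, b, "afr")
  g2 <- out$burden[out$burden$gene == "G2", ]
  expect_equal(g2$CAF, 0.02)
  expect_equal(out$imputed$gene, "G2")
  expect_equal(out$imputed$missing_from, "B")
})

test_that("concordance is 1 for identical cohorts and -1 for anti-ordered ones", {
  mk <- function(cafs) tibble::tibble(
    gene = paste0("G", seq_along(cafs)), inheritance = "AR",
    ancestry = "afr", tier_set = "PLP", n_variants = 1L, CAF = cafs,
    CrF = carrier_frequency(cafs), GP = genetic_prevalence(cafs, "AR"))
  same <- cohort_concordance(mk(c(0.01, 0.02, 0.03)), mk(c(0.01, 0.02, 0.03)))
  expect_equal(same$per_ancestry$r, 1)
  expect_equal(same$mean_r, 1)
  anti <- cohort_concordance(mk(c(1, 2, 3) * 1e-3), mk(c(3, 2, 1) * 1e-3))
  expect_equal(anti$per_ancestry$r, -1)
  flat <- cohort_concordance(mk(rep(0.01, 3)), mk(c(0.01, 0.02, 0.03)))
  expect_true(is.na(flat$per_ancestry$r))
})

test_that("log-log regression of calculated on reported CrF", {
  genes <- paste0("G", 1:10)
  crf <- seq(0.001, 0.1, length.out = 10)
  exact <- crf_regression(tibble::tibble(gene = genes, rCrF = crf),
                          tibble::tibble(gene = genes, CrF = crf))
  expect_equal(exact$R, 1)
  expect_equal(exact$slope, 1, tolerance = 1e-10)
  # constant multiplicative offset keeps R = 1 and slope 1 in log space
  off <- crf_regression(tibble::tibble(gene = genes, rCrF = crf),
                        tibble::tibble(gene = genes, CrF = 2 * crf))
  expect_equal(off$R, 1)
  expect_equal(off$slope, 1, tolerance = 1e-10)
  expect_error(crf_regression(tibble::tibble(gene = genes[1:2], rCrF = crf[1:2]),
                              tibble::tibble(gene = genes[1:2], CrF = crf[1:2])),
               "fewer than 3")
})

test_that("independent reported and calculated values give near-zero R", {
  set.seed(11)
  genes <- paste0("G", 1:1000)
  out <- crf_regression(
    tibble::tibble(gene = genes, rCrF = 10^runif(1000, -4, -1)),
    tibble::tibble(gene = genes, CrF = 10^runif(1000, -4, -1)))
  expect_lt(abs(out$R), 0.1)
})

test_that("disease-group prevalence sums members, non-exclusively", {
  genes <- make_gene_table(
    c("G1", "G2", "G3"), inheritance = c("AR", "AR", "AD_AR"),
    groups = list("eye", c("eye", "ear"), "skin"))
  burden <- tibble::tibble(
    gene = c("G1", "G2", "G3"), inheritance = genes$inheritance,
    ancestry = "afr", tier_set = "PLP", n_variants = 1L,
    CAF = c(0.1, 0.1, 0.1),
    CrF = carrier_frequency(0.1),
    GP = genetic_prevalence(c(0.1, 0.1, 0.1), genes$inheritance))
  suppressWarnings(out <- disease_group_burden(burden, genes))
  g <- out$by_ancestry
  expect_equal(g$GP[g$group == "eye"], 0.01 + 0.01)
  # multi-group gene contributes fully to both groups
  expect_equal(g$GP[g$group == "ear"], 0.01)
  # AD_AR gene contributes dominant + recessive terms to its group
  expect_equal(g$GP[g$group == "skin"], 0.18 + 0.01)
  expect_equal(g$GP[g$group == "respiratory"], 0)
  # every group total is bounded by the all-gene cumulative GP
  total <- cumulative_gp(burden)
  expect_true(all(g$GP <= total + 1e-15))
})

test_that("top-gene ranking is descending with lexicographic tie-break", {
  burden <- tibble::tibble(
    gene = c("B", "A", "C"), inheritance = "AD", ancestry = "afr",
    tier_set = "PLP", n_variants = 1L, CAF = c(0.1, 0.05, 0.15),
    CrF = c(0.2, 0.1, 0.3), GP = c(0.2, 0.1, 0.3))
  top2 <- rank_top_genes(burden, "CrF", 2)
  expect_equal(top2$gene, c("C", "B"))
  tie <- burden
  tie$CrF <- c(0.2, 0.2, 0.1)
  expect_equal(rank_top_genes(tie, "CrF", 2)$gene, c("A", "B"))
  expect_equal(nrow(rank_top_genes(burden, "CrF", 10)), 3)
  expect_error(rank_top_genes(burden, "CrF", 0), "positive")
})

test_that("screening candidacy is strict and set logic holds", {
  burden <- tibble::tibble(
    gene = rep(c("G1", "G2", "G3"), 2), inheritance = "AR",
    ancestry = rep(c("afr", "nfe"), each = 3), tier_set = "PLP",
    n_variants = 1L,
    CAF = 0.01,
    CrF = c(1 / 150, 1 / 200, 1 / 300,   # afr
            1 / 150, 1 / 150, 1 / 300),  # nfe
    GP = 0)
  out <- screening_candidates(burden)
  expect_equal(out$per_ancestry$afr, "G1")          # 1/150 qualifies
  expect_false("G2" %in% out$per_ancestry$afr)      # exactly 1/200 does not
  expect_setequal(out$per_ancestry$nfe, c("G1", "G2"))
  expect_setequal(out$union, c("G1", "G2"))
  expect_equal(out$intersection, "G1")
  for (a in names(out$per_ancestry)) {
    expect_true(all(out$intersection %in% out$per_ancestry[[a]]))
  }
})

test_that("secondary-findings report honors restrictions and counting rules", {
  tab <- make_variant_table(
    c("6:1:G:A", "6:2:G:A", "6:3:G:A", "2:1:C:T"),
    c("HFE", "HFE", "HFE", "G2"), c("P", "P", "LP", "P"))
  tab <- set_acan(tab, "afr", ac = c(10, 20, 30, 10), an = 1000)
  tab <- set_acan(tab, "nfe", ac = c(10, 20, 30, 10), an = 1000)
  genes <- dplyr::bind_rows(
    make_gene_table("HFE", inheritance = "AR", secondary_finding = TRUE,
                    sf_phenotype_group = "miscellaneous",
                    restricted = list("6:2:G:A")),
    make_gene_table("G2", inheritance = "AD", secondary_finding = TRUE,
                    sf_phenotype_group = "cardiovascular"))
  out <- secondary_findings_report(tab, genes, "PLP")
  hfe <- out$per_gene[out$per_gene$gene == "HFE" &
                        out$per_gene$ancestry == "afr", ]
  expect_equal(hfe$CAF, 0.02)  # only the restricted variant counts
  cum_afr <- out$cumulative[out$cumulative$ancestry == "afr", ]
  expect_equal(cum_afr$cumulative_CrF,
               carrier_frequency(0.02) + carrier_frequency(0.01))
  expect_equal(cum_afr$cumulative_GP, 0.02^2 + carrier_frequency(0.01))
  expect_setequal(out$by_phenotype_group$sf_phenotype_group,
                  c("miscellaneous", "cardiovascular"))
  bad <- genes
  bad$restricted_variant_ids[[1]] <- "6:999:G:A"
  expect_error(secondary_findings_report(tab, bad, "PLP"), "not present")
  none <- make_gene_table("G2", secondary_finding = FALSE)
  empty <- secondary_findings_report(tab, none, "PLP")
  expect_equal(sum(empty$cumulative$cumulative_CrF), 0)
})

test_that("population scaling weights each ancestry, never the mean", {
  cfg <- population_config(c(a1 = 100L, a2 = 100L),
                           c(a1 = 100, a2 = 300))
  expect_equal(scale_to_population(0.1, cfg, "ancestry", "a1"), 10)
  expect_equal(scale_to_population(0, cfg, "ancestry", "a2"), 0)
  global <- scale_to_population(c(a1 = 0.1, a2 = 0.3), cfg, "global")
  expect_equal(global, 10 + 90)  # not 0.2 * 400 = 80
  expect_equal(global,
               scale_to_population(0.1, cfg, "ancestry", "a1") +
                 scale_to_population(0.3, cfg, "ancestry", "a2"))
  expect_error(scale_to_population(0.1, cfg, "ancestry", "zz"), "unknown")
})

test_that("constraint flags use strict thresholds and recover planted contrast", {
  genes <- make_gene_table(
    paste0("G", 1:40),
    groups = c(rep(list("eye"), 20), rep(list(c("eye", "ear")), 20)))
  set.seed(21)
  metrics <- tibble::tibble(
    gene = genes$symbol,
    pLI = runif(40),
    LOEUF = c(runif(20, 0.8, 1.5), runif(20, 0.1, 0.5)),  # multi-group lower
    mis_z = rnorm(40), syn_z = rnorm(40))
  out <- constraint_comparison(metrics, genes)
  expect_true(out$flags$constrained_loeuf[out$flags$LOEUF == min(metrics$LOEUF)])
  row <- out$contrast[out$contrast$metric == "LOEUF", ]
  expect_equal(row$direction, "multi_lower")
  expect_lt(row$p, 0.01)
  # boundary strictness
  m2 <- tibble::tibble(gene = c("G1", "G2"), pLI = 0.5,
                       LOEUF = c(0.5, 0.6), mis_z = c(3.10, 3.09),
                       syn_z = c(3.72, 3.71))
  f2 <- constraint_comparison(m2, genes[1:2, ])$flags
  expect_equal(f2$constrained_loeuf, c(TRUE, FALSE))
  expect_equal(f2$constrained_mis, c(TRUE, FALSE))
  expect_equal(f2$constrained_syn, c(TRUE, FALSE))
  expect_error(constraint_comparison(m2[0, ], genes), "no overlap")
})

test_that("the full report is deterministic and order-invariant", {
  sp <- synthetic_spec(n_genes = 25, seed = 17, ancestries = c("afr", "nfe"))
  gs <- generate_gene_set(sp)
  vt <- generate_variant_table(gs$genes, sp)
  qc <- filter_variants_qc(vt$variants, 2 * sp$cohort_sizes)
  cfg <- population_config(sp$cohort_sizes,
                           c(afr = 1.4e9, nfe = 0.97e9))
  rep1 <- suppressWarnings(build_full_report(qc$variants, gs$genes, cfg))
  expect_true(all(c("gene_burden", "cumulative", "group_by_ancestry",
                    "top_crf", "screening_sets", "scaled_counts")
                  %in% names(rep1)))
  # permuting variant row order changes nothing
  perm <- qc$variants[rev(seq_len(nrow(qc$variants))), ]
  rep2 <- suppressWarnings(build_full_report(perm, gs$genes, cfg))
  expect_equal(rep1, rep2)
  # widening the tier set never decreases a cumulative metric
  cum <- rep1$cumulative
  for (a in unique(cum$ancestry)) {
    v <- cum[cum$ancestry == a, ]
    v <- v[match(c("P", "PLP", "PLPVH"), v$tier_set), ]
    expect_true(all(diff(v$cumulative_CrF) >= -1e-12))
    expect_true(all(diff(v$cumulative_GP) >= -1e-12))
  }
  # global scaled counts equal the sum of per-ancestry counts
  gp_vec <- with(cum[cum$tier_set == "PLP", ],
                 stats::setNames(pmin(cumulative_GP, 1), ancestry))
  expect_equal(scale_to_population(gp_vec, cfg, "global"),
               sum(rep1$scaled_counts$affected_individuals))
})
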
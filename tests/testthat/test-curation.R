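test_that("gene curation applies the retention rules and logs exclusions", {
  raw <- make_gene_table(sprintf("G%02d", 1:10))
  raw$protein_coding[1] <- FALSE
  raw$inheritance[2] <- "mitochondrial"
  raw$inheritance[3] <- "undefined"
  out <- curate_genes(raw, "PanelApp")
  expect_equal(nrow(out$genes), 7)
  expect_equal(nrow(out$excluded), 3)
  expect_setequal(out$excluded$reason,
                  c("non-protein-coding", "mitochondrial-inheritance",
                    "undefined-inheritance"))
  # no silent loss
  expect_equal(nrow(out$genes) + nrow(out$excluded), nrow(raw))
})

test_that("OMIM-only rules remove repeat-expansion-only and mechanism-less genes", {
  raw <- make_gene_table(c("A", "B", "C"))
  raw$repeat_expansion_only[2] <- TRUE
  raw$mechanism_established[3] <- FALSE
  pa <- curate_genes(raw, "PanelApp")
  expect_equal(nrow(pa$genes), 3)  # PanelApp source ignores both flags
  om <- curate_genes(raw, "OMIM")
  expect_equal(nrow(om$genes), 1)
  expect_equal(om$excluded$reason[om$excluded$symbol == "B"],
               "repeat-expansion-only")
  expect_equal(om$excluded$reason[om$excluded$symbol == "C"],
               "no-established-mechanism")
})

test_that("empty curation input yields empty output", {
  out <- curate_genes(make_gene_table(character(0)), "OMIM")
  expect_equal(nrow(out$genes), 0)
  expect_equal(nrow(out$excluded), 0)
})

test_that("merging sources unions symbols and reports overlap counts", {
  a <- make_gene_table(c("g1", "g2", "g3"), sources = list("PanelApp"))
  b <- make_gene_table(c("g2", "g3", "g4"), sources = list("OMIM"))
  m <- merge_gene_sources(a, b)
  expect_equal(nrow(m$genes), 4)
  expect_equal(m$counts$overlap, 2)
  expect_equal(m$counts$panelapp_only, 1)
  expect_equal(m$counts$omim_only, 1)
  g2 <- m$genes[m$genes$symbol == "g2", ]
  expect_setequal(g2$sources[[1]], c("PanelApp", "OMIM"))
})

test_that("inheritance conflicts resolve to the more inclusive mode", {
  a <- make_gene_table("g1", inheritance = "AD", sources = list("PanelApp"))
  b <- make_gene_table("g1", inheritance = "AD_AR", sources = list("OMIM"))
  m <- merge_gene_sources(a, b)
  expect_equal(m$genes$inheritance, "AD_AR")
  expect_equal(nrow(m$conflicts), 1)
  a2 <- make_gene_table("g1", inheritance = "AD", sources = list("PanelApp"))
  b2 <- make_gene_table("g1", inheritance = "AR", sources = list("OMIM"))
  expect_equal(merge_gene_sources(a2, b2)$genes$inheritance, "AD_AR")
})

test_that("disjoint sets merge without conflicts", {
  a <- make_gene_table(c("g1", "g2"), sources = list("PanelApp"))
  b <- make_gene_table(c("g3", "g4"), sources = list("OMIM"))
  m <- merge_gene_sources(a, b)
  expect_equal(nrow(m$genes), 4)
  expect_equal(m$counts$overlap, 0)
  expect_equal(nrow(m$conflicts), 0)
})

test_that("QC filter drops non-PASS rows and low-coverage pairs", {
  tab <- make_variant_table(sprintf("1:%d:A:G", 1:5), rep("G1", 5),
                            rep("P", 5), an = 900)
  tab$filter[1:2] <- "VQSRTrancheSNP"
  tab <- set_acan(tab, "afr", ac = c(1, 1, 1, 1, 1),
                  an = c(900, 900, 400, 900, 900))
  tab <- set_acan(tab, "nfe", ac = c(1, 1, 1, 1, 1),
                  an = c(900, 900, 350, 900, 900))
  out <- filter_variants_qc(tab, an_max = c(afr = 1000, nfe = 1000))
  expect_equal(nrow(out$variants), 2)  # row 3 unusable everywhere
  expect_equal(out$drop_counts$n[out$drop_counts$rule == "non_pass"], 2)
  expect_equal(out$drop_counts$n[out$drop_counts$rule == "no_usable_ancestry"], 1)
})

test_that("coverage is judged per ancestry, strictly above the cutoff", {
  tab <- make_variant_table("1:1:A:G", "G1", "P")
  tab <- set_acan(tab, "nfe", 1, 600)  # 0.6 of AN_max
  tab <- set_acan(tab, "afr", 1, 300)  # 0.3
  out <- filter_variants_qc(tab, an_max = c(afr = 1000, nfe = 1000))
  expect_equal(nrow(out$variants), 1)
  expect_true(is.na(out$variants$AN_afr))
  expect_equal(out$variants$AN_nfe, 600L)
  # exactly at the boundary is not retained
  tab2 <- set_acan(tab, "nfe", 1, 500)
  out2 <- filter_variants_qc(tab2, an_max = c(afr = 1000, nfe = 1000))
  expect_equal(nrow(out2$variants), 0)
})

test_that("QC filtering is idempotent and identity on clean input", {
  tab <- make_variant_table(sprintf("1:%d:A:G", 1:3), rep("G1", 3),
                            c("P", "LP", "B"), an = 1000)
  anm <- c(afr = 1000, nfe = 1000)
  once <- filter_variants_qc(tab, anm)
  expect_equal(once$variants, tab)
  twice <- filter_variants_qc(once$variants, anm)
  expect_equal(twice$variants, once$variants)
  expect_error(filter_variants_qc(tab, c(afr = 0, nfe = 1000)), "an_max = 0")
})

test_that("tier-set selection filters and is monotone under nesting", {
  tab <- make_variant_table(sprintf("1:%d:A:G", 1:4), rep("G1", 4),
                            c("P", "LP", "VUS-M", "B"))
  genes <- make_gene_table("G1")
  expect_equal(nrow(select_tier_set(tab, "PLP", genes)), 2)
  sel_p <- select_tier_set(tab, "P", genes)
  sel_plp <- select_tier_set(tab, "PLP", genes)
  sel_vh <- select_tier_set(tab, "PLPVH", genes)
  expect_true(all(sel_p$variant_id %in% sel_plp$variant_id))
  expect_true(all(sel_plp$variant_id %in% sel_vh$variant_id))
})

test_that("restricted-variant lists limit a gene to its reportable variant", {
  tab <- make_variant_table(sprintf("6:%d:G:A", 1:3), rep("HFE", 3),
                            c("P", "P", "LP"))
  genes <- make_gene_table("HFE", secondary_finding = TRUE,
                           restricted = list("6:2:G:A"))
  sel <- select_tier_set(tab, "PLP", genes, apply_restrictions = TRUE)
  expect_equal(sel$variant_id, "6:2:G:A")
  # restrictions are inert unless asked for
  expect_equal(nrow(select_tier_set(tab, "PLP", genes)), 3)
})
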
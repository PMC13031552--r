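# In-code fixtures: tiny tables with the exact column layout the readers
# and the pipeline expect. No files on disk except where a test writes one.

make_variant_table <- function(ids, genes, tiers, filter = "PASS",
                               ac = NULL, an = NULL,
                               ancestries = c("afr", "nfe")) {
  n <- length(ids)
  tab <- tibble::tibble(variant_id = ids, gene = genes,
                        tier = factor(tiers, levels = tier_levels()),
                        filter = rep_len(filter, n))
  for (a in ancestries) {
    tab[[paste0("AC_", a)]] <- as.integer(rep_len(if (is.null(ac)) 10L else ac, n))
    tab[[paste0("AN_", a)]] <- as.integer(rep_len(if (is.null(an)) 1000L else an, n))
  }
  tab
}

make_gene_table <- function(symbols, inheritance = "AR",
                            groups = list("congenital"),
                            mechanism = "LoF",
                            sources = list(c("PanelApp", "OMIM")),
                            secondary_finding = FALSE,
                            sf_phenotype_group = NA_character_,
                            restricted = NULL) {
  n <- length(symbols)
  if (!is.list(groups)) groups <- list(groups)
  tibble::tibble(
    symbol = symbols,
    protein_coding = TRUE,
    inheritance = rep_len(inheritance, n),
    mechanism = rep_len(mechanism, n),
    sources = rep_len(sources, n),
    disease_groups = rep_len(groups, n),
    repeat_expansion_only = FALSE,
    mechanism_established = TRUE,
    secondary_finding = rep_len(secondary_finding, n),
    sf_phenotype_group = rep_len(sf_phenotype_group, n),
    restricted_variant_ids = if (is.null(restricted))
      rep(list(character(0)), n) else rep_len(restricted, n))
}

# A variant table in which one ancestry column carries chosen AC/AN pairs.
set_acan <- function(tab, ancestry, ac, an) {
  tab[[paste0("AC_", ancestry)]] <- as.integer(ac)
  tab[[paste0("AN_", ancestry)]] <- as.integer(an)
  tab
}
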
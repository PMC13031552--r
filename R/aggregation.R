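#' Per-gene burden for one tier set
#'
#' For every retained gene and requested ancestry: CAF is the sum of the
#' allele frequencies (AC/AN) of the gene's tier-set variants usable in that
#' ancestry; CrF follows from Hardy-Weinberg ([carrier_frequency()]); GP
#' from the inheritance dispatch ([genetic_prevalence()], so an AD_AR gene
#' is reported with GP = CrF). Genes with no passing variants get
#' CAF = CrF = GP = 0. Variants whose gene is absent from the gene set are
#' skipped with a warning.
#'
#' @param variants QC-filtered variant tibble.
#' @param genes Gene annotation tibble (curated).
#' @param tiers Tier-set name or explicit tier vector (see
#'   [select_tier_set()]).
#' @param ancestries Ancestry codes to compute; defaults to those present in
#'   the variant table.
#' @param apply_restrictions Honor per-gene restricted variant lists.
#' @return Tibble with columns `gene`, `inheritance`, `ancestry`,
#'   `tier_set`, `n_variants`, `CAF`, `CrF`, `GP`.
#' @export
compute_gene_burden <- function(variants, genes, tiers = "PLP",
                                ancestries = NULL,
                                apply_restrictions = FALSE) {
  tier_label <- if (length(tiers) == 1 && tiers %in% tier_set_names()) tiers
                else paste(tiers, collapse = "+")
  if (is.null(ancestries)) ancestries <- variant_ancestries(variants)
  orphan <- setdiff(unique(variants$gene), genes$symbol)
  if (length(orphan) > 0) {
    warning("skipping variants of ", length(orphan),
            " gene(s) absent from the gene set: ",
            paste(utils::head(orphan, 5), collapse = ", "))
  }
  sel <- select_tier_set(variants, tiers, genes, apply_restrictions)
  out <- vector("list", length(ancestries))
  for (k in seq_along(ancestries)) {
    a <- ancestries[k]
    ac <- sel[[paste0("AC_", a)]]
    an <- sel[[paste0("AN_", a)]]
    if (is.null(ac)) stop("variant table has no AC/AN columns for ancestry ", a)
    use <- !is.na(an) & an > 0
    af <- ifelse(use, ac / an, 0)
    agg <- if (nrow(sel) == 0) {
      data.frame(gene = character(0), caf = numeric(0), n = numeric(0))
    } else {
      stats::aggregate(cbind(caf = af, n = as.numeric(use)),
                       by = list(gene = sel$gene), FUN = sum)
    }
    i <- match(genes$symbol, agg$gene)
    caf <- ifelse(is.na(i), 0, agg$caf[i])
    over <- caf > 1
    if (any(over)) {
      warning("CAF capped at 1 for gene(s): ",
              paste(genes$symbol[over], collapse = ", "))
      caf[over] <- 1
    }
    out[[k]] <- tibble::tibble(
      gene = genes$symbol,
      inheritance = genes$inheritance,
      ancestry = a,
      tier_set = tier_label,
      n_variants = as.integer(ifelse(is.na(i), 0, agg$n[i])),
      CAF = caf,
      CrF = carrier_frequency(caf),
      GP = genetic_prevalence(caf, genes$inheritance))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$ancestry, .data$gene)
}

#' Average per-gene CAF between two cohorts
#'
#' For every (gene, shared ancestry): the averaged CAF is the arithmetic
#' mean of the two cohort CAFs; CrF and GP are then recomputed from the
#' averaged CAF (they are not averaged themselves, since neither is linear
#' in CAF). A gene estimated in only one cohort is averaged against CAF = 0
#' by default — absence of evidence at passing sites — and logged; set
#' `missing_as_zero = FALSE` to instead carry the observing cohort's CAF
#' through unchanged. Ancestries not listed as shared pass through from
#' cohort A.
#'
#' @param burden_a,burden_b Gene-burden tibbles from [compute_gene_burden()]
#'   on the same gene set and tier set.
#' @param shared_ancestries Ancestry codes present in both cohorts.
#' @param missing_as_zero Treat a gene missing from one cohort as CAF 0.
#' @return List with `burden` (averaged tibble) and `imputed` (tibble of
#'   `gene`, `ancestry`, `missing_from`).
#' @export
average_cohorts <- function(burden_a, burden_b, shared_ancestries,
                            missing_as_zero = TRUE) {
  for (a in shared_ancestries) {
    if (!a %in% burden_a$ancestry) stop("ancestry ", a, " missing from cohort A")
    if (!a %in% burden_b$ancestry) stop("ancestry ", a, " missing from cohort B")
  }
  if (!all(burden_a$tier_set[1] == burden_b$tier_set[1])) {
    stop("cohorts were computed on different tier sets")
  }
  key <- function(b) paste(b$gene, b$ancestry)
  a_sh <- burden_a[burden_a$ancestry %in% shared_ancestries, , drop = FALSE]
  b_sh <- burden_b[burden_b$ancestry %in% shared_ancestries, , drop = FALSE]
  all_genes <- union(a_sh$gene, b_sh$gene)
  grid <- expand.grid(gene = all_genes, ancestry = shared_ancestries,
                      stringsAsFactors = FALSE)
  ia <- match(paste(grid$gene, grid$ancestry), key(a_sh))
  ib <- match(paste(grid$gene, grid$ancestry), key(b_sh))
  caf_a <- a_sh$CAF[ia]
  caf_b <- b_sh$CAF[ib]
  imput <- tibble::tibble(
    gene = c(grid$gene[is.na(ia)], grid$gene[is.na(ib)]),
    ancestry = c(grid$ancestry[is.na(ia)], grid$ancestry[is.na(ib)]),
    missing_from = rep(c("A", "B"), c(sum(is.na(ia)), sum(is.na(ib)))))
  if (missing_as_zero) {
    caf_a[is.na(caf_a)] <- 0
    caf_b[is.na(caf_b)] <- 0
    caf <- (caf_a + caf_b) / 2
  } else {
    caf <- rowMeans(cbind(caf_a, caf_b), na.rm = TRUE)
    caf[is.nan(caf)] <- 0
  }
  inh <- dplyr::coalesce(a_sh$inheritance[ia], b_sh$inheritance[ib])
  n_var <- pmax(dplyr::coalesce(a_sh$n_variants[ia], 0L),
                dplyr::coalesce(b_sh$n_variants[ib], 0L))
  avg <- tibble::tibble(
    gene = grid$gene, inheritance = inh, ancestry = grid$ancestry,
    tier_set = burden_a$tier_set[1], n_variants = n_var, CAF = caf,
    CrF = carrier_frequency(caf),
    GP = genetic_prevalence(caf, inh))
  rest <- burden_a[!burden_a$ancestry %in% shared_ancestries, , drop = FALSE]
  list(burden = dplyr::arrange(dplyr::bind_rows(avg, rest),
                               .data$ancestry, .data$gene),
       imputed = imput)
}

#' Concordance of per-gene CAF between two cohorts
#'
#' Correlates the per-gene CAF vectors of two cohorts within each shared
#' ancestry (Pearson by default; Spearman by flag) and reports the
#' unweighted mean across ancestries. An ancestry with fewer than 3 genes
#' having nonzero CAF in both cohorts, or with a zero-variance vector, is
#' reported as `NA`.
#'
#' @param burden_a,burden_b Gene-burden tibbles on the same tier set.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `per_ancestry` (tibble `ancestry`, `n_genes`, `r`) and
#'   `mean_r` (mean over non-missing ancestries).
#' @export
cohort_concordance <- function(burden_a, burden_b,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(unique(burden_a$ancestry), unique(burden_b$ancestry))
  rows <- lapply(shared, function(a) {
    va <- burden_a[burden_a$ancestry == a, , drop = FALSE]
    vb <- burden_b[burden_b$ancestry == a, , drop = FALSE]
    genes <- intersect(va$gene, vb$gene)
    x <- va$CAF[match(genes, va$gene)]
    y <- vb$CAF[match(genes, vb$gene)]
    r <- NA_real_
    if (sum(x > 0 & y > 0) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      r <- stats::cor(x, y, method = method)
    }
    tibble::tibble(ancestry = a, n_genes = length(genes), r = r)
  })
  per <- dplyr::bind_rows(rows)
  list(per_ancestry = per, mean_r = mean(per$r, na.rm = TRUE))
}

#' Regression of calculated on reported carrier frequency
#'
#' Ordinary least squares of log(calculated CrF) on log(reported CrF) over
#' genes with both quantities positive, as used to compare the genomic
#' estimates against carrier frequencies back-calculated from reported
#' epidemiological prevalences.
#'
#' @param reported Tibble with columns `gene` and `rCrF` (or `rP`, from
#'   which rCrF is derived via [reported_crf()]).
#' @param calculated Tibble with columns `gene` and `CrF`.
#' @return List with `R` (signed correlation coefficient of the log values),
#'   `p` (two-sided p-value for the slope), `n`, `slope`, `intercept`.
#' @export
crf_regression <- function(reported, calculated) {
  if (!"rCrF" %in% names(reported)) {
    if (!"rP" %in% names(reported)) stop("reported needs an rCrF or rP column")
    reported$rCrF <- reported_crf(reported$rP)
  }
  m <- dplyr::inner_join(reported[, c("gene", "rCrF")],
                         calculated[, c("gene", "CrF")], by = "gene")
  m <- m[m$rCrF > 0 & m$CrF > 0, , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 usable gene pairs for the regression")
  fit <- stats::lm(log(CrF) ~ log(rCrF), data = m)
  sm <- summary(fit)
  list(R = stats::cor(log(m$rCrF), log(m$CrF)),
       p = sm$coefficients[2, 4],
       n = nrow(m),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Disease-group genetic prevalence table
#'
#' For each of the 13 ICD-10-based groups and each ancestry, sums the
#' genetic prevalences of member genes under the cumulative counting rule
#' (one term per inheritance phenotype entry, so an AD_AR gene contributes
#' both its dominant and recessive terms). Because gene membership is
#' many-to-many, a multi-group gene contributes fully to every group it
#' belongs to, and group prevalences are non-mutually exclusive. Also
#' returns the unweighted cross-ancestry mean per group.
#'
#' @param burden Gene-burden tibble (one row per gene x ancestry).
#' @param genes Gene annotation tibble carrying `disease_groups`.
#' @return List with `by_ancestry` (tibble `group`, `ancestry`, `GP`) and
#'   `mean` (tibble `group`, `GP`); groups with no member genes are reported
#'   as 0 with a warning.
#' @export
disease_group_burden <- function(burden, genes) {
  membership <- tidyr::unnest(genes[, c("symbol", "disease_groups")],
                              cols = "disease_groups")
  names(membership) <- c("gene", "group")
  empty <- setdiff(disease_groups(), membership$group)
  if (length(empty) > 0) {
    warning("disease group(s) with no member genes: ",
            paste(empty, collapse = ", "))
  }
  b <- burden
  b$gp_entry <- gp_cumulative_contribution(b$CAF, b$inheritance)
  joined <- dplyr::inner_join(membership, b[, c("gene", "ancestry", "gp_entry")],
                              by = "gene", relationship = "many-to-many")
  by_anc <- dplyr::summarise(
    dplyr::group_by(joined, .data$group, .data$ancestry),
    GP = sum(.data$gp_entry), .groups = "drop")
  grid <- tidyr::expand_grid(group = disease_groups(),
                             ancestry = unique(burden$ancestry))
  by_anc <- dplyr::left_join(grid, by_anc, by = c("group", "ancestry"))
  by_anc$GP[is.na(by_anc$GP)] <- 0
  mean_tab <- dplyr::summarise(dplyr::group_by(by_anc, .data$group),
                               GP = mean(.data$GP), .groups = "drop")
  mean_tab <- mean_tab[match(disease_groups(), mean_tab$group), , drop = FALSE]
  list(by_ancestry = by_anc, mean = mean_tab)
}

#' Top genes by a burden metric
#'
#' Per-ancestry ranking in descending metric order; ties are broken by gene
#' symbol lexicographically for determinism.
#'
#' @param burden Gene-burden tibble.
#' @param metric `"CrF"` or `"GP"`.
#' @param n Number of genes to keep per ancestry (positive).
#' @return Tibble of the top rows per ancestry, with a `rank` column.
#' @export
rank_top_genes <- function(burden, metric = c("CrF", "GP"), n = 30) {
  metric <- match.arg(metric)
  if (n <= 0) stop("n must be positive")
  ord <- burden[order(burden$ancestry, -burden[[metric]], burden$gene), ,
                drop = FALSE]
  out <- dplyr::slice_head(dplyr::group_by(ord, .data$ancestry), n = n)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  dplyr::ungroup(out)
}

#' Carrier-screening candidate genes
#'
#' A gene qualifies for screening in an ancestry when its carrier frequency
#' strictly exceeds the threshold (default 1/200, the couple-screening
#' recommendation). Returns the per-ancestry sets, their union, and the
#' genes qualifying in every ancestry.
#'
#' @param burden Gene-burden tibble (typically the P+LP tier set).
#' @param threshold Strict CrF cutoff; default `1/200`.
#' @return List with `per_ancestry` (named list of sorted symbol vectors),
#'   `union` and `intersection`.
#' @export
screening_candidates <- function(burden, threshold = 1 / 200) {
  anc <- unique(burden$ancestry)
  per <- lapply(anc, function(a) {
    sort(burden$gene[burden$ancestry == a & burden$CrF > threshold])
  })
  names(per) <- anc
  list(per_ancestry = per,
       union = sort(Reduce(union, per, accumulate = FALSE)),
       intersection = sort(Reduce(intersect, per)))
}

#' Secondary-findings burden report
#'
#' Recomputes burden over the actionable (secondary-finding) gene subset,
#' honoring per-gene reportable-variant restrictions (e.g. limiting the
#' hemochromatosis gene to its single recommended variant), then reports
#' cumulative CrF (each gene once) and cumulative GP (one term per
#' inheritance phenotype entry) per ancestry, the per-gene table, and
#' per-phenotype-group totals (cardiovascular, cancer, inborn errors of
#' metabolism, miscellaneous).
#'
#' @param variants QC-filtered variant tibble.
#' @param genes Gene annotation tibble; rows with `secondary_finding = TRUE`
#'   form the actionable set.
#' @param tiers Tier set; default `"PLP"`.
#' @return List with `per_gene`, `cumulative` (tibble `ancestry`,
#'   `cumulative_CrF`, `cumulative_GP`) and `by_phenotype_group` (tibble
#'   `sf_phenotype_group`, `ancestry`, `GP`).
#' @export
secondary_findings_report <- function(variants, genes, tiers = "PLP") {
  sf <- genes[genes$secondary_finding, , drop = FALSE]
  if (nrow(sf) == 0) {
    return(list(per_gene = tibble::tibble(),
                cumulative = tibble::tibble(
                  ancestry = variant_ancestries(variants),
                  cumulative_CrF = 0, cumulative_GP = 0),
                by_phenotype_group = tibble::tibble()))
  }
  ids <- unlist(sf$restricted_variant_ids)
  unknown <- setdiff(ids, variants$variant_id)
  if (length(unknown) > 0) {
    stop("restricted variant id(s) not present in the variant table: ",
         paste(unknown, collapse = ", "))
  }
  per_gene <- compute_gene_burden(
    variants[variants$gene %in% sf$symbol, , drop = FALSE], sf, tiers,
    apply_restrictions = TRUE)
  per_gene$gp_entry <- gp_cumulative_contribution(per_gene$CAF,
                                                  per_gene$inheritance)
  cumu <- dplyr::summarise(
    dplyr::group_by(per_gene, .data$ancestry),
    cumulative_CrF = sum(.data$CrF),
    cumulative_GP = sum(.data$gp_entry), .groups = "drop")
  per_gene$sf_phenotype_group <- sf$sf_phenotype_group[match(per_gene$gene,
                                                             sf$symbol)]
  by_grp <- dplyr::summarise(
    dplyr::group_by(per_gene, .data$sf_phenotype_group, .data$ancestry),
    GP = sum(.data$gp_entry), .groups = "drop")
  per_gene$gp_entry <- NULL
  list(per_gene = per_gene, cumulative = cumu, by_phenotype_group = by_grp)
}

#' Convert a prevalence to an absolute affected count
#'
#' Ancestry scope multiplies the prevalence by that ancestry's world
#' population. Global scope takes a named per-ancestry prevalence vector and
#' returns the population-weighted sum of per-ancestry counts — never a mean
#' prevalence times the total, which would mis-weight unequal populations.
#'
#' @param prevalence For `scope = "ancestry"`, a scalar in \[0, 1\]; for
#'   `scope = "global"`, a numeric vector named by ancestry code.
#' @param config A [population_config()].
#' @param scope `"ancestry"` or `"global"`.
#' @param ancestry Ancestry code (required for ancestry scope).
#' @return Expected number of affected individuals.
#' @export
scale_to_population <- function(prevalence, config,
                                scope = c("ancestry", "global"),
                                ancestry = NULL) {
  scope <- match.arg(scope)
  if (any(prevalence < 0) || any(prevalence > 1)) {
    stop("prevalence must lie in [0, 1]")
  }
  if (scope == "ancestry") {
    if (is.null(ancestry) || !ancestry %in% names(config$world_population)) {
      stop("unknown or missing ancestry for ancestry-scope scaling")
    }
    return(unname(prevalence * config$world_population[[ancestry]]))
  }
  if (is.null(names(prevalence))) {
    stop("global scaling needs a prevalence vector named by ancestry")
  }
  miss <- setdiff(names(prevalence), names(config$world_population))
  if (length(miss) > 0) stop("unknown ancestry: ", paste(miss, collapse = ", "))
  sum(prevalence * config$world_population[names(prevalence)])
}

#' Constraint-metric flags and single- vs multi-group contrast
#'
#' Flags genes as constrained at the standard thresholds (LOEUF < 0.6,
#' missense Z > 3.09, synonymous Z > 3.71, all strict) and contrasts the
#' constraint distributions between genes assigned to a single disease
#' group and genes assigned to several, using a two-sided rank-sum
#' (Mann-Whitney) test per metric.
#'
#' @param metrics Tibble with columns `gene`, `pLI`, `LOEUF`, `mis_z`,
#'   `syn_z` (extra columns pass through).
#' @param genes Gene annotation tibble carrying `disease_groups`.
#' @return List with `flags` (metrics plus logical `constrained_loeuf`,
#'   `constrained_mis`, `constrained_syn` and `multi_group`) and `contrast`
#'   (tibble `metric`, `median_single`, `median_multi`, `direction`, `p`).
#' @export
constraint_comparison <- function(metrics, genes) {
  m <- dplyr::inner_join(metrics,
                         tibble::tibble(
                           gene = genes$symbol,
                           n_groups = vapply(genes$disease_groups, length, 0L)),
                         by = "gene")
  if (nrow(m) == 0) stop("no overlap between constraint metrics and gene set")
  m$constrained_loeuf <- m$LOEUF < 0.6
  m$constrained_mis <- m$mis_z > 3.09
  m$constrained_syn <- m$syn_z > 3.71
  m$multi_group <- m$n_groups > 1
  contrast_one <- function(col) {
    x <- m[[col]][!m$multi_group]
    y <- m[[col]][m$multi_group]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(metric = col, median_single = stats::median(x),
                            median_multi = stats::median(y),
                            direction = NA_character_, p = NA_real_))
    }
    w <- stats::wilcox.test(x, y, exact = FALSE)
    tibble::tibble(
      metric = col,
      median_single = stats::median(x),
      median_multi = stats::median(y),
      direction = ifelse(stats::median(y) < stats::median(x),
                         "multi_lower", "multi_higher"),
      p = w$p.value)
  }
  list(flags = m,
       contrast = dplyr::bind_rows(lapply(c("LOEUF", "mis_z", "syn_z"),
                                          contrast_one)))
}

#' Assemble the full burden report
#'
#' Orchestrates the pipeline on validated inputs: per-tier-set gene burden
#' (with optional second-cohort averaging), cumulative CrF/GP per ancestry
#' and their unweighted cross-ancestry means, the non-carrier likelihood per
#' tier set, the disease-group table, top-N rankings, screening candidates,
#' the secondary-findings report and absolute-count conversions. The result
#' is a pure function of its inputs: rerunning, or permuting input row
#' order, yields an identical report.
#'
#' @param variants QC-filtered variant tibble (cohort A).
#' @param genes Curated, merged gene annotation tibble.
#' @param config A [population_config()].
#' @param tier_sets Tier-set names to compute; default all three.
#' @param cohort_b Optional second QC-filtered variant tibble to average
#'   with, over `shared_ancestries`.
#' @param shared_ancestries Ancestries shared by the two cohorts.
#' @param top_n Rows per ancestry in the ranking tables.
#' @param screening_threshold Strict CrF cutoff for screening candidacy.
#' @param screening_tier_set Tier set used for screening and secondary
#'   findings; default `"PLP"`.
#' @return A `burden_report` list.
#' @export
build_full_report <- function(variants, genes, config = default_population_config(),
                              tier_sets = tier_set_names(),
                              cohort_b = NULL, shared_ancestries = NULL,
                              top_n = 30, screening_threshold = 1 / 200,
                              screening_tier_set = "PLP") {
  burdens <- list()
  for (ts in tier_sets) {
    b <- compute_gene_burden(variants, genes, ts)
    if (!is.null(cohort_b)) {
      b2 <- compute_gene_burden(cohort_b, genes, ts)
      if (is.null(shared_ancestries)) {
        shared_ancestries <- intersect(unique(b$ancestry), unique(b2$ancestry))
      }
      b <- average_cohorts(b, b2, shared_ancestries)$burden
    }
    burdens[[ts]] <- b
  }
  gene_burden <- dplyr::bind_rows(burdens)
  cumulative <- dplyr::bind_rows(lapply(names(burdens), function(ts) {
    b <- burdens[[ts]]
    dplyr::summarise(
      dplyr::group_by(b, .data$ancestry),
      tier_set = ts,
      cumulative_CrF = sum(.data$CrF),
      cumulative_GP = sum(gp_cumulative_contribution(.data$CAF, .data$inheritance)),
      noncarrier_likelihood = noncarrier_likelihood(.data$CrF),
      .groups = "drop")
  }))
  cumulative_mean <- dplyr::summarise(
    dplyr::group_by(cumulative, .data$tier_set),
    cumulative_CrF = mean(.data$cumulative_CrF),
    cumulative_GP = mean(.data$cumulative_GP),
    noncarrier_likelihood = mean(.data$noncarrier_likelihood),
    .groups = "drop")
  scr_burden <- burdens[[screening_tier_set]]
  if (is.null(scr_burden)) scr_burden <- burdens[[1]]
  groups <- disease_group_burden(scr_burden, genes)
  top_crf <- rank_top_genes(scr_burden, "CrF", top_n)
  top_gp <- rank_top_genes(scr_burden, "GP", top_n)
  screening <- screening_candidates(scr_burden, screening_threshold)
  sf <- secondary_findings_report(variants, genes, screening_tier_set)
  anc <- intersect(unique(scr_burden$ancestry), names(config$world_population))
  cum_scr <- cumulative[cumulative$tier_set == scr_burden$tier_set[1], ,
                        drop = FALSE]
  gp_vec <- stats::setNames(cum_scr$cumulative_GP, cum_scr$ancestry)[anc]
  scaled <- tibble::tibble(
    ancestry = anc,
    cumulative_GP = unname(gp_vec),
    affected_individuals = vapply(anc, function(a) {
      scale_to_population(min(gp_vec[[a]], 1), config, "ancestry", a)
    }, numeric(1)))
  report <- list(
    gene_burden = gene_burden,
    cumulative = cumulative,
    cumulative_mean = cumulative_mean,
    group_by_ancestry = groups$by_ancestry,
    group_mean = groups$mean,
    top_crf = top_crf,
    top_gp = top_gp,
    screening_per_ancestry = tibble::tibble(
      ancestry = rep(names(screening$per_ancestry),
                     vapply(screening$per_ancestry, length, 0L)),
      gene = unlist(screening$per_ancestry, use.names = FALSE)),
    screening_sets = screening,
    sf_per_gene = sf$per_gene,
    sf_cumulative = sf$cumulative,
    sf_by_phenotype_group = sf$by_phenotype_group,
    scaled_counts = scaled)
  class(report) <- c("burden_report", class(report))
  report
}
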
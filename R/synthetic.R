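#' Specification for the synthetic-data generator
#'
#' Bundles every knob of the generator with defaults that mirror the
#' statistical structure the analysis assumes in real cohort summaries:
#'
#' * `inheritance_mix` follows the breakdown of curated disease-gene panels
#'   (about 53% AR, 28% AD, 13% AD_AR, 5.5% X-linked, mostly recessive);
#' * `tier_mix` follows the observed classification shares (P 0.5%,
#'   LP 2.4%, VUS-H 1.8%, VUS-M 3.0%, VUS-L 68.1%, LB 23.6%, B 0.6%), so
#'   only a few percent of generated variants enter any burden tier set;
#' * per-variant allele frequencies are log-uniform on
#'   `[af_min, af_max] = [1e-6, 1e-2]`, with a small fraction
#'   (`common_frac`) of common outliers drawn uniformly up to
#'   `common_max = 0.3`;
#' * variant counts per gene are Poisson with mean `mean_variants = 30`
#'   (desk-scale; population catalogs carry orders of magnitude more);
#' * disease-group multiplicity: 40% of genes in one group, 32% in two,
#'   28% in more than two (capped at 5 here; real panels reach 9);
#' * cohorts of 100,000 individuals per ancestry (AN_max 200,000);
#'   `coverage_fail_frac` of (variant, ancestry) pairs are planted with
#'   AN/AN_max = 0.4 to exercise the coverage filter.
#'
#' `noiseless = TRUE` sets AN = AN_max everywhere, disables planted
#' coverage failures and makes AC deterministic, so the whole pipeline
#' becomes an exact identity on the recorded ground truth.
#'
#' @param n_genes Number of genes.
#' @param inheritance_mix Named proportions over the inheritance modes.
#' @param tier_mix Named proportions over the seven tiers.
#' @param af_min,af_max Bounds of the log-uniform allele-frequency model.
#' @param common_frac Fraction of variants drawn as common outliers.
#' @param common_max Upper bound of the common-outlier AF.
#' @param mean_variants Poisson mean of the per-gene variant count.
#' @param ancestries Ancestry codes to emit AC/AN columns for.
#' @param cohort_sizes Named vector of cohort individuals per ancestry
#'   (AN_max is twice this for autosomes).
#' @param group_mult_probs Probabilities of a gene belonging to 1..5 groups.
#' @param coverage_fail_frac Fraction of planted low-coverage pairs.
#' @param sf_frac Fraction of genes flagged as secondary-finding genes.
#' @param noiseless Disable all sampling noise.
#' @param seed Integer seed; fully determines the output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 100,
                           inheritance_mix = c(AD = 0.281, AR = 0.533,
                                               AD_AR = 0.130, XLR = 0.045,
                                               XLD = 0.011),
                           tier_mix = c("P" = 0.005, "LP" = 0.024,
                                        "VUS-H" = 0.018, "VUS-M" = 0.030,
                                        "VUS-L" = 0.681, "LB" = 0.236,
                                        "B" = 0.006),
                           af_min = 1e-6, af_max = 1e-2,
                           common_frac = 0.005, common_max = 0.3,
                           mean_variants = 30,
                           ancestries = ancestry_codes(),
                           cohort_sizes = NULL,
                           group_mult_probs = c(0.40, 0.32, 0.16, 0.08, 0.04),
                           coverage_fail_frac = 0.02,
                           sf_frac = 0.02,
                           noiseless = FALSE,
                           seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be positive")
  check_mix <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " proportions must be non-negative and sum to 1")
    }
  }
  check_mix(inheritance_mix, "inheritance_mix")
  check_mix(tier_mix, "tier_mix")
  check_mix(group_mult_probs, "group_mult_probs")
  if (!setequal(names(tier_mix), tier_levels())) {
    stop("tier_mix must name exactly the seven tiers")
  }
  if (!all(names(inheritance_mix) %in% inheritance_modes())) {
    stop("inheritance_mix names must be inheritance modes")
  }
  if (is.null(cohort_sizes)) {
    cohort_sizes <- stats::setNames(rep(100000L, length(ancestries)), ancestries)
  }
  structure(list(
    n_genes = as.integer(n_genes), inheritance_mix = inheritance_mix,
    tier_mix = tier_mix[tier_levels()], af_min = af_min, af_max = af_max,
    common_frac = common_frac, common_max = common_max,
    mean_variants = mean_variants, ancestries = ancestries,
    cohort_sizes = cohort_sizes, group_mult_probs = group_mult_probs,
    coverage_fail_frac = if (noiseless) 0 else coverage_fail_frac,
    sf_frac = sf_frac, noiseless = noiseless, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic gene annotation set
#'
#' Draws gene symbols, inheritance modes, mechanisms, source provenance,
#' disease-group memberships and secondary-finding flags per the spec.
#' Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genes` (annotation tibble, X-linked genes marked by
#'   inheritance) and `ground_truth` (the same draws, kept as the ledger).
#' @export
generate_gene_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  symbols <- sprintf("GENE%04d", seq_len(n))
  inh <- sample(names(spec$inheritance_mix), n, replace = TRUE,
                prob = spec$inheritance_mix)
  mech <- sample(c("LoF", "GoF", "LoF_GoF"), n, replace = TRUE,
                 prob = c(0.935, 0.052, 0.013))
  src_kind <- sample(c("both", "PanelApp", "OMIM"), n, replace = TRUE,
                     prob = c(0.803, 0.075, 0.122))
  sources <- lapply(src_kind, function(k) {
    if (k == "both") c("PanelApp", "OMIM") else k
  })
  n_groups <- sample(seq_along(spec$group_mult_probs), n, replace = TRUE,
                     prob = spec$group_mult_probs)
  groups <- lapply(n_groups, function(k) sort(sample(disease_groups(), k)))
  sf <- stats::runif(n) < spec$sf_frac
  sfg <- ifelse(sf, sample(sf_phenotype_groups(), n, replace = TRUE),
                NA_character_)
  genes <- tibble::tibble(
    symbol = symbols, protein_coding = TRUE, inheritance = inh,
    mechanism = mech, sources = sources, disease_groups = groups,
    repeat_expansion_only = FALSE, mechanism_established = TRUE,
    secondary_finding = sf, sf_phenotype_group = sfg,
    restricted_variant_ids = rep(list(character(0)), n))
  list(genes = genes, ground_truth = genes)
}

#' Generate a synthetic variant table with known ground truth
#'
#' Per gene, a Poisson number of variants with tiers and true allele
#' frequencies drawn per the spec (true AFs are shared across ancestries).
#' For every ancestry: AN is AN_max (2 x cohort individuals) except for a
#' planted fraction of low-coverage pairs at 40% of AN_max, and AC is drawn
#' binomially from (AN, true AF). In noiseless mode AN = AN_max everywhere
#' and AC = round(AF x AN), with the ground-truth AF redefined as AC/AN so
#' the recorded truth is exactly recoverable. X-linked genes are placed on
#' chrX; the ground-truth ledger records, per gene and tier set, the exact
#' CAF implied by the true AFs.
#'
#' @param genes Gene tibble from [generate_gene_set()].
#' @param spec The same [synthetic_spec()].
#' @return List with `variants` (variant tibble), `truth_caf` (tibble
#'   `gene`, `tier_set`, `true_CAF`) and `truth_af` (per-variant true AFs).
#' @export
generate_variant_table <- function(genes, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n_var <- stats::rpois(nrow(genes), spec$mean_variants)
  total <- sum(n_var)
  gene_of <- rep(genes$symbol, n_var)
  inh_of <- rep(genes$inheritance, n_var)
  tier <- sample(names(spec$tier_mix), total, replace = TRUE,
                 prob = spec$tier_mix)
  af <- 10^stats::runif(total, log10(spec$af_min), log10(spec$af_max))
  common <- stats::runif(total) < spec$common_frac
  af[common] <- stats::runif(sum(common), spec$af_max, spec$common_max)
  chrom <- ifelse(inh_of %in% c("XLR", "XLD"), "X",
                  as.character(1 + (match(gene_of, genes$symbol) %% 22)))
  pos <- seq_len(total) * 100 + 1000  # globally unique positions
  variant_id <- paste(chrom, pos, "A", "G", sep = ":")
  tab <- tibble::tibble(variant_id = variant_id, gene = gene_of,
                        tier = tier, filter = "PASS")
  for (a in spec$ancestries) {
    an_max <- 2L * spec$cohort_sizes[[a]]
    an <- rep(an_max, total)
    fail <- stats::runif(total) < spec$coverage_fail_frac
    an[fail] <- as.integer(floor(0.4 * an_max))
    if (spec$noiseless) {
      ac <- as.integer(round(af * an))
    } else {
      ac <- stats::rbinom(total, an, af)
    }
    tab[[paste0("AC_", a)]] <- ac
    tab[[paste0("AN_", a)]] <- as.integer(an)
  }
  if (spec$noiseless && length(spec$ancestries) > 0) {
    # redefine truth on the emitted rational grid so recovery is exact
    a1 <- spec$ancestries[1]
    af <- tab[[paste0("AC_", a1)]] / tab[[paste0("AN_", a1)]]
  }
  truth_af <- tibble::tibble(variant_id = tab$variant_id, gene = gene_of,
                             tier = tier, true_AF = af)
  truth_caf <- dplyr::bind_rows(lapply(tier_set_names(), function(ts) {
    keep <- tier %in% tier_set(ts)
    agg <- stats::aggregate(list(true_CAF = af[keep]),
                            by = list(gene = gene_of[keep]), FUN = sum)
    i <- match(genes$symbol, agg$gene)
    tibble::tibble(gene = genes$symbol, tier_set = ts,
                   true_CAF = ifelse(is.na(i), 0, agg$true_CAF[i]))
  }))
  tab$tier <- factor(tab$tier, levels = tier_levels())
  list(variants = tab, truth_caf = truth_caf, truth_af = truth_af)
}

#' Genotype-level simulator: the brute-force oracle
#'
#' Simulates individual genotypes for one gene under Hardy-Weinberg
#' equilibrium and independent assortment, at the haplotype level: each
#' haplotype carries variant j independently with probability AF_j, and a
#' haplotype is pathogenic if it carries at least one qualifying allele.
#' Diploid (autosomal) individuals have two haplotypes; under the X-linked
#' model each individual is female with probability `sex_ratio` (two
#' haplotypes) and male otherwise (one). Empirical fractions
#' are returned for comparison against the closed-form carrier frequency,
#' biallelic (homozygote + compound-heterozygote in trans) frequency, and
#' the X-linked prevalence forms.
#'
#' @param afs Numeric vector of qualifying-variant allele frequencies.
#' @param n_individuals Positive number of individuals to simulate.
#' @param model `"autosomal"` or `"x_linked"`.
#' @param sex_ratio Female fraction under the X-linked model; default 0.5.
#' @param seed Integer seed.
#' @return List with `carrier_fraction` (exactly one pathogenic haplotype
#'   among diploids), `biallelic_fraction` (both haplotypes pathogenic),
#'   and under the X-linked model `hemizygous_fraction` (pathogenic males /
#'   all individuals), `xlr_fraction` (hemizygous males + biallelic
#'   females) and `xld_fraction` (those plus heterozygous females); plus
#'   `allele_counts`, the per-individual count of carried qualifying
#'   alleles, and `n_*` tallies.
#' @export
simulate_genotypes <- function(afs, n_individuals,
                               model = c("autosomal", "x_linked"),
                               sex_ratio = 0.5, seed = 1L) {
  model <- match.arg(model)
  if (n_individuals <= 0) stop("n_individuals must be positive")
  if (length(afs) > 0 && (any(afs < 0) || any(afs > 1))) {
    stop("allele frequencies must lie in [0, 1]")
  }
  set.seed(seed)
  n <- as.integer(n_individuals)
  draw_hap <- function(m) {
    # m individuals; returns list(pathogenic flag, allele count per haplotype)
    carries <- integer(m)
    for (f in afs) carries <- carries + (stats::runif(m) < f)
    carries
  }
  if (model == "autosomal") {
    h1 <- draw_hap(n)
    h2 <- draw_hap(n)
    path <- (h1 > 0) + (h2 > 0)
    return(list(
      carrier_fraction = mean(path == 1),
      biallelic_fraction = mean(path == 2),
      allele_counts = h1 + h2,
      n_individuals = n))
  }
  female <- stats::runif(n) < sex_ratio
  n_f <- sum(female)
  n_m <- n - n_f
  f1 <- draw_hap(n_f); f2 <- draw_hap(n_f)
  m1 <- draw_hap(n_m)
  f_path <- (f1 > 0) + (f2 > 0)
  m_path <- m1 > 0
  counts <- integer(n)
  counts[female] <- f1 + f2
  counts[!female] <- m1
  list(
    carrier_fraction = mean(f_path == 1),      # among females (diploid sense)
    biallelic_fraction = mean(f_path == 2),    # among females
    hemizygous_fraction = sum(m_path) / n,
    xlr_fraction = (sum(m_path) + sum(f_path == 2)) / n,
    xld_fraction = (sum(m_path) + sum(f_path >= 1)) / n,
    allele_counts = counts,
    n_individuals = n, n_female = n_f, n_male = n_m)
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a synthetic dataset from the spec, runs the full pipeline
#' (QC filter, tier-set selection, per-gene burden) on it, and compares the
#' estimated CAF per (gene, ancestry, tier set) against the recorded ground
#' truth. In noiseless mode the pipeline is an exact identity on the truth;
#' with binomial sampling at AN = 200,000 the absolute CAF error is at the
#' binomial-sampling scale sqrt(CAF/AN).
#'
#' @param spec A [synthetic_spec()].
#' @param tier_sets Tier sets to evaluate.
#' @param tolerance Absolute-error tolerance for the `fraction_within`
#'   summary; default 1e-4.
#' @return List with `per_gene` (tibble `gene`, `ancestry`, `tier_set`,
#'   `true_CAF`, `est_CAF`, `abs_error`) and `summary` (per tier set:
#'   median/max absolute error and fraction within tolerance).
#' @export
recovery_experiment <- function(spec, tier_sets = tier_set_names(),
                                tolerance = 1e-4) {
  gs <- generate_gene_set(spec)
  vt <- generate_variant_table(gs$genes, spec)
  an_max <- 2 * spec$cohort_sizes
  qc <- filter_variants_qc(vt$variants, an_max)
  per <- dplyr::bind_rows(lapply(tier_sets, function(ts) {
    b <- compute_gene_burden(qc$variants, gs$genes, ts)
    truth <- vt$truth_caf[vt$truth_caf$tier_set == ts, , drop = FALSE]
    b$true_CAF <- truth$true_CAF[match(b$gene, truth$gene)]
    tibble::tibble(gene = b$gene, ancestry = b$ancestry, tier_set = ts,
                   true_CAF = b$true_CAF, est_CAF = b$CAF,
                   abs_error = abs(b$CAF - b$true_CAF))
  }))
  summ <- dplyr::summarise(
    dplyr::group_by(per, .data$tier_set),
    median_abs_error = stats::median(.data$abs_error),
    max_abs_error = max(.data$abs_error),
    fraction_within = mean(.data$abs_error <= tolerance),
    .groups = "drop")
  list(per_gene = per, summary = summ)
}
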
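#' Registered genetic ancestry codes
#'
#' The nine ancestry groups the pipeline knows about by default: afr
#' (African), amr_iam (Admixed/Indigenous American), asj (Ashkenazi Jewish),
#' eas (East Asian), fin (Finnish), mid (Middle Eastern), nfe (non-Finnish
#' European), sas (South Asian) and tur (Turkish). The registry is
#' extensible: readers and the generator accept an `ancestries` argument, so
#' additional codes can be used as long as they are declared.
#'
#' @return Character vector of ancestry codes.
#' @export
ancestry_codes <- function() {
  c("afr", "amr_iam", "asj", "eas", "fin", "mid", "nfe", "sas", "tur")
}

#' The thirteen ICD-10-based disease groups
#'
#' Phenotype categories used for group-level burden aggregation. Gene
#' membership is many-to-many, so group prevalences are non-mutually
#' exclusive.
#'
#' @return Character vector of the 13 group names.
#' @export
disease_groups <- function() {
  c("congenital", "musculoskeletal_connective", "blood_immune", "nervous",
    "skin", "endocrine_metabolic", "circulatory", "eye", "ear",
    "genitourinary", "neoplasm", "digestive", "respiratory")
}

#' Variant classification tiers
#'
#' The seven classification categories, ordered from most to least likely
#' pathogenic. The descriptive posterior odds-of-pathogenicity bands are
#' P >99%, LP 90%, VUS-H 67.5%, VUS-M 41%, VUS-L 14%, LB 10%, B <1%.
#'
#' @return Character vector of tier tokens in decreasing pathogenicity order.
#' @export
tier_levels <- function() {
  c("P", "LP", "VUS-H", "VUS-M", "VUS-L", "LB", "B")
}

#' Posterior odds-of-pathogenicity band for a tier
#'
#' @param tier Character vector of tier tokens.
#' @return Named numeric vector: nominal posterior probability band per tier.
#' @export
tier_odds_band <- function(tier = tier_levels()) {
  bands <- c("P" = 0.99, "LP" = 0.90, "VUS-H" = 0.675, "VUS-M" = 0.41,
             "VUS-L" = 0.14, "LB" = 0.10, "B" = 0.01)
  bad <- setdiff(tier, names(bands))
  if (length(bad) > 0) {
    stop("unknown tier token(s): ", paste(bad, collapse = ", "))
  }
  bands[tier]
}

#' Nested tier sets used for burden estimation
#'
#' Burden metrics are computed for three nested variant sets: pathogenic
#' only (`"P"`), pathogenic plus likely pathogenic (`"PLP"`), and those plus
#' high-confidence VUS (`"PLPVH"`).
#'
#' @param name One of `"P"`, `"PLP"`, `"PLPVH"`.
#' @return Character vector of member tiers.
#' @export
#' @examples
#' tier_set("PLP")   # "P"  "LP"
tier_set <- function(name = c("P", "PLP", "PLPVH")) {
  name <- match.arg(name)
  switch(name,
         P     = "P",
         PLP   = c("P", "LP"),
         PLPVH = c("P", "LP", "VUS-H"))
}

#' Names of the three nested tier sets
#' @return Character vector `c("P", "PLP", "PLPVH")`, in nesting order.
#' @export
tier_set_names <- function() c("P", "PLP", "PLPVH")

#' Inheritance modes
#'
#' Canonical single-gene inheritance modes: autosomal dominant (AD),
#' autosomal recessive (AR), both (AD_AR), X-linked recessive (XLR) and
#' X-linked dominant (XLD). Pseudoautosomal dominant/recessive annotations
#' are mapped to AD/AR at ingestion, since pseudoautosomal loci behave
#' autosomally for allele-frequency arithmetic.
#'
#' @return Character vector of mode tokens.
#' @export
inheritance_modes <- function() c("AD", "AR", "AD_AR", "XLR", "XLD")

# Normalizes inheritance spellings seen in source tables. Pre-curation
# tokens (mitochondrial, undefined, ...) pass through unchanged so that
# curate_genes() can log them as exclusions.
normalize_inheritance <- function(x) {
  x <- trimws(x)
  map <- c("AD/AR" = "AD_AR", "AR/AD" = "AD_AR",
    "pseudoautosomal_dominant" = "AD", "pseudoautosomal_recessive" = "AR",
    "PAD" = "AD", "PAR" = "AR", "XL" = "XLR")
  hit <- match(x, names(map))
  x[!is.na(hit)] <- map[hit[!is.na(hit)]]
  x
}

#' Secondary-findings phenotype groups
#' @return Character vector of the four actionable phenotype groups.
#' @export
sf_phenotype_groups <- function() {
  c("cardiovascular", "cancer", "inborn_errors_of_metabolism", "miscellaneous")
}

#' Population configuration
#'
#' Holds, per ancestry, the sequenced cohort size (individuals) and the
#' world population the ancestry represents (persons). The reference
#' population for global absolute-count conversions is the sum of the
#' world-population column.
#'
#' @param cohort_individuals Named integer vector (names = ancestry codes).
#' @param world_population Named numeric vector (persons), same names.
#' @return A `population_config` list with elements `cohort_individuals`,
#'   `world_population` and `reference_population`.
#' @export
population_config <- function(cohort_individuals, world_population) {
  if (is.null(names(cohort_individuals)) || is.null(names(world_population))) {
    stop("cohort_individuals and world_population must be named by ancestry")
  }
  if (!setequal(names(cohort_individuals), names(world_population))) {
    stop("ancestry names of cohort_individuals and world_population differ")
  }
  world_population <- world_population[names(cohort_individuals)]
  if (any(cohort_individuals <= 0) || any(world_population <= 0)) {
    stop("all cohort and world population sizes must be positive")
  }
  structure(
    list(cohort_individuals = cohort_individuals,
         world_population = world_population,
         reference_population = sum(world_population)),
    class = "population_config")
}

#' Default population configuration for the nine-ancestry registry
#'
#' Synthetic stand-in sizes: cohorts of 100,000 individuals per ancestry and
#' rounded world-population figures chosen to sum to 7.47 billion persons,
#' the reference total used for absolute-count conversions.
#'
#' @return A `population_config`.
#' @export
default_population_config <- function() {
  anc <- ancestry_codes()
  world <- c(afr = 1.40e9, amr_iam = 6.6e8, asj = 1.0e7, eas = 1.90e9,
             fin = 5.6e6, mid = 4.894e8, nfe = 9.7e8, sas = 1.95e9,
             tur = 8.5e7)
  population_config(
    cohort_individuals = stats::setNames(rep(100000L, length(anc)), anc),
    world_population = world[anc])
}
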
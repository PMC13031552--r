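#' Allele frequency from allele counts
#'
#' @param ac Alternate allele count (AC), `0 <= ac <= an`.
#' @param an Called allele number (AN), positive.
#' @return AF = AC / AN.
#' @export
allele_frequency <- function(ac, an) {
  if (any(an == 0)) stop("AN = 0: variant has no called alleles in this ancestry")
  if (any(ac < 0) || any(ac > an)) stop("require 0 <= AC <= AN")
  ac / an
}

#' Cumulative allele frequency of a gene
#'
#' Sum of the allele frequencies of a gene's qualifying variants, assuming
#' independent assortment. The raw sum is capped at 1 with a warning, since
#' the independence assumption can push it above 1 for extreme inputs.
#'
#' @param afs Numeric vector of per-variant allele frequencies in \[0, 1\].
#' @return CAF in \[0, 1\].
#' @export
cumulative_allele_frequency <- function(afs) {
  if (length(afs) == 0) return(0)
  if (any(afs < 0) || any(afs > 1)) stop("allele frequencies must lie in [0, 1]")
  caf <- sum(afs)
  if (caf > 1) {
    warning("raw CAF ", format(caf), " exceeds 1; capped (independence assumption broken)")
    caf <- 1
  }
  caf
}

#' Carrier frequency under Hardy-Weinberg equilibrium
#'
#' Proportion of individuals heterozygous for exactly one qualifying allele:
#' CrF = 2·CAF·(1 − CAF). Symmetric about CAF = 0.5 where it attains its
#' maximum of 0.5.
#'
#' @param caf Cumulative allele frequency in \[0, 1\].
#' @return CrF in \[0, 0.5\].
#' @export
carrier_frequency <- function(caf) {
  if (any(caf < 0) || any(caf > 1)) stop("CAF must lie in [0, 1]")
  2 * caf * (1 - caf)
}

#' Invert the carrier-frequency formula
#'
#' Solves 2·c·(1 − c) = CrF for the minor root c = (1 − sqrt(1 − 2·CrF)) / 2,
#' the CAF a reported carrier frequency implies in the minor-allele regime.
#'
#' @param crf Carrier frequency in \[0, 0.5\].
#' @return CAF in \[0, 0.5\].
#' @export
#' @examples
#' invert_carrier_frequency(1 / 21)  # 0.0244...
invert_carrier_frequency <- function(crf) {
  if (any(crf < 0) || any(crf > 0.5)) {
    stop("CrF must lie in [0, 0.5]: 0.5 is the maximum of 2*CAF*(1-CAF)")
  }
  (1 - sqrt(1 - 2 * crf)) / 2
}

#' Combined homozygote and compound-heterozygote frequency
#'
#' HomF = CAF^2: the Hardy-Weinberg probability that both haplotypes carry a
#' qualifying allele.
#'
#' @param caf Cumulative allele frequency in \[0, 1\].
#' @return HomF in \[0, 1\].
#' @export
homozygote_comphet_frequency <- function(caf) {
  if (any(caf < 0) || any(caf > 1)) stop("CAF must lie in [0, 1]")
  caf^2
}

#' Compound-heterozygote frequency for one pair of alleles
#'
#' Frequency of the trans genotype combining two distinct alleles:
#' (AF_i + AF_ii)^2 − AF_i^2 − AF_ii^2 = 2·AF_i·AF_ii. Summing this over all
#' unordered pairs and adding the per-allele homozygote terms AF^2
#' reconstitutes CAF^2 exactly.
#'
#' @param af_i,af_ii Allele frequencies of the two alleles.
#' @return Pair genotype frequency.
#' @export
compound_het_pair <- function(af_i, af_ii) {
  if (any(c(af_i, af_ii) < 0) || any(c(af_i, af_ii) > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  2 * af_i * af_ii
}

#' Genetic prevalence by inheritance mode
#'
#' Dispatches CAF to the genotype-frequency model of the gene's inheritance:
#' * AD and AD_AR: CrF = 2·CAF·(1 − CAF) (one pathogenic allele suffices);
#' * AR: HomF = CAF^2 (biallelic genotype);
#' * XLR: CAF·(CAF + 1)/2 — hemizygous males plus biallelic females at a
#'   50:50 sex ratio;
#' * XLD: (1 − CAF)·CAF + CAF·(CAF + 1)/2 — the XLR term plus heterozygous
#'   females.
#'
#' @param caf Cumulative allele frequency in \[0, 1\] (vectorized).
#' @param inheritance Mode token(s) from [inheritance_modes()]; recycled
#'   against `caf`.
#' @return Genetic prevalence in \[0, 1\].
#' @export
genetic_prevalence <- function(caf, inheritance) {
  if (any(caf < 0) || any(caf > 1)) stop("CAF must lie in [0, 1]")
  n <- max(length(caf), length(inheritance))
  caf <- rep_len(caf, n)
  inheritance <- rep_len(inheritance, n)
  bad <- setdiff(inheritance, inheritance_modes())
  if (length(bad) > 0) stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "))
  xlr <- caf * (caf + 1) / 2
  out <- numeric(n)
  out[inheritance %in% c("AD", "AD_AR")] <- (2 * caf * (1 - caf))[inheritance %in% c("AD", "AD_AR")]
  out[inheritance == "AR"] <- (caf^2)[inheritance == "AR"]
  out[inheritance == "XLR"] <- xlr[inheritance == "XLR"]
  out[inheritance == "XLD"] <- ((1 - caf) * caf + xlr)[inheritance == "XLD"]
  out
}

#' Likelihood of carrying no qualifying variant
#'
#' Product over genes of (1 − CrF_i): the probability that an individual is
#' a carrier for none of the genes considered.
#'
#' @param crfs Numeric vector of per-gene carrier frequencies in \[0, 1\].
#' @return Probability in \[0, 1\]; 1 for an empty input.
#' @export
noncarrier_likelihood <- function(crfs) {
  if (any(crfs < 0) || any(crfs > 1)) stop("CrF values must lie in [0, 1]")
  prod(1 - crfs)
}

#' Carrier frequency implied by a reported disease prevalence
#'
#' For an autosomal recessive disease with reported prevalence rP, the
#' Hardy-Weinberg carrier frequency is rCrF = 2·sqrt(rP)·(1 − sqrt(rP)).
#' Composing this with the AR prevalence model (rP = CAF^2) recovers the
#' forward carrier-frequency formula exactly.
#'
#' @param rp Reported prevalence in \[0, 1\].
#' @return Implied carrier frequency.
#' @export
reported_crf <- function(rp) {
  if (any(rp < 0) || any(rp > 1)) stop("reported prevalence must lie in [0, 1]")
  2 * sqrt(rp) * (1 - sqrt(rp))
}

# One dispatch term per inheritance phenotype entry. A gene with both a
# dominant and a recessive phenotype (AD_AR) has two entries; X-linked
# genes have one.
gp_phenotype_entries <- function(inheritance) {
  switch(inheritance,
         AD = "dominant", AR = "recessive",
         AD_AR = c("dominant", "recessive"),
         XLR = "xlr", XLD = "xld",
         stop("unknown inheritance mode: ", inheritance))
}

gp_entry_value <- function(caf, entry) {
  switch(entry,
         dominant = 2 * caf * (1 - caf),
         recessive = caf^2,
         xlr = caf * (caf + 1) / 2,
         xld = (1 - caf) * caf + caf * (caf + 1) / 2,
         stop("unknown phenotype entry: ", entry))
}

#' Per-gene genetic prevalence contribution under the cumulative counting rule
#'
#' For cumulative (and disease-group) genetic prevalence, a gene is counted
#' once for each inheritance phenotype it has: an AD_AR gene contributes its
#' dominant term 2·CAF·(1 − CAF) plus its recessive term CAF^2, while for
#' the per-gene table the same gene is reported with GP = CrF. Vectorized
#' over genes.
#'
#' @param caf Numeric vector of per-gene CAFs.
#' @param inheritance Inheritance mode per gene.
#' @return Numeric vector of summed phenotype-entry prevalences.
#' @export
gp_cumulative_contribution <- function(caf, inheritance) {
  if (length(caf) == 0) return(numeric(0))
  mapply(function(c1, mode) {
    sum(vapply(gp_phenotype_entries(mode), gp_entry_value, numeric(1), caf = c1))
  }, caf, inheritance, USE.NAMES = FALSE)
}

#' Cumulative carrier frequency across genes
#'
#' Expected number of qualifying carried variants per individual: the sum of
#' per-gene carrier frequencies, each gene counted exactly once regardless
#' of inheritance.
#'
#' @param burden A gene-burden table (one row per gene) with columns `gene`
#'   and `CrF`, or a numeric vector of CrFs named by gene.
#' @return Numeric scalar.
#' @export
cumulative_crf <- function(burden) {
  if (is.numeric(burden)) {
    crf <- burden
    genes <- names(burden)
  } else {
    crf <- burden$CrF
    genes <- burden$gene
  }
  if (!is.null(genes) && anyDuplicated(genes) > 0) {
    stop("duplicate gene in cumulative CrF input: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  sum(crf)
}

#' Cumulative genetic prevalence across genes
#'
#' Expected number of disease-compatible genotypes per individual: the sum
#' over (gene, inheritance-phenotype-entry) pairs of the dispatched
#' prevalence, so an AD_AR gene contributes both its dominant and its
#' recessive term.
#'
#' @param burden A gene-burden table (one row per gene) with columns `gene`
#'   and `CAF`.
#' @param inheritance Inheritance mode per gene (recycled if scalar); taken
#'   from a `inheritance` column of `burden` when present.
#' @return Numeric scalar.
#' @export
cumulative_gp <- function(burden, inheritance = NULL) {
  if (is.null(inheritance)) inheritance <- burden$inheritance
  if (is.null(inheritance)) stop("inheritance modes are required")
  if (anyDuplicated(burden$gene) > 0) {
    stop("duplicate gene in cumulative GP input")
  }
  sum(gp_cumulative_contribution(burden$CAF, rep_len(inheritance, nrow(burden))))
}
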
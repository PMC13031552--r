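#' Curate a raw disease-gene list
#'
#' Applies the gene-retention rules to one source list. For every source:
#' non-protein-coding genes are removed (exomes cover them poorly), as are
#' genes with undefined/unascertained, mitochondrial, digenic or Y-linked
#' inheritance. For OMIM-derived lists two further rules apply: genes whose
#' disease arises only through repeat expansion are removed (such variation
#' is absent from short-variant summaries), and genes without an established
#' disease mechanism are removed. Nothing errors: every exclusion is logged.
#'
#' @param raw Gene annotation tibble (see [read_gene_annotations()]).
#' @param source `"PanelApp"` or `"OMIM"`; selects the OMIM-only rules.
#' @return List with `genes` (retained tibble) and `excluded` (tibble of
#'   `symbol`, `reason`); `nrow(genes) + nrow(excluded) == nrow(raw)`.
#' @export
curate_genes <- function(raw, source = c("PanelApp", "OMIM")) {
  source <- match.arg(source)
  reason <- rep(NA_character_, nrow(raw))
  mark <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- mark(!raw$protein_coding, "non-protein-coding")
  reason <- mark(raw$inheritance == "mitochondrial", "mitochondrial-inheritance")
  reason <- mark(raw$inheritance %in% c("undefined", "unascertained"),
                 "undefined-inheritance")
  reason <- mark(!raw$inheritance %in% inheritance_modes(),
                 "unsupported-inheritance")
  if (source == "OMIM") {
    reason <- mark(raw$repeat_expansion_only, "repeat-expansion-only")
    reason <- mark(!raw$mechanism_established, "no-established-mechanism")
  }
  keep <- is.na(reason)
  list(genes = raw[keep, , drop = FALSE],
       excluded = tibble::tibble(symbol = raw$symbol[!keep],
                                 reason = reason[!keep]))
}

# More inclusive of two inheritance modes: AD vs AR (or either vs AD_AR)
# resolves to AD_AR; otherwise no automatic resolution.
more_inclusive_mode <- function(a, b) {
  if (a == b) return(a)
  auto <- c("AD", "AR", "AD_AR")
  if (a %in% auto && b %in% auto) return("AD_AR")
  NA_character_
}

#' Merge curated PanelApp and OMIM gene sets
#'
#' Union by symbol with provenance: the `sources` field of a merged gene is
#' the union of the source lists. Where the two sources disagree on
#' inheritance, the more inclusive mode wins (AD vs AR, or either vs AD_AR,
#' resolves to AD_AR); irreconcilable conflicts (e.g. autosomal vs X-linked)
#' keep the OMIM mode. Mechanism conflicts keep the OMIM mechanism and are
#' flagged for manual review. Disease-group memberships and report flags are
#' unioned. All conflicts are logged.
#'
#' @param panelapp,omim Curated gene tibbles.
#' @return List with `genes` (merged tibble), `conflicts` (tibble of
#'   `symbol`, `field`, `panelapp`, `omim`, `resolved`) and `counts`
#'   (overlap and unique-to-each tallies).
#' @export
merge_gene_sources <- function(panelapp, omim) {
  shared <- intersect(panelapp$symbol, omim$symbol)
  counts <- tibble::tibble(
    overlap = length(shared),
    panelapp_only = nrow(panelapp) - length(shared),
    omim_only = nrow(omim) - length(shared))
  conflicts <- list()
  merged <- omim[omim$symbol %in% shared, , drop = FALSE]
  merged <- merged[order(match(merged$symbol, shared)), , drop = FALSE]
  pa <- panelapp[match(shared, panelapp$symbol), , drop = FALSE]
  for (i in seq_along(shared)) {
    merged$sources[[i]] <- union(pa$sources[[i]], merged$sources[[i]])
    merged$disease_groups[[i]] <- union(pa$disease_groups[[i]],
                                        merged$disease_groups[[i]])
    merged$secondary_finding[i] <- pa$secondary_finding[i] || merged$secondary_finding[i]
    if (pa$inheritance[i] != merged$inheritance[i]) {
      res <- more_inclusive_mode(pa$inheritance[i], merged$inheritance[i])
      resolved <- if (is.na(res)) merged$inheritance[i] else res
      conflicts[[length(conflicts) + 1]] <- tibble::tibble(
        symbol = shared[i], field = "inheritance",
        panelapp = pa$inheritance[i], omim = merged$inheritance[i],
        resolved = resolved)
      merged$inheritance[i] <- resolved
    }
    if (!is.na(pa$mechanism[i]) && !is.na(merged$mechanism[i]) &&
        pa$mechanism[i] != merged$mechanism[i]) {
      conflicts[[length(conflicts) + 1]] <- tibble::tibble(
        symbol = shared[i], field = "mechanism",
        panelapp = pa$mechanism[i], omim = merged$mechanism[i],
        resolved = merged$mechanism[i])
    }
  }
  genes <- dplyr::bind_rows(
    panelapp[!panelapp$symbol %in% shared, , drop = FALSE],
    merged,
    omim[!omim$symbol %in% shared, , drop = FALSE])
  genes <- genes[order(genes$symbol), , drop = FALSE]
  list(genes = tibble::as_tibble(genes),
       conflicts = if (length(conflicts) > 0) dplyr::bind_rows(conflicts) else
         tibble::tibble(symbol = character(0), field = character(0),
                        panelapp = character(0), omim = character(0),
                        resolved = character(0)),
       counts = counts)
}

#' Quality-control filter for variant records
#'
#' Retains variants whose filter status is `PASS` and, per ancestry, keeps
#' an (AC, AN) pair usable only when the called-allele fraction AN/AN_max
#' strictly exceeds `min_call_fraction` (default 0.5 — the "covered more
#' than half of the individuals" rule). A variant failing coverage in one
#' ancestry is treated as absent there (its AC/AN set to NA) but still
#' contributes to ancestries where it is well covered. Idempotent.
#'
#' @param variants Variant tibble.
#' @param an_max Named numeric vector: maximum possible called alleles per
#'   ancestry for autosomal sites (2 x cohort individuals).
#' @param min_call_fraction Strict lower bound on AN/AN_max; default 0.5.
#' @param an_max_x Optional named numeric vector of AN_max for chrX sites
#'   (depends on the cohort's sex composition, so it is supplied, not
#'   inferred). Defaults to `an_max`.
#' @return List with `variants` (filtered tibble) and `drop_counts`
#'   (tibble of `rule`, `n`): `non_pass` rows removed, `low_coverage_pairs`
#'   ancestry pairs masked, `no_usable_ancestry` rows removed because no
#'   ancestry survived.
#' @export
filter_variants_qc <- function(variants, an_max, min_call_fraction = 0.5,
                               an_max_x = NULL) {
  anc <- variant_ancestries(variants)
  miss <- setdiff(anc, names(an_max))
  if (length(miss) > 0) stop("an_max missing for ancestry: ", paste(miss, collapse = ", "))
  if (any(an_max[anc] == 0)) stop("an_max = 0 for a declared ancestry")
  if (is.null(an_max_x)) an_max_x <- an_max
  n_nonpass <- sum(variants$filter != "PASS")
  out <- variants[variants$filter == "PASS", , drop = FALSE]
  on_x <- variant_chrom(out$variant_id) %in% c("X", "chrX")
  masked <- 0L
  for (a in anc) {
    denom <- ifelse(on_x, an_max_x[[a]], an_max[[a]])
    an <- out[[paste0("AN_", a)]]
    bad <- !is.na(an) & (an / denom <= min_call_fraction)
    masked <- masked + sum(bad)
    out[[paste0("AC_", a)]][bad] <- NA_integer_
    out[[paste0("AN_", a)]][bad] <- NA_integer_
  }
  usable <- rowSums(!is.na(as.matrix(out[, paste0("AN_", anc), drop = FALSE]))) > 0
  n_empty <- sum(!usable)
  out <- out[usable, , drop = FALSE]
  list(variants = out,
       drop_counts = tibble::tibble(
         rule = c("non_pass", "low_coverage_pairs", "no_usable_ancestry"),
         n = c(n_nonpass, masked, n_empty)))
}

#' Restrict variants to a tier set and a retained gene set
#'
#' Keeps variants whose tier belongs to the tier set and whose gene is in
#' the retained gene list. When `apply_restrictions = TRUE`, genes carrying
#' a `restricted_variant_ids` list (e.g. the single reportable
#' hemochromatosis variant in secondary-findings analyses) are limited to
#' those variant ids. Selection is monotone in the tier set: widening the
#' set never removes a variant.
#'
#' @param variants Variant tibble.
#' @param tiers Tier-set name (`"P"`, `"PLP"`, `"PLPVH"`) or an explicit
#'   character vector of tier tokens.
#' @param genes Gene annotation tibble, or a character vector of symbols.
#' @param apply_restrictions Honor per-gene restricted variant lists.
#' @return Filtered variant tibble.
#' @export
select_tier_set <- function(variants, tiers, genes,
                            apply_restrictions = FALSE) {
  if (length(tiers) == 1 && tiers %in% tier_set_names()) tiers <- tier_set(tiers)
  bad <- setdiff(tiers, tier_levels())
  if (length(bad) > 0) stop("unknown tier token(s): ", paste(bad, collapse = ", "))
  symbols <- if (is.character(genes)) genes else genes$symbol
  out <- variants[as.character(variants$tier) %in% tiers &
                    variants$gene %in% symbols, , drop = FALSE]
  if (apply_restrictions && !is.character(genes) &&
      "restricted_variant_ids" %in% names(genes)) {
    restricted <- genes[vapply(genes$restricted_variant_ids, length, 0L) > 0, ,
                        drop = FALSE]
    for (i in seq_len(nrow(restricted))) {
      ids <- restricted$restricted_variant_ids[[i]]
      g <- restricted$symbol[i]
      drop <- out$gene == g & !out$variant_id %in% ids
      out <- out[!drop, , drop = FALSE]
    }
  }
  out
}
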
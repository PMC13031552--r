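# Inheritance tokens tolerated at ingestion. Canonical modes plus
# pre-curation states that curate_genes() later logs as exclusions.
precuration_inheritance <- function() {
  c(inheritance_modes(), "mitochondrial", "undefined", "unascertained",
    "digenic", "Y_linked")
}

#' Read a variant summary table
#'
#' The native exchange format is TSV with one row per biallelic,
#' left-normalized GRCh38 variant and ancestry-suffixed allele-count
#' columns: `variant_id` (`chrom:pos:ref:alt`), `gene`, `tier`, `filter`,
#' then `AC_<ancestry>` / `AN_<ancestry>` pairs. `#`-prefixed header
#' comments are allowed. A VCF v4.2 dialect is also accepted
#' (`dialect = "vcf"`): sites-only records carrying `AC_<ancestry>` and
#' `AN_<ancestry>` INFO keys (requires the vcfR package).
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param ancestries Registered ancestry codes the AC/AN columns may use.
#' @return A tibble of variant records; tier is a factor ordered by
#'   decreasing pathogenicity.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               ancestries = ancestry_codes()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "vcf") {
    tab <- read_variant_vcf(path, ancestries)
  } else {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  }
  validate_variant_table(tab, ancestries, where = path)
}

read_variant_vcf <- function(path, ancestries) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF dialect requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- tibble::tibble(
    variant_id = paste(fx$CHROM, fx$POS, fx$REF, fx$ALT, sep = ":"),
    gene = vcfR::extract.info(v, "GENE"),
    tier = vcfR::extract.info(v, "TIER"),
    filter = fx$FILTER)
  for (a in ancestries) {
    ac <- suppressWarnings(as.integer(vcfR::extract.info(v, paste0("AC_", a))))
    an <- suppressWarnings(as.integer(vcfR::extract.info(v, paste0("AN_", a))))
    if (all(is.na(ac)) && all(is.na(an))) next
    out[[paste0("AC_", a)]] <- ac
    out[[paste0("AN_", a)]] <- an
  }
  out
}

validate_variant_table <- function(tab, ancestries, where = "variant table") {
  need <- c("variant_id", "gene", "tier", "filter")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(where, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  acan <- grep("^A[CN]_", names(tab), value = TRUE)
  suff <- unique(sub("^A[CN]_", "", acan))
  bad <- setdiff(suff, ancestries)
  if (length(bad) > 0) {
    stop(where, ": unregistered ancestry column suffix(es): ",
         paste(bad, collapse = ", "))
  }
  odd <- suff[!(paste0("AC_", suff) %in% names(tab) &
                  paste0("AN_", suff) %in% names(tab))]
  if (length(odd) > 0) {
    stop(where, ": unpaired AC/AN column for ancestry ", paste(odd, collapse = ", "))
  }
  if (length(suff) == 0) stop(where, ": no AC_<ancestry>/AN_<ancestry> columns")
  badtier <- setdiff(unique(tab$tier), tier_levels())
  if (length(badtier) > 0) {
    stop(where, ": unknown tier token(s): ", paste(badtier, collapse = ", "))
  }
  tab$tier <- factor(tab$tier, levels = tier_levels())
  if (anyDuplicated(tab$variant_id) > 0) {
    stop(where, ": duplicate variant_id: ",
         paste(unique(tab$variant_id[duplicated(tab$variant_id)]), collapse = ", "))
  }
  for (a in suff) {
    ac <- tab[[paste0("AC_", a)]]
    an <- tab[[paste0("AN_", a)]]
    viol <- which(!is.na(ac) & !is.na(an) & (ac < 0 | an < 0 | ac > an))
    if (length(viol) > 0) {
      stop(where, ": AC > AN (or negative count) for ancestry ", a,
           " at row ", viol[1], " (variant ", tab$variant_id[viol[1]], ")")
    }
  }
  attr(tab, "ancestries") <- suff
  tab
}

# Ancestries a variant table carries AC/AN columns for.
variant_ancestries <- function(tab) {
  unique(sub("^AC_", "", grep("^AC_", names(tab), value = TRUE)))
}

# Chromosome token of each variant_id ("chrom:pos:ref:alt").
variant_chrom <- function(variant_id) {
  sub("^(chr)?([^:]+):.*$", "\\2", variant_id)
}

#' Write a variant table in the native TSV dialect
#'
#' @param tab Variant tibble as produced by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tab, path) {
  tab$tier <- as.character(tab$tier)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `symbol`, `protein_coding` (logical), `inheritance`,
#' `mechanism` (`LoF`/`GoF`/`LoF_GoF`), `sources` and `disease_groups`
#' (`;`-separated), plus optional flags `repeat_expansion_only`,
#' `mechanism_established`, `secondary_finding`, `sf_phenotype_group` and
#' `restricted_variant_ids` (`;`-separated). Inheritance accepts the
#' canonical modes, `AD/AR`, pseudoautosomal dominant/recessive (mapped to
#' AD/AR) and pre-curation states (`mitochondrial`, `undefined`, ...), which
#' survive until [curate_genes()] excludes them.
#'
#' @param path File path.
#' @return A tibble with list-columns `sources`, `disease_groups` and
#'   `restricted_variant_ids`.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("symbol", "inheritance", "mechanism", "sources", "disease_groups")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$symbol) > 0) {
    stop(path, ": duplicate gene symbol: ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))
  }
  tab$inheritance <- normalize_inheritance(tab$inheritance)
  badinh <- setdiff(unique(tab$inheritance), precuration_inheritance())
  if (length(badinh) > 0) {
    stop(path, ": unknown inheritance token(s): ", paste(badinh, collapse = ", "))
  }
  split_col <- function(x) {
    lapply(ifelse(is.na(x), "", x), function(s) {
      parts <- strsplit(s, ";", fixed = TRUE)[[1]]
      trimws(parts[nzchar(trimws(parts))])
    })
  }
  tab$sources <- split_col(tab$sources)
  tab$disease_groups <- split_col(tab$disease_groups)
  badgrp <- setdiff(unique(unlist(tab$disease_groups)), disease_groups())
  if (length(badgrp) > 0) {
    stop(path, ": unknown disease group(s) ", paste(badgrp, collapse = ", "),
         "; valid groups are: ", paste(disease_groups(), collapse = ", "))
  }
  for (flag in c("protein_coding", "repeat_expansion_only",
                 "mechanism_established", "secondary_finding")) {
    if (!flag %in% names(tab)) {
      tab[[flag]] <- switch(flag, protein_coding = TRUE,
                            mechanism_established = TRUE, FALSE)
    }
    tab[[flag]] <- as.logical(tab[[flag]])
  }
  if (!"sf_phenotype_group" %in% names(tab)) tab[[ "sf_phenotype_group" ]] <- NA_character_
  if ("restricted_variant_ids" %in% names(tab)) {
    tab$restricted_variant_ids <- split_col(tab$restricted_variant_ids)
  } else {
    tab$restricted_variant_ids <- rep(list(character(0)), nrow(tab))
  }
  tibble::as_tibble(tab)
}

#' Write a gene annotation table
#'
#' Serializes the list-columns back to `;`-separated strings so that the
#' file round-trips through [read_gene_annotations()].
#'
#' @param genes Gene annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(genes, path) {
  flat <- genes
  for (col in c("sources", "disease_groups", "restricted_variant_ids")) {
    if (col %in% names(flat) && is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ";")
    }
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Write the tables of a burden report to TSV files
#'
#' One file per report section, in a deterministic column order, with
#' full-precision fractions alongside their `"1 in x"` renderings where a
#' frequency column is present.
#'
#' @param report A `burden_report` as produced by [build_full_report()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_burden_tables <- function(report, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  files <- character(0)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (!is.data.frame(x)) next
    path <- file.path(outdir, paste0(nm, ".tsv"))
    tab <- x
    for (col in intersect(c("CrF", "GP", "CAF"), names(tab))) {
      shown <- tab[[col]] > 0 & !is.na(tab[[col]])
      one_in <- rep(NA_character_, nrow(tab))
      if (any(shown)) one_in[shown] <- format_one_in(tab[[col]][shown], "gene")
      tab[[paste0(col, "_one_in")]] <- one_in
    }
    for (col in names(tab)) if (is.list(tab[[col]])) {
      tab[[col]] <- vapply(tab[[col]], paste, character(1), collapse = ";")
    }
    if ("tier" %in% names(tab)) tab$tier <- as.character(tab$tier)
    readr::write_tsv(tab, path, progress = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}
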
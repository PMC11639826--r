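#' Canonical pathway names
#'
#' The eleven curated signaling pathways used throughout the package, in the
#' fixed order used to index pathway profiles, summary tables and plots:
#' cell cycle, Hippo, Myc, Notch, oxidative stress/Nrf2, PI3K, RTK/RAS/MAP,
#' TGF-beta, p53, beta-catenin/Wnt, and DNA damage response and repair (DDR).
#'
#' @return Character vector of length 11.
#' @export
pathway_names <- function() {
  c("cell_cycle", "hippo", "myc", "notch", "oxidative_stress_nrf2",
    "pi3k", "rtk_ras_map", "tgf_beta", "p53", "beta_catenin_wnt", "ddr")
}

#' Construct a pathway catalog
#'
#' A pathway catalog maps each of the eleven canonical pathways to a set of
#' member gene symbols. Pathway names are matched case-insensitively against
#' [pathway_names()] and reordered into canonical order; gene symbols are
#' uppercased, trimmed and deduplicated. A gene may belong to several pathways.
#'
#' @param gene_sets Named list of character vectors: pathway name -> genes.
#' @return A `pathway_catalog` object (named list of character vectors in
#'   canonical order).
#' @export
pathway_catalog <- function(gene_sets) {
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    stop("gene_sets must be a named list of gene symbol vectors")
  }
  canon <- pathway_names()
  got <- tolower(trimws(names(gene_sets)))
  missing <- setdiff(canon, got)
  extra <- setdiff(got, canon)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("catalog error: pathway set mismatch",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(got)) stop("catalog error: duplicated pathway names")
  out <- lapply(canon, function(p) {
    genes <- unique(toupper(trimws(gene_sets[[match(p, got)]])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("catalog error: pathway '", p, "' has no genes")
    genes
  })
  names(out) <- canon
  structure(out, class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat("Pathway catalog: 11 pathways,",
      length(unique(unlist(x))), "distinct genes\n")
  for (p in names(x)) cat(sprintf("  %-22s %3d genes\n", p, length(x[[p]])))
  invisible(x)
}

#' Default pathway catalog (synthetic stand-in)
#'
#' A best-effort stand-in gene catalog assembled from widely used curated
#' driver-gene lists for the eleven pathways. It exists so that synthetic
#' cohorts and examples are self-contained; for real analyses the catalog
#' should be read from a GMT file with [read_gmt()], which is treated as
#' authoritative. `ATM` appears in both the p53 and DDR sets, illustrating
#' that multi-pathway membership is legal.
#'
#' @return A `pathway_catalog`.
#' @export
default_catalog <- function() {
  pathway_catalog(list(
    cell_cycle = c("CDKN2A", "CDK4", "CDK6", "CCND1", "CCNE1", "RB1"),
    hippo = c("NF2", "LATS1", "LATS2", "FAT1"),
    myc = c("MYC", "MYCN", "MYCL", "MAX"),
    notch = c("NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4", "FBXW7", "CREBBP"),
    oxidative_stress_nrf2 = c("NFE2L2", "KEAP1", "CUL3"),
    pi3k = c("PIK3CA", "PIK3R1", "PTEN", "AKT1", "MTOR", "TSC1", "TSC2", "STK11"),
    rtk_ras_map = c("EGFR", "KRAS", "NRAS", "HRAS", "BRAF", "MAP2K1", "ALK",
                    "ERBB2", "MET", "RET", "ROS1", "NF1"),
    tgf_beta = c("SMAD4", "SMAD2", "SMAD3", "TGFBR1", "TGFBR2"),
    p53 = c("TP53", "MDM2", "MDM4", "ATM"),
    beta_catenin_wnt = c("CTNNB1", "APC", "AXIN1", "AXIN2", "TCF7L2"),
    ddr = c("BRCA2", "BRCA1", "ATM", "ATR", "CHEK1", "CHEK2", "PALB2",
            "RAD51", "MLH1", "MSH2", "MSH6", "PMS2", "POLE", "ERCC2", "FANCA")
  ))
}

#' Read a pathway catalog from a GMT file
#'
#' Standard GMT: one gene set per line, `name<TAB>description<TAB>gene...`.
#' Exactly the eleven canonical pathways must be present (case-insensitive
#' name match); they are reordered canonically and genes deduplicated.
#'
#' @param path Path to a GMT file.
#' @return A `pathway_catalog`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  pathway_catalog(fgsea::gmtPathways(path))
}

#' Write a pathway catalog to a GMT file
#'
#' @param catalog A `pathway_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  lines <- vapply(names(catalog), function(p) {
    paste(c(p, "na", catalog[[p]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Genes belonging to exactly one pathway
#'
#' Used by the synthetic generator so that an emitted mutation record maps
#' back to exactly the pathway bit it was sampled for.
#'
#' @param catalog A `pathway_catalog`.
#' @return Named list (per pathway) of genes unique to that pathway.
#' @export
unique_pathway_genes <- function(catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  all_genes <- unlist(catalog, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  out <- lapply(catalog, function(g) setdiff(g, shared))
  if (any(vapply(out, length, integer(1)) == 0)) {
    stop("catalog has a pathway with no pathway-unique gene; ",
         "the synthetic generator cannot use it")
  }
  out
}
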
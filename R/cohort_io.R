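# Readers and writers for the three standard inputs (mutation TSV, clinical
# TSV, GMT) and the network artifacts. TSV dialect: tab-separated, UTF-8,
# "." or empty cell = missing.

.smoking_levels <- c("never", "former", "current")
.response_levels <- c("CR", "PR", "SD", "PD", "NE")

.parse_bool <- function(x, column, lines) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "1", "yes")] <- TRUE
  out[x %in% c("false", "0", "no")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop("unparseable boolean in column '", column, "' at line ",
         paste(lines[bad], collapse = ", "))
  }
  out
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c(".", ""),
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a somatic mutation table
#'
#' MAF-lite TSV with columns `patient_id`, `gene`, `variant_label` (optional),
#' `cosmic_pathogenic`, `clinvar_pathogenic`. Gene symbols are uppercased and
#' trimmed; booleans accept true/false, 1/0, yes/no (case-insensitive). Row
#' order is preserved.
#'
#' @param path Path to the TSV file.
#' @return Data frame of mutation records.
#' @export
read_mutations <- function(path) {
  df <- .read_tsv(path, c("patient_id", "gene",
                          "cosmic_pathogenic", "clinvar_pathogenic"))
  n <- nrow(df)
  lines <- seq_len(n) + 1L  # header is line 1
  out <- data.frame(
    patient_id = trimws(df$patient_id),
    gene = toupper(trimws(df$gene)),
    variant_label = if ("variant_label" %in% names(df)) df$variant_label
                    else rep(NA_character_, n),
    cosmic_pathogenic = .parse_bool(df$cosmic_pathogenic, "cosmic_pathogenic", lines),
    clinvar_pathogenic = .parse_bool(df$clinvar_pathogenic, "clinvar_pathogenic", lines),
    stringsAsFactors = FALSE
  )
  if (n > 0 && any(!nzchar(out$patient_id))) {
    stop("validation error: empty patient_id at line ",
         paste(lines[!nzchar(out$patient_id)], collapse = ", "))
  }
  if (n > 0 && any(!nzchar(out$gene))) {
    stop("validation error: empty gene at line ",
         paste(lines[!nzchar(out$gene)], collapse = ", "))
  }
  out
}

#' Read a clinical table
#'
#' TSV with columns `patient_id`, `smoking_status` (never/former/current),
#' `tmb` (Mut/Mb), `pdl1_pct` (optional), `os_months`, `os_event`,
#' `pfs_months`, `pfs_event`, `best_response` (CR/PR/SD/PD/NE). Times and TMB
#' must be non-negative; `pfs_months <= os_months` is deliberately NOT
#' enforced, since real assessment schedules can violate it.
#'
#' @param path Path to the TSV file.
#' @return Data frame of patient records, input row order preserved.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path, c("patient_id", "smoking_status", "tmb", "os_months",
                          "os_event", "pfs_months", "pfs_event", "best_response"))
  n <- nrow(df)
  lines <- seq_len(n) + 1L
  pid <- trimws(df$patient_id)
  smoking <- tolower(trimws(df$smoking_status))
  bad <- which(!is.na(smoking) & !(smoking %in% .smoking_levels))
  if (length(bad) > 0) {
    stop("validation error: unknown smoking_status '", df$smoking_status[bad[1]],
         "' for patient ", pid[bad[1]])
  }
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  tmb <- num("tmb"); osm <- num("os_months"); pfm <- num("pfs_months")
  for (v in list(list(tmb, "tmb"), list(osm, "os_months"), list(pfm, "pfs_months"))) {
    neg <- which(!is.na(v[[1]]) & v[[1]] < 0)
    if (length(neg) > 0) {
      stop("validation error: negative ", v[[2]], " for patient ", pid[neg[1]])
    }
  }
  resp <- toupper(trimws(df$best_response))
  resp[is.na(resp)] <- "NE"
  badr <- which(!(resp %in% .response_levels))
  if (length(badr) > 0) {
    stop("validation error: unknown best_response '", df$best_response[badr[1]],
         "' for patient ", pid[badr[1]])
  }
  pdl1 <- if ("pdl1_pct" %in% names(df)) num("pdl1_pct") else rep(NA_real_, n)
  if (any(!is.na(pdl1) & (pdl1 < 0 | pdl1 > 100))) {
    stop("validation error: pdl1_pct outside [0, 100]")
  }
  out <- data.frame(
    patient_id = pid,
    smoking_status = smoking,
    tmb = tmb,
    pdl1_pct = pdl1,
    os_months = osm,
    os_event = .parse_bool(df$os_event, "os_event", lines),
    pfs_months = pfm,
    pfs_event = .parse_bool(df$pfs_event, "pfs_event", lines),
    best_response = resp,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$patient_id)) {
    stop("validation error: duplicated patient_id: ",
         out$patient_id[anyDuplicated(out$patient_id)])
  }
  out
}

.format_bool <- function(x) ifelse(x, "true", "false")

#' Write a mutation table
#' @param mutations Mutation data frame (see [read_mutations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  df <- mutations
  df$cosmic_pathogenic <- .format_bool(df$cosmic_pathogenic)
  df$clinvar_pathogenic <- .format_bool(df$clinvar_pathogenic)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a clinical table
#' @param patients Patient data frame (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(patients, path) {
  df <- patients
  df$os_event <- .format_bool(df$os_event)
  df$pfs_event <- .format_bool(df$pfs_event)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble a cohort
#'
#' Bundles patients, mutations and the pathway catalog, checking that every
#' mutation's patient appears in the clinical table and patient ids are unique.
#'
#' @param patients Patient data frame.
#' @param mutations Mutation data frame.
#' @param catalog A `pathway_catalog`.
#' @return A `cohort` object.
#' @export
cohort <- function(patients, mutations, catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  if (anyDuplicated(patients$patient_id)) {
    stop("cohort error: duplicated patient_id")
  }
  orphan <- setdiff(mutations$patient_id, patients$patient_id)
  if (length(orphan) > 0) {
    stop("cohort error: mutations for unknown patient(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  structure(list(patients = patients, mutations = mutations, catalog = catalog),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ns <- sum(x$patients$smoking_status == "never")
  cat("Cohort:", nrow(x$patients), "patients (", ns, "never-smokers ),",
      nrow(x$mutations), "mutation records\n")
  invisible(x)
}

#' Write a cohort as the three standard input files
#'
#' Writes `mutations.tsv`, `clinical.tsv` and `pathways.gmt` under `dir`,
#' the exact formats the readers consume (round-trip property).
#'
#' @param x A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mutations(x$mutations, file.path(dir, "mutations.tsv"))
  write_clinical(x$patients, file.path(dir, "clinical.tsv"))
  write_gmt(x$catalog, file.path(dir, "pathways.gmt"))
  invisible(dir)
}

#' Read a cohort from a directory of standard input files
#' @param dir Directory containing `mutations.tsv`, `clinical.tsv`, `pathways.gmt`.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  cohort(read_clinical(file.path(dir, "clinical.tsv")),
         read_mutations(file.path(dir, "mutations.tsv")),
         read_gmt(file.path(dir, "pathways.gmt")))
}

#' Write a similarity network to GraphML and an edge list
#'
#' The GraphML file carries node attributes (patient id, TMB, TMB class,
#' smoking status and, when a partition is supplied, community label) and the
#' edge attribute `weight`. The edge-list variant is a plain 3-column TSV
#' `(i, j, weight)` using patient ids, weights printed with full precision.
#'
#' @param net A `similarity_network` (see [build_similarity_network()]).
#' @param path Output path; the edge list is written to `<path>.edges.tsv`
#'   unless `edge_path` is given.
#' @param patients Optional patient data frame for node attributes.
#' @param strata Optional stratification data frame (see [stratify()]).
#' @param partition Optional `community_partition`.
#' @param edge_path Optional explicit edge-list path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, patients = NULL, strata = NULL,
                          partition = NULL, edge_path = NULL) {
  stopifnot(inherits(net, "similarity_network"))
  ids <- net$patient_ids
  if (length(ids) == 0) stop("empty network: nothing to write")
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$patient_id <- ids
  if (!is.null(patients)) {
    idx <- match(ids, patients$patient_id)
    igraph::V(g)$tmb <- patients$tmb[idx]
    igraph::V(g)$smoking_status <- patients$smoking_status[idx]
  }
  if (!is.null(strata)) {
    idx <- match(ids, strata$patient_id)
    igraph::V(g)$tmb_class <- strata$tmb_class[idx]
  }
  if (!is.null(partition)) {
    igraph::V(g)$community <- partition$assignment[ids]
  }
  igraph::write_graph(g, path, format = "graphml")
  if (is.null(edge_path)) edge_path <- paste0(path, ".edges.tsv")
  ut <- which(upper.tri(net$W), arr.ind = TRUE)
  el <- data.frame(i = ids[ut[, 1]], j = ids[ut[, 2]],
                   weight = sprintf("%.17g", net$W[ut]))
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3-column edge list written by [write_network()]
#' @param path Edge-list TSV path.
#' @return Data frame with columns `i`, `j`, `weight` (numeric).
#' @export
read_edge_list <- function(path) {
  df <- .read_tsv(path, c("i", "j", "weight"))
  df$weight <- as.numeric(df$weight)
  df
}
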
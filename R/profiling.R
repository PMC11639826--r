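# Pathway-level mutational profiling: deleterious-mutation filtering, binary
# 11-pathway profiles, TMB / smoking stratification, and the per-stratum
# summary table of mutated-pathway counts.

#' Filter deleterious mutations
#'
#' A mutation is deleterious when it is flagged pathogenic in COSMIC and/or
#' ClinVar (the database lookups are frozen into the two boolean input
#' columns). The default rule is OR — either database's pathogenic call
#' suffices; `rule = "and"` requires both. Row order is preserved.
#'
#' @param mutations Mutation data frame.
#' @param rule `"or"` (default) or `"and"`.
#' @return Filtered mutation data frame.
#' @export
filter_deleterious <- function(mutations, rule = c("or", "and")) {
  rule <- match.arg(rule)
  keep <- if (rule == "or") {
    mutations$cosmic_pathogenic | mutations$clinvar_pathogenic
  } else {
    mutations$cosmic_pathogenic & mutations$clinvar_pathogenic
  }
  mutations[keep, , drop = FALSE]
}

#' Build per-patient binary pathway profiles
#'
#' For each patient, bit p is 1 iff the patient carries at least one
#' deleterious mutation in a member gene of pathway p. A gene belonging to
#' two pathways sets both bits; duplicated mutation rows are harmless (set
#' semantics); patients with no qualifying mutations get the all-zero
#' profile. Mutated genes absent from every pathway are ignored.
#'
#' @param x A `cohort`.
#' @param deleterious_only If `TRUE` (default), apply [filter_deleterious()]
#'   first; set `FALSE` to count every detected mutation.
#' @param rule Pathogenicity rule passed to [filter_deleterious()].
#' @return Integer matrix (patients x 11), rownames = patient ids, colnames =
#'   [pathway_names()], entries in {0, 1}.
#' @export
build_pathway_profiles <- function(x, deleterious_only = TRUE, rule = "or") {
  stopifnot(inherits(x, "cohort"))
  ids <- x$patients$patient_id
  muts <- x$mutations
  if (deleterious_only) muts <- filter_deleterious(muts, rule = rule)
  prof <- matrix(0L, nrow = length(ids), ncol = 11,
                 dimnames = list(ids, pathway_names()))
  for (p in pathway_names()) {
    hit <- muts$patient_id[muts$gene %in% x$catalog[[p]]]
    prof[unique(hit), p] <- 1L
  }
  prof
}

#' Stratify patients by TMB and smoking status
#'
#' TMB class is `"H"` iff `tmb > tmb_cutoff` (strictly; the boundary value is
#' low-TMB). Smoking class is `"S"` for current or former smokers by default,
#' `"NS"` otherwise.
#'
#' @param patients Patient data frame.
#' @param tmb_cutoff TMB cutoff in Mut/Mb; default 10.
#' @param smoker_classes Smoking statuses counted as smokers.
#' @return Data frame with columns `patient_id`, `tmb_class`, `smoking_class`,
#'   `subgroup` (one of `"S/H"`, `"S/L"`, `"NS/H"`, `"NS/L"`).
#' @export
stratify <- function(patients, tmb_cutoff = 10,
                     smoker_classes = c("former", "current")) {
  stopifnot(tmb_cutoff > 0)
  if (anyNA(patients$tmb)) {
    stop("stratification error: missing tmb for patient ",
         patients$patient_id[which(is.na(patients$tmb))[1]])
  }
  tmb_class <- ifelse(patients$tmb > tmb_cutoff, "H", "L")
  smoking_class <- ifelse(patients$smoking_status %in% smoker_classes, "S", "NS")
  data.frame(
    patient_id = patients$patient_id,
    tmb_class = tmb_class,
    smoking_class = smoking_class,
    subgroup = paste(smoking_class, tmb_class, sep = "/"),
    stringsAsFactors = FALSE
  )
}

# Round half away from zero, the convention used for printed percentages.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-pathway mutated-patient counts by smoking class
#'
#' For each pathway and smoking class: the number of patients with at least
#' one deleterious mutation in the pathway, and the percentage of the class
#' (rounded half-up to one decimal). An empty class yields `NA` percentages.
#'
#' @param profiles Profile matrix from [build_pathway_profiles()].
#' @param strata Stratification data frame from [stratify()].
#' @return Data frame: `pathway`, `S_count`, `S_pct`, `NS_count`, `NS_pct`.
#' @export
pathway_summary <- function(profiles, strata) {
  if (!setequal(rownames(profiles), strata$patient_id)) {
    stop("profiles and strata must cover the same patients")
  }
  cls <- strata$smoking_class[match(rownames(profiles), strata$patient_id)]
  count_pct <- function(which_class) {
    sub <- profiles[cls == which_class, , drop = FALSE]
    n <- nrow(sub)
    cnt <- colSums(sub)
    pct <- if (n > 0) round_half_up(100 * cnt / n, 1) else rep(NA_real_, ncol(sub))
    list(count = as.integer(cnt), pct = pct)
  }
  s <- count_pct("S"); ns <- count_pct("NS")
  data.frame(pathway = pathway_names(),
             S_count = s$count, S_pct = unname(s$pct),
             NS_count = ns$count, NS_pct = unname(ns$pct),
             row.names = NULL, stringsAsFactors = FALSE)
}
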
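#!/usr/bin/env Rscript
# Pathway enrichment of the four reported patient subgroups of the fixture
# cohort — high-TMB, never-smokers, smoker/high-TMB, never-smoker/high-TMB —
# each against the whole cohort, with BH correction across the 11 pathways
# of each family.

suppressMessages(library(psnpath))

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fx <- build_realworld_fixture()
prof <- build_pathway_profiles(fx)
st <- stratify(fx$patients)

subgroups <- list(
  htmb = st$patient_id[st$tmb_class == "H"],
  never_smokers = st$patient_id[st$smoking_class == "NS"],
  s_htmb = st$patient_id[st$subgroup == "S/H"],
  ns_htmb = st$patient_id[st$subgroup == "NS/H"])

for (nm in names(subgroups)) {
  e <- enrich_pathways(prof, subgroups[[nm]])
  write.table(e, file.path(out, paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- e$pathway[e$significant]
  cat(sprintf("%-14s n = %3d: %s\n", nm, length(subgroups[[nm]]),
              if (length(sig)) paste(sig, collapse = ", ") else
                "no significant pathway"))
}

e_nsh <- enrich_pathways(prof, subgroups$ns_htmb)
ddr <- e_nsh[e_nsh$pathway == "ddr", ]
cat(sprintf("NS/H DDR: k = %d of n = %d vs K = %d of N = %d, p = %.2e, q = %.2e\n",
            ddr$k, ddr$n, ddr$K, ddr$N, ddr$p_value, ddr$q_value))
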
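# psnpath

Patient similarity networks from pathway-level somatic mutation profiles,
for immunotherapy cohort analysis.

## What this solves

In advanced non-small cell lung cancer treated with PD-1 blockade, tumor
mutation burden (TMB) and smoking history are entangled: smokers usually
carry high TMB, never-smokers low TMB. Never-smokers whose TMB nevertheless
exceeds the conventional 10 Mut/Mb cutoff are a small, clinically striking
group, and the hypothesis this pipeline operationalizes is that defects in
DNA damage response and repair (DDR) genes both explain their mutation load
and mark them as immunotherapy responders.

`psnpath` provides the full analysis chain as tested, reusable functions:

1. **Profiling** — classify deleterious mutations (pathogenic in COSMIC
   and/or ClinVar, frozen into input flags) and collapse them to a binary
   vector `x ∈ {0,1}^11` over eleven curated signaling pathways (cell cycle,
   Hippo, Myc, Notch, oxidative stress/Nrf2, PI3K, RTK/RAS/MAP, TGF-β, p53,
   β-catenin/Wnt, DDR); stratify by TMB (`H` iff TMB > 10 Mut/Mb, strictly)
   and smoking status.
2. **Enrichment** — upper-tail hypergeometric test of each pathway in a
   patient subgroup against a background, `P(X ≥ k) = Σ_j C(K,j) C(N−K,n−j)
   / C(N,n)`, with Benjamini–Hochberg FDR across the 11 pathways of each
   comparison family.
3. **Network** — Euclidean distances between profiles, edge weights from the
   locally scaled exponential kernel
   `W_ij = exp(−D_ij² / (μ ε_ij))`, `ε_ij = (d̄_i + d̄_j + D_ij)/3`
   (`d̄_i` = mean distance to the k nearest neighbors), Louvain community
   detection with restarts on the full weighted graph.
4. **Characterization & outcomes** — per-community mutated-pathway
   percentages, Kruskal–Wallis TMB comparison, high-TMB hypergeometric
   enrichment, Spearman profile correlation with Monte-Carlo permutation
   p-values, Kaplan–Meier curves and medians, log-rank tests, ORR/DCR,
   reverse-KM median follow-up.
5. **Synthetic data** — a stochastic cohort generator with a planted
   never-smoker/high-TMB DDR-boosted subgroup, and a deterministic fixture
   cohort whose published marginal counts hold exactly, so everything above
   runs without access to patient-level data.

Inputs are plain files: a MAF-lite mutation TSV (`patient_id`, `gene`,
`cosmic_pathogenic`, `clinvar_pathogenic`, optional `variant_label`), a
clinical TSV (smoking status, TMB, OS/PFS with event flags, RECIST best
response), and a GMT gene-set file for the eleven pathways
(`inst/extdata/pathways_default.gmt` ships a synthetic stand-in catalog).

## Worked example

```r
library(psnpath)

fx <- build_realworld_fixture()        # deterministic 142-patient cohort
prof <- build_pathway_profiles(fx)     # 142 x 11 binary matrix
st <- stratify(fx$patients)            # TMB x smoking strata

# pathway summary by smoking class (the published-table layout)
tab <- pathway_summary(prof, st)
tab[tab$pathway == "ddr", ]
#>   pathway S_count S_pct NS_count NS_pct
#>       ddr      21  18.9       14   45.2

# never-smoker/high-TMB subgroup enrichment vs the whole cohort
nsh <- st$patient_id[st$subgroup == "NS/H"]
length(nsh)                            # 11 patients
e <- enrich_pathways(prof, nsh)
e[e$pathway %in% c("ddr", "beta_catenin_wnt"), c("pathway", "k", "n", "p_value", "q_value")]
#>            pathway k  n      p_value     q_value
#>   beta_catenin_wnt 5 11 0.0006268806 0.003513600
#>                ddr 8 11 0.0006388363 0.003513600

# similarity network of the 31 never-smokers + Louvain communities
net <- build_similarity_network(prof[st$patient_id[st$smoking_class == "NS"], ])
part <- detect_communities(net, seed = 1, n_restarts = 100)
part
#> Community partition: 5 communities, Q = 0.4786

# the DDR-richest community is all high-TMB
cp <- community_profiles(part, prof[net$patient_ids, ])
c1 <- cp[which.max(cp$ddr), ]
c1[, c("community", "size", "ddr", "cell_cycle")]
#>   community size ddr cell_cycle
#>           1    6 100        100
htmb_enrichment(part, st, c1$community)$p_value
#> [1] 0.0006274778

# outcomes in the never-smoker/high-TMB subgroup
idx <- match(nsh, fx$patients$patient_id)
response_rates(fx$patients$best_response[idx])$orr_pct   # 100
km_estimate(fx$patients$os_months[idx], fx$patients$os_event[idx])$median
#> [1] 27.95
```

Reading the numbers: 14 of 31 never-smokers (45.2%) carry a deleterious DDR
mutation versus 21 of 111 smokers (18.9%); among the 11 never-smokers above
10 Mut/Mb, 8 are DDR-mutated, and against the 142-patient background both
DDR and β-catenin/Wnt clear FDR 0.05 (q ≈ 0.0035). The never-smoker network
isolates a community of 6 patients, every one high-TMB (hypergeometric
p = 6.3e-4) and every one DDR-mutated, with a 100% objective response rate
and median OS of 27.95 months in the surrounding NS/H subgroup — the
DDR-signature pattern the pipeline is built to surface.

## Analysis scripts

`analysis/01_build_cohorts.R` … `05_calibration.R` run the pipeline as a
narrative sequence (cohort construction, enrichment, networks, outcomes,
calibration of the stochastic machinery) and write their tables under
`results/`. Each is a thin driver over the package functions:

```sh
Rscript analysis/01_build_cohorts.R
Rscript analysis/02_enrichment.R
# ...
```

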
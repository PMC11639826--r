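Package: psnpath
Title: Patient Similarity Networks from Pathway-Level Somatic Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway-level profiling of somatic mutation data for immunotherapy
    cohorts: classifies deleterious mutations, builds per-patient binary profiles
    over eleven curated signaling pathways, stratifies patients by tumor mutation
    burden and smoking status, tests pathway enrichment in patient subgroups
    (hypergeometric test with Benjamini-Hochberg false discovery rate control),
    constructs weighted patient similarity networks with a locally scaled
    exponential kernel, partitions them with Louvain community detection, and
    characterizes communities by mutational profile, tumor mutation burden, and
    survival and response endpoints. Includes a synthetic cohort generator and a
    deterministic synthetic fixture cohort matching published marginal counts so
    the full pipeline runs without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    fgsea,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
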
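---
title: "Pathway-level patient similarity networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level patient similarity networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnpath)
```

## The problem

Advanced non-small cell lung cancer (aNSCLC) patients with high PD-L1
expression receive first-line pembrolizumab, but response varies widely.
Tumor mutation burden (TMB, somatic coding mutations per megabase) predicts
response imperfectly, and it is confounded with smoking: smokers typically
have high TMB, never-smokers low TMB. The interesting patients are the
exceptions — never-smokers with TMB above the conventional 10 Mut/Mb cutoff —
because whatever drives their mutation load without tobacco exposure (most
plausibly defects in DNA damage response and repair, DDR) may itself shape
immunotherapy response.

`psnpath` implements the analysis pipeline for this question: it re-expresses
each patient's somatic mutation calls as a binary profile over eleven curated
signaling pathways, stratifies patients by TMB and smoking status, tests
pathway over-representation in patient subgroups, builds a patient similarity
network (PSN) per smoking stratum, partitions it into communities, and
characterizes the communities molecularly (mutated-pathway percentages, TMB)
and clinically (survival, response).

## The model, step by step

### Pathway profiles

A mutation is *deleterious* when it is flagged pathogenic in COSMIC and/or
ClinVar. The database lookups are frozen into two boolean input columns so
the pipeline is reproducible offline; the disjunction is the default because
either database's pathogenic call is standardly sufficient, and the stricter
conjunction is available via `filter_deleterious(rule = "and")`.

Patient $i$'s profile is $x_i \in \{0,1\}^{11}$ over the fixed pathway order
(cell cycle, Hippo, Myc, Notch, oxidative stress/Nrf2, PI3K, RTK/RAS/MAP,
TGF-β, p53, β-catenin/Wnt, DDR): $x_{ip} = 1$ iff patient $i$ carries at
least one deleterious mutation in a member gene of pathway $p$. Membership
is by exact uppercase symbol match against a GMT catalog; a gene may sit in
several pathways (e.g. `ATM` in both p53 and DDR) and then sets several
bits. Only the deleterious-only reading of "mutated pathway" is used by
default (`deleterious_only = TRUE`), since the classification step exists
precisely to restrict to pathogenic calls; counting all detected mutations
is a toggle.

The bundled `default_catalog()` is a synthetic stand-in assembled from
widely used driver-gene lists; the GMT file supplied by the user is always
treated as authoritative.

### Stratification

TMB class is high iff `tmb > 10` strictly — a boundary value of exactly
10 Mut/Mb is low-TMB. Former smokers count as smokers. Both choices are
configuration fields (`stratify()`), and TMB is always an input, never
recomputed from mutation counts, because panel-size normalization belongs to
the assay, not this pipeline.

### Subgroup enrichment

For each pathway, over-representation of mutated patients in a subgroup of
size $n$ against a background of size $N$ with $K$ mutated is the upper-tail
hypergeometric probability

$$P(X \ge k) \;=\; \sum_{j=k}^{\min(n,K)}
  \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

computed by log-gamma summation (exact to double precision at cohort
scales; verified against direct enumeration in the tests). Only the
one-sided over-representation test is offered. The eleven pathways of one
comparison form the BH-FDR family; families are never pooled across
comparisons, matching per-comparison FDR reporting.

**Background choice.** The background of a subgroup comparison defaults to
the whole cohort. This was a genuinely open design point; the parent-stratum
background was considered and rejected because it cannot reproduce the
headline result at the published counts: with 14 of 31 never-smokers
DDR-mutated and 8 of the 11 never-smoker/high-TMB patients DDR-mutated, the
never-smoker background gives $p = 0.0275$, which no BH adjustment over 11
pathways can bring under 0.05 once β-catenin/Wnt ($p = 0.0027$) occupies the
top rank — whereas the whole-cohort background gives $p = 6.4\times10^{-4}$
(DDR) and $6.3\times10^{-4}$ (Wnt), both $q \approx 0.0035$. The background
remains an explicit argument of `enrich_pathways()`, so stratum-internal
comparisons are one call away. The flip side of a whole-cohort background is
a smoking confound, discussed under *Limitations*.

### The similarity network

Profiles are compared by Euclidean distance (for binary vectors,
$\sqrt{\text{Hamming}}$, at most $\sqrt{11}$). Distances become edge weights
through a locally scaled exponential kernel,

$$W_{ij} = \exp\!\left(-\frac{D_{ij}^2}{\mu\,\varepsilon_{ij}}\right),
\qquad
\varepsilon_{ij} = \frac{\bar d_i + \bar d_j + D_{ij}}{3},$$

where $\bar d_i$ is the mean distance from $i$ to its $k$ nearest neighbors.
The local bandwidth $\varepsilon_{ij}$ adapts to density: a pair that is
mutually close relative to its neighborhoods gets a high weight even if the
absolute distance is moderate. Defaults are $k = \min(n-1, 20)$ and
$\mu = 0.5$, the middle of the kernel's conventional ranges ($k$ 10–30,
$\mu$ 0.3–0.8); both are exposed because the method description fixes
neither. Degenerate identical neighborhoods ($\varepsilon_{ij} = 0$, which
forces $D_{ij} = 0$) get weight 1 by continuity. Binary profiles collide
often; duplicate profiles are legal, receive weight 1, and co-cluster under
any strong partition — this is property-tested rather than assumed.

### Community detection

Louvain modularity maximization runs on the **full** weighted graph — no
k-nearest-neighbor sparsification, since the method description mentions
none (an option exists upstream of the call for users who want it, by
zeroing weights before `detect_communities()`). Louvain is greedy and
order-dependent, so the implementation restarts it `n_restarts = 100` times
with consecutive seeds and keeps the partition with the highest classic
(resolution-1) modularity $Q$, ties to the lowest seed; the resolution
parameter (default $\gamma = 1$) only steers the search. Labels are
canonical — 0-based, size-descending, ties by smallest member index — so
"community 0" is reproducible across runs. A stratum is declared to lack
community structure when the best partition is trivial (one community) or
its $Q$ falls below 0.05.

### Community characterization

Each community is summarized by its mutated-pathway percentage vector, its
TMB distribution (tie-corrected Kruskal–Wallis across communities, with the
all-values-identical degenerate case returning $H = 0$, $p = 1$ and a flag),
and its high-TMB enrichment (hypergeometric, background = the smoking
stratum the network was built on). Cross-cohort comparison of two community
profiles uses Spearman correlation; because the profiles have length 11 and
tie-rich ranks, the p-value is estimated against the permutation null by
Monte Carlo (default $10^6$ permutations, fixed seed, accurate to about
three decimals) rather than the rough $t$ approximation.

### Survival and response

Kaplan–Meier estimation, log-rank tests and reverse-KM median follow-up are
delegated to the `survival` package, with the conventions pinned down here:
the KM median is the smallest observed time with $S(t) \le 0.5$; tied events
and censorings process events first; the log-rank statistic is the
unweighted Mantel–Haenszel chi-square on $g-1$ degrees of freedom. ORR is
the percentage of CR+PR, DCR adds SD; patients with best response NE stay in
the denominator by default (conservative), with a toggle to drop them. For
the survival comparison of merged communities, pooled two-group log-rank is
the default mode (a three-group test is the same call with different
labels).

## The synthetic data

No patient-level data are deposited, so the package carries two synthetic
artifacts with different jobs.

**The deterministic fixture** (`build_realworld_fixture()`) is a seed-free
142-patient cohort whose published marginals hold *exactly*: 111 smokers /
31 never-smokers; all 22 per-pathway mutated-patient counts by smoking
class; stratum TMB medians 8 and 4 Mut/Mb (never-smoker maximum 39.09,
smoker range 0–55, 53 patients above 10 Mut/Mb); an 11-patient
never-smoker/high-TMB subgroup with median TMB 16.39, 8 of 11 DDR-mutated
and 11/11 objective responders. The never-smoker profiles are arranged in
four blocks (a dense high-TMB block with DDR/cell-cycle/RTK/p53/Notch/Nrf2/Wnt
co-mutation, an RTK+p53 block, a cell-cycle+RTK+p53 block, and a weak
block) so the similarity network reproduces the qualitative community
pattern; the smoker profiles are a greedy striped completion of the
marginals. Within-patient co-occurrence beyond these constraints is
unconstrained by the published tables, so this is one valid completion among
many — conclusions that depend on co-occurrence outside the never-smoker
blocks (for instance *which* pathways come out enriched in the smoker/high-TMB
family) are fixture artifacts, not reproductions. Survival times are
deterministic grids calibrated so the KM medians land near the reported
values (overall OS 18.3, PFS 12.2, follow-up 17.05, never-smoker/high-TMB OS
27.95 months; the fixture achieves 18.12, 12.21, 17.30, 27.95). These
reported medians, and every other externally derived number, are available
as `calibration_targets()`, each row flagged `verifiable_here = FALSE`:
they are inputs to the synthesis, never validation truth.

**The stochastic generator** (`generate_cohort()`) samples smoking status
(smoker fraction 111/142), independent per-pathway Bernoulli bits at the
published per-stratum frequencies, log-normal TMB with stratum medians 8
and 4 Mut/Mb (log-scale SD 0.9, a spread consistent with the published
ranges), exponential survival parameterized by subgroup medians with uniform
administrative censoring at 12–36 months, and RECIST categories from
per-class multinomials. A planted never-smoker/high-TMB subgroup (size 11,
TMB forced above the cutoff around median 16.39) gets boosted DDR and
β-catenin/Wnt probabilities and an all-responder response mix. The DDR boost
defaults to 0.9: the two observed subgroup rates are 8/11 (73%) in the
discovery cohort and 17/18 (94%) in the validation cohort, and 0.9 sits in
that range; the Wnt boost is 0.5. Pathway bits are independent given the
stratum — the generator reproduces marginals and the planted signature, not
the co-mutation correlation structure of real tumors. Mutation records are
emitted with one pathogenic call per set bit in a gene *unique* to that
pathway, so profiles rebuild exactly from the written files (round-trip
property); Poisson passenger records with both pathogenicity flags false
exercise the filtering path.

What passing tests on these cohorts shows: the machinery is correct at its
contracts (exact counts, exact probabilities, deterministic partitions,
calibrated detection rates). What it does not show: anything about real
tumor biology — gene-level recurrence, pathway co-occurrence, non-Bernoulli
mutation processes, informative censoring, or assay noise are all absent
from the generator by construction.

**Planted partitions** (`generate_planted_partition()`) drive the community
detection calibration: four blocks of sizes 8/4/7/12, templates chosen as
the four maximally separated binary codewords in 11 bits (pairwise Hamming
distance ≥ 7, the Plotkin bound), independent bit flips at 0.05. Under
these conditions the pipeline recovers the blocks with adjusted Rand index
1.0 in 95 of 100 fixed seeds; the misses are seeds where a deviating
partition (typically splitting off a heavily flipped patient) genuinely has
*higher* modularity than the planted one, so they are properties of the
noise realization, not search failures — more restarts do not change them.

## Positive and negative enrichment controls

With the planted subgroup present, the never-smoker/high-TMB DDR q-value
clears 0.05 in ≈ 98% of seeds (48–49/50 at the fixed test seeds). The
negative control removes the planted subgroup entirely
(`planted_size = 0`), so the subgroup under test is just the never-smokers
whose sampled TMB exceeds the cutoff; DDR is then non-significant in ≈ 98%
of seeds. The alternative "null" — keep the forced 11-patient high-TMB
subgroup but drop the boost — is *not* null under a whole-cohort
background: its members still mutate DDR at the never-smoker base rate
(45.2%) against a ≈ 25% cohort background, a real enrichment the test
correctly finds in ≈ 16% of seeds. That is the smoking confound of
whole-cohort backgrounds in miniature, and the reason stratum-internal
backgrounds remain a supported option even though the headline analysis
uses the cohort background.

## Numerical choices and degenerate inputs

* Hypergeometric tails by log-gamma summation over the support; `K = 0`
  gives $p = 1$; preconditions outside $0 \le k \le \min(n, K)$ are domain
  errors, not silent clamps.
* Printed percentages round half away from zero to one decimal, matching
  the published table formatting; full precision is kept internally.
* The Kruskal–Wallis tie correction is undefined when all values coincide;
  the implementation returns $H = 0$, $p = 1$ with a `degenerate` flag.
* Zero-variance community profiles make Spearman correlation undefined —
  explicit error rather than `NA` propagation.
* Strata with fewer than 3 patients skip network construction with a
  warning (a 2-node network has no community structure to find).
* All stochastic steps take explicit seeds; `generate_cohort()` and
  friends restore the caller's RNG state.

## Problem sizes

The shipped analyses and tests run at the study's own scales: 142-patient
cohorts, 31- and 111-node networks, 100 restarts per Louvain call, 100
seeds for the recovery calibration and 50 per enrichment control, $10^5$ to
$10^6$ permutations for Spearman p-values, and exhaustive hypergeometric
verification up to $N = 60$. A structurally similar validation-scale cohort
(853 patients, never-smoker fraction 0.16) can be generated with
`generator_config(n_patients = 853L, smoker_fraction = 713/853, planted_size = 18L)`.

## Known limitations

* Gene symbols match by exact uppercase string equality; no alias or
  identifier mapping.
* Pathogenicity is an input flag; no live database queries, no HGVS
  validation.
* The enrichment layer offers only the pathway-level 2×2 hypergeometric
  test — no permutation or gene-level burden testing.
* The network is single-layer; no similarity-network fusion across data
  types.
* Statistics published for the external validation trials (e.g. the DDR
  enrichment $p = 0.0297$ at 17/18 mutated, the community-profile
  correlation $\rho = 0.727$) require that cohort's patient-level data and
  are therefore out of reach of any synthetic reconstruction here; they are
  recorded in `calibration_targets()` as context, never asserted. The same
  applies to figure-only quantities, which are not printed numerically and
  are deliberately not encoded anywhere.
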
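---
title: "Connectivity mapping for signature reversal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity mapping for signature reversal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

## The scientific problem

Drug repositioning by transcriptomic signature reversal asks: among a
library of compounds, each profiled by RNA-seq under several experimental
conditions (cell context x dose) against vehicle controls, which compound's
transcriptional effect *opposes* a disease's case-versus-control expression
signature? A compound that drives the genes a disease pushes up back down
(and vice versa) is predicted to "normalise" the disease state and is a
repositioning candidate. The canonical application is a small clinic-ready
compound library screened against a steatohepatitis (NASH) biopsy
signature, where the decision rule is that a credible candidate must show
*significantly negative connectivity in every condition it was profiled
under*, and must rank near the top when the strength of its connection is
compared across the whole library.

`sigrev` implements this analysis end to end — differential signatures,
rank-based connectivity with permutation FDR, cross-condition inverse
concordance, library percentile ranking, directional GSEA validation, a
simplified upstream-regulator chain — together with a synthetic-data
generator that plants a known drug–disease reversal, so every stage can be
validated against ground truth.

## The synthetic study generator

`synthetic_config()` describes a study: `n_compounds` compounds (one
planted, the rest decoys) x `n_conditions` conditions, plus `n_diseases`
diseases (one target, the rest decoys). Counts are negative binomial
(`size = 1/dispersion`) around lognormal per-gene baselines shared by the
whole study; `ground_truth()` fixes the planted effect genes (sampled
without replacement) and their fair-coin directions. The planted compound
shifts its effect genes' log2 means by `±effect_size` at high dose and half
that at low dose; cell contexts share the effect and differ only in noise
draws — the simplest structure under which concordance across all four
conditions is achievable and testable. The target disease mirrors the
planted compound: same effect genes, opposite directions, magnitude
`reversal_strength * effect_size`. Decoy compounds and diseases draw
independent effect genes of the same magnitude, so decoys are not merely
flat noise — they carry real but unrelated signal, which is what makes
uniqueness of the planted call a meaningful test.

Defaults are chosen once to emulate the intended study scale: 2,000 genes,
150 effect genes, log2 effect 2 at high dose, reversal strength 0.5,
51 compounds x 4 conditions, 10 diseases, NB dispersion 0.1 (a typical
bulk RNA-seq overdispersion), lognormal baselines with meanlog 5 and
sdlog 1.5 (median ~150 counts, a realistic dynamic range), 5 samples per
compound arm, and 12 cases vs 5 controls per disease cohort — the size of
the small biopsy cohort this design emulates. Every draw derives from
`seed` plus a stable per-entity offset, so outputs are pure functions of
the configuration and adding entities never perturbs existing ones.

What the generator does *not* emulate: library-size artefacts, batch
effects, GC bias, correlated gene modules, or the real cohorts' expression
values. Passing tests therefore demonstrate the *machinery* — calibration,
ranking, recovery under a known planted structure — not performance on any
real dataset.

## Differential signatures

`differential_signature()` normalises counts to CPM, applies
`log2(CPM + 0.5)`, and computes a moderated two-sample t: each gene's
pooled variance is shrunk toward the across-gene mean variance with prior
weight `prior_df = 10`, and p-values come from the t distribution on
`prior_df + residual` degrees of freedom. This is a deliberate,
self-contained ranking statistic, not a count-model GLM: the connectivity
machinery only needs a well-calibrated gene ranking, and the moderation
stabilises small-sample variances the standard way. Pseudocount (0.5) and
prior df (10) are conventional and configurable. Under the null
(effect size 0) the p-value distribution passes a uniformity KS test at
α = 0.01 on 2,000 genes, which the suite asserts.

Tag sets (`signature_gene_sets()`) come in two modes because published
pipelines differ: size mode (top/bottom `n_top` by statistic — used for
connectivity, default 100) and FDR-cutoff mode (q below a threshold, split
by fold-change sign — mirroring a p < 0.05 FDR tag-set rule). Ranked lists
break statistic ties by ascending gene identifier, making every downstream
score reproducible across platforms.

## Connectivity scoring

`ks_enrichment()` is the classic signed Kolmogorov–Smirnov tag-set
statistic. With the `t` retained tag positions `V(1) < … < V(t)` in a list
of length `n`:

- `a = max_j ( j/t − V(j)/n )` (deviation above uniform — tags near the top),
- `b = max_j ( V(j)/n − (j−1)/t )` (deviation below — tags near the bottom),

and the ES is `a` if `a ≥ b`, else `−b` (the `a = b` tie takes the positive
branch — arbitrary but fixed). The connectivity score of an up/down pair is
`(es_up − es_down)/2` when the two enrichments disagree in sign, and 0 when
they agree (including either being exactly 0): a compound whose up- and
down-tags move the same way in a disease is uninterpretable as reversal or
mimicry. Negative scores mean predicted normalisation. The statistic itself
is the standard rank-based connectivity formulation; the package documents
it as an interpretation of "modified connectivity mapping", not a
reproduction of any proprietary variant.

### Permutation significance: a deliberate design choice

The null redraws both tag sets jointly (disjoint, without replacement) and
rescores. Significance is two-sided on the magnitude of the *un-zeroed*
half-difference `(es_up − es_down)/2`, for both observed and null values,
while the reported score keeps the sign-opposition zeroing. The reason is
calibration: under the null the zeroed score has an atom of probability
≈ 1/2 at exactly 0, so a p-value defined on the zeroed statistic piles half
its mass at p = 1 and can never be uniform — and uniform null p-values are
exactly what Benjamini–Hochberg FDR control and the package's own
calibration tests require. The un-zeroed statistic is continuous and
symmetric under the null, so its permutation p-values are uniform by
construction. One consequence is documented rather than hidden: a pair
whose score is zeroed can still carry a small p; concordance calls are
unaffected because they require `score < 0` *and* `q` below threshold.

### Pooled null and FDR

`score_library()` pools null draws across all pairs within strata of
identical geometry (list length, retained tag sizes); each pair contributes
`n_perm` draws and is referred to the pooled sample. Because the null
distribution of the statistic depends on the pair only through that
geometry, pooling is statistically exact here, and it sharpens the
attainable p resolution from `1/(n_perm+1)` to roughly
`1/(n_perm x stratum size)`. This matters arithmetically: with per-pair
nulls of 1,000 draws, the best attainable BH q over a 2,040-pair run is
about 0.5 — no hit could ever reach q < 0.01. With pooling, the planted
pair reaches q ≈ 2.5e-4 in the standard study. BH is applied once per run
(one family), the simplest defensible reading of a library-wide FDR
threshold; rows failing tag coverage (< 25% of tags retained) are flagged
and excluded from the family.

`concordant_inverse()` is strict: every expected condition present, every
score negative, every q strictly below threshold (exactly-at-threshold
fails); a missing condition is incomplete evidence, an error rather than a
quiet FALSE. `percentile_rank()` ranks scores ascending with ties sharing
the best rank, so the top compound of 51 sits at 100 x 1/51 ≈ 1.96%. The
compound-level score used for ranking is the mean across the compound's
conditions for the disease in question — an aggregate was needed, the
choice is documented here, and the per-condition table is always available.

## GSEA validation

`gsea_es()` is the weighted running-sum enrichment statistic (hit
increments `|r|^exponent`, normalised; miss increments `1/(n−t)`; ES = the
signed maximum absolute deviation, ties to the positive branch). At
exponent 0 it reduces to the unweighted statistic and is checked exactly
against a brute-force walk; at exponent 1 it agrees with an independent
implementation to machine precision. Significance uses gene-set
permutation — the package scores external ranked profiles whose
sample-level data it does not ingest, and gene-set permutation is the
standard choice in that situation. NES divides the ES by the mean |ES| of
same-signed null values. `signature_direction_panel()` calls a disease
profile *inverse* when the drug's up-tags are depleted and down-tags
enriched (both FDRs below threshold, default 0.05), *concordant* for the
mirror configuration, *null* otherwise.

## Upstream regulators

The expression-to-kinases chain is implemented in its standard simplified
form: one-sided hypergeometric overrepresentation of a DEG list in a
TF→targets library (`fisher_enrichment()`, exact and testable against
enumeration), expansion of the enriched TFs through an undirected
protein-interaction network (`expand_network()`: every node on a simple
path of length ≤ 2, by default, between two distinct seeds), and
hypergeometric kinase→substrate enrichment of the subnetwork
(`kinase_enrichment()`). Libraries are user-supplied GMT files; toy
libraries are constructed in the test suite. No attempt is made to match
any hosted tool's databases or composite scores.

## Histology metrics

`nafld_activity_score()` composes NAS = steatosis (0–3) + ballooning (0–2)
+ lobular inflammation (0–3); fibrosis stage and portal inflammation are
carried separately and never summed. Group-mean mode accepts fractional
components because published tables report fractional means; per-animal
mode enforces integers. `group_summary()` reports mean ± SEM
(sd/√n, n−1 denominator). Note that published group tables built from
rounded per-animal means need not be internally additive; the package
asserts the formula, not any particular printed row.

## Numerical choices and degenerate inputs

- Ties in ranked lists break by ascending gene identifier; the KS and GSEA
  tie-at-extremes both take the positive branch. Fixed, documented,
  asserted.
- Tag genes absent from a ranked list are dropped; below 25% retention the
  pair is flagged rather than scored.
- Zero residual variance in a contrast yields stat 0 (p 1) when the means
  agree and ±Inf (p 0) when they differ.
- Single-sample arms return fold-changes with tests flagged unavailable.
- A useful algebraic subtlety the tests encode: under list reversal the KS
  enrichment negates exactly (up to 1/n) *except* when the two branch
  maxima `a` and `b` lie within 2/n of each other — inside that tie window
  the dominant branch can swap and only the magnitude is preserved. The
  property tests assert the exact provable form (magnitudes always within
  `1/t + 1/n`; signed negation outside the tie window).

## Problem sizes

The validation suite runs the standard study at 2,000 genes,
51 compounds x 4 conditions, 10 diseases, tag sets of 100, and 1,000
permutation draws per pair (pooled); the null-calibration study uses 13
compounds (520 pairs) with all effects zeroed; the recovery sweep runs one
planted compound at effect sizes {0.5, 1, 2, 4}. These sizes exercise the
full machinery at the scale the design emulates while keeping a complete
run in the minutes range on a single core.

## Known limitations

- The moderated t with a fixed prior df is mildly miscalibrated when
  per-gene variances are strongly heterogeneous (very low-count genes); at
  the simulated depths this stays within the asserted uniformity tolerance.
- Gene-set permutation nulls (connectivity and GSEA) test tag-set
  *position* structure, not inter-gene correlation; with strongly
  correlated modules in real data they are anti-conservative, which is one
  reason the cross-condition concordance requirement exists.
- The percentile aggregate (mean across conditions) is one of several
  defensible choices (best condition, median); changing it only requires a
  different aggregate over the per-condition table.
- Decoy compounds share the planted compound's effect-gene count and
  magnitude; real libraries have heterogeneous potencies.
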
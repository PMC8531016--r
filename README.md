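# sigrev

Transcriptomic signature reversal for computational drug repositioning.

## What it does

Given a library of drug perturbation signatures (treated vs vehicle
RNA-seq, one signature per compound-condition) and a library of disease
signatures (case vs control), `sigrev` finds compounds whose
transcriptional effect *opposes* a disease profile — candidates predicted
to normalise the disease state. The package implements:

- **Differential signatures** — moderated t on log2 CPM: each gene's pooled
  variance is shrunk toward the across-gene mean with prior df
  `d0` (default 10); `t_g = log2FC_g / sqrt(s̃²_g (1/n₁ + 1/n₂))`,
  p from t on `d0 + residual` df, Benjamini–Hochberg q.
- **Connectivity scoring** — the signed KS tag-set statistic. For tag
  positions `V(1)<…<V(t)` in a ranked list of length `n`,
  `a = max_j(j/t − V(j)/n)`, `b = max_j(V(j)/n − (j−1)/t)`, ES = `a` if
  `a ≥ b` else `−b`; score = `(ES_up − ES_down)/2`, zeroed when the two
  enrichments share a sign. Negative score = predicted reversal.
  Permutation significance with a pooled empirical null and one BH family
  per run.
- **Inverse concordance** — a compound is called only when *every*
  condition scores negative with q strictly below threshold
  (default FDR < 0.01).
- **Library percentile ranking** — compound-level mean score, ascending
  ranks, ties share the best rank.
- **Directional GSEA** — weighted running-sum ES with gene-set permutation
  null and NES, calling disease profiles inverse / concordant / null.
- **Upstream regulators** — hypergeometric TF enrichment of a DEG list,
  interaction-network expansion of the enriched TFs (simple paths of
  length ≤ 2 between seeds), kinase-substrate enrichment of the subnetwork.
- **Histology metrics** — NAFLD activity score composition
  (NAS = steatosis + ballooning + lobular inflammation, 0–8) and
  mean ± SEM group summaries.
- **Synthetic studies** — a negative-binomial generator that plants a known
  drug–disease reversal (decoy compounds and diseases carry independent
  real effects), so the whole pipeline is validated against ground truth.

File formats are the community standards: expression TSV, GMT gene sets,
RNK ranked lists, CSV results.

## Worked example

A complete seeded study: 51 compounds (one planted) x 4 conditions
against 10 diseases (one the planted mirror), scored and ranked.

```r
library(sigrev)

cfg <- synthetic_config(n_genes = 2000, n_effect_genes = 150,
                        effect_size = 2, reversal_strength = 0.5,
                        n_compounds = 51, n_conditions = 4,
                        n_diseases = 10, seed = 101)
truth <- ground_truth(cfg)
lib   <- generate_compound_library(cfg, truth)
dis   <- generate_disease_library(cfg, truth)

drug_sets <- lapply(lib, function(cc) signature_gene_sets(
  differential_signature(cc$treated, cc$control), n_top = 100))
disease_ranked <- lapply(dis, function(d)
  ranked_list(differential_signature(d$case, d$control)))

conn <- score_library(drug_sets, disease_ranked, n_perm = 1000, seed = 101)
conn[conn$compound == truth$planted_compound_id &
     conn$disease == truth$target_disease_id, ]
#>    compound  condition disease   es_up es_down    score            p            q n_perm flag
#> 1    cpd001 cellA_high   dis01 -0.5810  0.7255 -0.65325 4.901958e-07 0.0002499999 2040000
#> 11   cpd001  cellA_low   dis01 -0.4910  0.6045 -0.54775 4.901958e-07 0.0002499999 2040000
#> 21   cpd001 cellB_high   dis01 -0.5935  0.7365 -0.66500 4.901958e-07 0.0002499999 2040000
#> 31   cpd001  cellB_low   dis01 -0.5510  0.6145 -0.58275 4.901958e-07 0.0002499999 2040000

concordant_inverse(conn, truth$planted_compound_id,
                   truth$target_disease_id)$inverse_concordant
#> [1] TRUE

head(rank_compounds(conn, truth$target_disease_id), 3)
#>    compound      score percentile
#> 1    cpd001 -0.6121875   1.960784
#> 48   cpd048 -0.0923750   3.921569
#> 6    cpd006 -0.0662500   5.882353
```

All four planted-pair conditions score strongly negative (the drug's
up-tags sit at the bottom of the disease ranking and vice versa) at
q ≈ 2.5e-4, the planted compound is the only one called
inverse-concordant, and it ranks 1st of 51 — the 1.96th percentile.
`run_pipeline(cfg, "outdir")` runs the same flow and writes results plus a
provenance manifest; `nas_summary()` handles histology score tables.

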
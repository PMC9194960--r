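# lncImmNet

Immune-related lncRNA discovery, lncRNA–pathway networks, and immune
subtyping for small inflammation cohorts (built around the inflamed
dental pulp / pulpitis setting, where public microarray series have only
5–7 samples per condition).

## What it computes

For a paired lncRNA/mRNA log2 expression bundle with a
`normal`/`pulpitis` design:

1. **Moderated differential expression** — per-gene two-group fit with
   empirical-Bayes variance shrinkage (`s² ~ s₀² F(df, d₀)`, prior
   estimated by digamma/trigamma moment inversion), BH FDR, and the dual
   rule `adj_p < α`, `|log2FC| ≥ lfc`.
2. **lncRES scoring** — for each lncRNA, every mRNA gets a rank score
   `RS = −log10(P) · sign(CC)` from its correlation with the lncRNA; the
   ranked mRNA list is tested against each of 17 immune gene-set
   categories by weighted Kolmogorov–Smirnov enrichment with a
   gene-permutation p-value, transformed to
   `lncRES = 1 − 2p` (ES > 0) or `2p − 1` (ES < 0).
   Pairs with `lncRES > 0.995` and `FDR < 0.05` are significant; a
   lncRNA with any significant pair is *immune-related*.
3. **Network export** — the same enrichment against pathway collections
   (e.g. MSigDB hallmark), exported as a bipartite lncRNA–pathway edge
   list in SIF and GraphML.
4. **Consensus-clustering subtypes** — subsampled hierarchical consensus
   clustering (reps = 1000, pItem = 0.8, pFeature = 1, euclidean) of
   immune-related differential lncRNA expression over the pulpitis
   cohort, with CDF-delta-area k selection, PCA validation and top-50
   subtype-gene export.
5. **Immune profiles** — per-sample gene-set variation scores for the 17
   immune categories, marker-mean immune-cell abundance scores, and
   exact Wilcoxon comparisons between subtypes.
6. **Synthetic worlds** — a seeded generator that plants known
   immune-related lncRNAs (latent-factor co-expression at an exact
   target correlation), differential genes and immune subtypes, so every
   stage is testable against ground truth without any download.

## Worked example

```r
library(lncImmNet)

cfg <- synth_config(seed = 42)        # 5 normal + 7 pulpitis, 300 lnc, 2000 mRNA
sim <- generate_bundle(cfg)
sim$bundle
#> expression_bundle: 300 lncRNAs, 2000 mRNAs, 12 samples (normal=5, pulpitis=7)

de  <- de_analysis(sim$bundle$lnc, sim$bundle$design$condition)
sum(de$significant)                   # DElncRNAs
#> 39

rec <- lncres_score(sim$bundle$lnc, sim$bundle$mrna, sim$immune_sets,
                    nperm = 1000, seed = 42)
imm <- immune_lnc_ids(rec)
length(imm)                           # immune-related lncRNAs
#> 185
intersect_with_de(imm, de$gene[de$significant])$n_overlap
#> 30
sum(sim$truth$planted_lnc_ids %in% imm)   # all 20 planted drivers found
#> 20

mat <- sim$bundle$lnc[unlist(sim$truth$marker_lnc_ids),
                      names(sim$truth$subtype_labels)]
res <- consensus_cluster(mat, k_range = 2:5, reps = 1000, seed = 42)
res
#> consensus_result: k in {2,3,4,5}, selected k = 2, 7 samples
#> cluster
#> 1 2
#> 4 3
adjusted_rand_index(sim$truth$subtype_labels, res$labels)
#> [1] 1
```

Reading the numbers: all 20 planted co-expression drivers are recovered
(sensitivity 1.0) and the planted 4/3 subtype split is recovered exactly
(ARI 1), but 185 lncRNAs are called immune-related — far more than the
20 planted — because at 12 samples many noise lncRNAs correlate by
chance with a set's shared latent factor and then carry a genuine
coherent enrichment the gene-permutation null cannot discount. Calls at
this sample size are co-expression candidates, to be validated across
cohorts (`overlap_validation()` against a `replication_config()` bundle)
and experimentally.

## Pipeline CLI

```sh
Rscript inst/cli/lncimmnet.R --stage all --outdir out --seed 1
# or stage by stage, with a JSON config overriding any default:
Rscript inst/cli/lncimmnet.R --stage simulate --config my.json --outdir out
```

Artifacts (TSV/SIF/GraphML/JSON) and a `manifest.json` recording config,
seeds and per-stage outputs land in `--outdir`; reruns with the same
config and seeds reproduce the analysis tables byte-identically.

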
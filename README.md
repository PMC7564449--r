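# cernaweaver

Discovery and validation of trait-linked competing-endogenous-RNA (ceRNA)
networks from bulk expression cohorts.

## The problem

In IDH-mutant oligodendroglioma, the 1p/19q codeletion marks a subgroup
with distinctly better overall survival, and part of its expression
signature is thought to run through ceRNA circuits: a long non-coding RNA
(or pseudogene) shares miRNA response elements with an mRNA, sponges the
shared miRNA, and thereby de-represses the mRNA. Finding such circuits
from expression data takes a long chain of standard steps — filtering,
differential expression, co-expression modules, target matching, cluster
validation, survival analysis — each with thresholds that matter.
`cernaweaver` packages that chain as tested, reusable, seed-deterministic
functions, together with a synthetic-cohort generator that plants known
structure so every stage can be validated against ground truth.

## The method

Given raw counts for coding RNA/lncRNA/pseudogenes, miRNA RPM, a clinical
table and miRNA–target interaction tables, the pipeline:

1. **Preprocess** — drop outlier samples (mean inter-sample Spearman
   correlation < 0.6 on log2 counts), normalize counts (library-size to
   the median library plus a composition-robust median-of-ratios
   correction), remove the lowest quartile of genes by mean, drop genes
   where one patient holds more than a third of the gene's total, filter
   miRNAs with mean RPM < 3 and move survivors to log2(RPM + 1).
2. **Differential expression** — per-gene Wilcoxon rank-sum between the
   two subgroups, Benjamini–Hochberg FDR within each biotype class; calls
   at |log2FC| > 1 and FDR < 0.05 (both strict).
3. **Co-expression modules** — signed weighted network on the DE genes of
   each direction: adjacency `a_ij = (0.5 (1 + cor(i,j)))^beta` with
   `beta = 4` (a 1–20 scan with the scale-free fit index is available),
   topological overlap, average-linkage dendrogram, dynamic tree cut
   (minimum module size 15), eigengene merging at dissimilarity 0.3, and
   Pearson module-eigengene/trait correlations. The module with the
   largest |r| is the key module.
4. **ceRNA assembly** — one candidate network per DE miRNA of direction
   opposite the key module, its targets restricted to key-module members
   supported by the (union-combined) interaction tables; a network needs
   at least one coding and one non-coding target.
5. **Validation** — Ward clustering (k = 2 for a two-subgroup cohort,
   k = 3 for three) of samples on each network's coding genes, scored
   against the clinical subgroups by adjusted Rand index; networks with
   ARI > 0.6 are retained.
6. **Survival** — (miRNA, ceRNA) pairs with Pearson r < −0.3, exact 1-D
   2-means high/low expression split, Kaplan–Meier medians with log-log
   Greenwood 95% CIs, log-rank p, BH FDR across all pairs in the cohort.

Everything is driven by one configuration object (`cerna_config()`), and
all randomness flows from its `rng_seed`.

## Worked example

```r
library(cernaweaver)

res <- run_cerna_pipeline(cerna_config(rng_seed = 7), simulate = TRUE,
                          output_dir = "run7")
res
#> <cw_pipeline> run at run7
#>   DEGs: 217 genes, 13 miRNAs
#>   networks built: 8 | retained: 8
#>   survival pairs: 17 | FDR<0.05: 15

head(res$evaluation[, c("network_id", "mirna_id", "n_coding", "n_nc",
                        "ari", "retained")], 3)
#>   network_id mirna_id        n_coding  n_nc   ari retained
#> 1 Network01  hsa-sim-miR-001       12     2 1     TRUE
#> 2 Network07  hsa-sim-miR-007       12     2 1     TRUE
#> 3 Network08  hsa-sim-miR-008       14     2 1     TRUE

head(tibble::as_tibble(res$survival)[, c("mirna_id", "cerna_id",
                                         "pearson_r", "median_high",
                                         "median_low", "fdr")], 2)
#>   mirna_id        cerna_id pearson_r median_high median_low     fdr
#> 1 hsa-sim-miR-001 LNC006      -0.475       6448.      4618. 0.00213
#> 2 hsa-sim-miR-005 LNC006      -0.429       6448.      4618. 0.00213
```

The synthetic cohort (168 samples, 127 codel / 41 noncodel) plants eight
sponge miRNAs in a codeletion-coupled module. The run recovers all eight
as networks, every one concordant with the subgroups (ARI near 1), and
the sponge lncRNAs stratify survival: high-expression patients' median
overall survival is ~1800 days longer, at FDR ~0.002. `res$truth` holds
the planted ground truth for comparison; `autoplot()` methods draw
volcano, module-trait, ARI and Kaplan–Meier figures.

A thin command-line wrapper lives at `inst/scripts/cerna-weaver.R`
(subcommands `simulate` and `run-all`); every intermediate stage is an
exported function (`preprocess_mrna()`, `differential_test()`,
`wgcna_modules()`, `build_cerna_networks()`, `evaluate_networks()`,
`survival_stratification()`).

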
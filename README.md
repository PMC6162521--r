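# tissueIFS

Classification of human tissues from bulk RNA-seq expression profiles via
**quantitatively tissue-specific expressed genes** — genes expressed in all
or most tissues whose expression *level*, not presence, separates tissues.
Catalogues of tissue-enriched genes (high in one tissue, absent elsewhere)
miss this population entirely; tissueIFS finds a compact panel of such
genes and quantifies its discriminative power.

The package is aimed at computational biologists working with
genes × samples expression matrices (RPKM or comparable non-negative
units, e.g. a GTEx-style 25-tissue panel) who want a reproducible,
fully testable implementation of the following pipeline:

1. **Filtering** — drop tissues with fewer than 80 samples, then genes
   with no non-zero value in any sample.
2. **mRMR ranking** — discretize each gene into three states around
   mean ± α·SD, then rank genes greedily by minimum-redundancy
   maximum-relevance mutual information against the tissue label:
   pick argmax *I*(f; c) first, then repeatedly the gene maximizing
   *I*(f; c) − mean<sub>s∈S</sub> *I*(f; s) (MID; MIQ quotient form
   available).
3. **Incremental feature selection (IFS)** — score growing prefixes
   F_i = [f1 … fi] of the ranked list (default i = 4..500) with a
   degree-1 polynomial-kernel SVM (SMO-type solver, C = 1, tolerance
   0.001, one-vs-one voting, per-feature min–max normalization fitted on
   training folds only) under stratified 10-fold cross-validation, and
   keep the prefix with the highest multiclass Matthews correlation
   coefficient.
4. **Measurement** — Gorodkin's multiclass MCC
   (cov(X,Y)/√(cov(X,X)·cov(Y,Y)) over truth/prediction indicator
   matrices), per-tissue accuracies ACC_j = n_j/N_j and overall accuracy
   TACC = Σn_j/ΣN_j.
5. **Baselines** — any externally supplied gene list, and the union of
   per-tissue top-19 one-vs-rest Welch t-test genes, evaluated under the
   identical cross-validation harness.

A synthetic-data generator (`generateDataset`) plants known quantitative,
tissue-enriched and noise genes on a log-normal background shaped like the
25-tissue panel (sample sizes 83..1259), so every stage is validated
end-to-end without external downloads.

## Worked example

```r
library(tissueIFS)

spec <- syntheticSpec(nTissues = 6, samplesPerTissue = 20, nQuantGenes = 10,
                      nEnrichedGenes = 0, nNoiseGenes = 100, effectSd = 1.5,
                      seed = 7)
tes <- generateDataset(spec)
tes
#> TissueExpressionSet: 110 genes x 120 samples, 6 tissues
#>   samples/tissue: T1=20 T2=20 T3=20 T4=20 T5=20 T6=20
#>   planted roles: noise=100 quantitative=10

disc   <- discretizeExpression(tes)                 # 3 states at mean ± 1·SD
ranked <- rankFeaturesMRMR(disc, tissueLabels(tes), topN = 40)
ranked
#> RankedFeatures: 40 genes, criterion MID
#>   top: QGENE0006, QGENE0005, QGENE0008, NGENE00068, QGENE0009 ...
sum(geneRoles(tes)[ranking(ranked)[1:10]] == "quantitative")
#> [1] 8

curve <- runIFS(tes, ranked, iMin = 4, iMax = 40, step = 2,
                params = svmParams(logTransform = TRUE), seed = 1)
opt <- selectOptimal(curve, ranked)
opt$result
#> CVResult over 6 tissues, 120 samples
#>   TACC = 0.9083   MCC = 0.8904
#>   ACC_j range: 0.7000 .. 1.0000
opt$size
#> [1] 12
```

Of the ten planted level-shifted genes, eight head the mRMR list (the
other two are diluted by 100 noise genes at this small sample size), and
the IFS scan finds its best 10-fold cross-validated MCC of 0.89 using the
top 12 ranked genes — a compact panel recovering most of the planted
signal. `runPipeline()` wires all stages together (including an optional
independent test split) and writes ranked lists, the IFS curve and
per-tissue reports to a run directory;
`inst/scripts/tissueifs.R` exposes `simulate`, `run-all` and `evaluate`
subcommands for shell use.

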
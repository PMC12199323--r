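# driverSigDR

Predicting how sensitive a cancer cell line is to a drug — its LN IC50 —
is a central problem in pharmacogenomics: screens such as GDSC measure
hundreds of thousands of cell–drug pairs, and a model that generalizes to
unmeasured pairs, unseen cell lines or unseen drugs can prioritize
compounds long before a wet-lab screen. driverSigDR implements a
driver-signal-informed deep learning approach to this problem, for
computational biologists working with expression, mutation and compound
structure data.

## The method

The premise is that drug response is shaped by how cancer driver
mutations perturb the pathway state of the cell, not by mutation status
alone. The pipeline therefore has two stages.

**Characterization.** Driver genes are placed as seeds on a
high-confidence protein–protein interaction network (edges supported by
at least two independent sources; largest connected component) and
diffused by random walk with restart,

    c^{t+1} = (1 − β) T c^t + β c⁰,     β = 0.9,

where `T` is the column-normalized adjacency (`T[i,j] = P[i,j]/deg(j)`)
and `c⁰` puts equal mass on the mapped drivers; iteration stops when the
max-norm change drops below 1e-10. The converged scores rank every gene
by its proximity to the driver signal. Preranked GSEA screens a pathway
collection against this ranking, and pathways with ES > 0 and FDR < 0.2
form the signature; each cell line's expression profile is then reduced
to per-pathway activities by single-sample GSEA (ssGSEA).

**Prediction.** Binary driver-mutation profiles and 1024-bit circular
(Morgan) drug fingerprints are each compressed by an autoencoder
(dense–batchnorm–ReLU encoder, mirrored sigmoid decoder; widths chosen by
a grid search over {300,200,100}×{100,50,30}×{30,20,10} on held-out
reconstruction BCE). A feedforward network regresses LN IC50 from the
concatenated activities and embeddings, trained end to end with Adam
(learning rate 1e-3, early stopping with patience 10, at most 100 epochs)
under the unified loss

    L = MSE(S, S′) + λ_C·BCE(R_C, R_C′) + λ_D·BCE(R_D, R_D′),   λ = 1.

Evaluation covers pair-level ("mix"), unseen-cell, unseen-drug and
doubly-unseen ("both") splits, Monte Carlo cross-validation, regression
metrics (PCC, RMSE) and lowest-quartile sensitive/insensitive
classification (AUROC, F1). Trained models are interpreted with
integrated gradients over the predictor input, and mutation-embedding
dimensions are annotated by correlation-ranking GSEA against the pathway
collection.

A seeded synthetic-cohort generator (`simulateCohort()`) produces a
modular gene network whose modules double as planted pathways, driver
genes concentrated in response-relevant modules, and LN IC50 built from
pathway-activity, mutation and drug latents plus noise — so the whole
pipeline can be validated end to end without external data. See the
methods vignette (`vignettes/driver-signal-drug-sensitivity.Rmd`) for
every modeling choice and its rationale.

## Worked example

```r
library(driverSigDR)

co <- simulateCohort(cohortSpec(nGenes = 200, nCells = 50, nDrugs = 10,
                                nPathways = 10, nDecoys = 5,
                                nDriverGenes = 20, nDriverModules = 3,
                                nBits = 128, seed = 7))
co
#> SyntheticCohort: 200 genes x 50 cells; 10 drugs; 500 pairs; 15 gene sets ( 10 planted )

res <- runFull(co, strategy = "mix",
               config = list(batchSize = 64L, maxEpochs = 40L, patience = 10L),
               characterizeArgs = list(nPerm = 300), seed = 11)
res$signature
#> PathwaySignature: 4 pathways (es > 0 , fdr < 0.2 )
#>     pathway size        es      pValue        fdr
#>  pathway_02   20 0.7833333 0.006451613 0.01838235
#>  pathway_03   20 0.7388889 0.006535948 0.01838235
#>  pathway_01   20 0.7111111 0.005714286 0.01838235
#>  pathway_04   20 0.4444444 0.007352941 0.01838235
str(res$metrics)
#> List of 5
#>  $ pcc  : num 0.821
#>  $ rmse : num 1.17
#>  $ auroc: num 0.946
#>  $ f1   : num 0.526
#>  $ n    : int 50
```

The signature recovers planted driver-module pathways (the cohort's
drivers sit in modules 1–3, and pathways 01–03 head the table with
positive enrichment at FDR ≈ 0.02). On the held-out 10% of pairs the
trained model reaches Pearson correlation 0.82 against observed LN IC50
with RMSE 1.17; AUROC 0.95 and F1 0.53 score the lowest-quartile
(sensitive) classification derived from the same predictions.

A thin command-line wrapper over these functions is provided at
`inst/scripts/driversig-dr.R` (subcommands `simulate`, `characterize`,
`train`, `explain`).

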
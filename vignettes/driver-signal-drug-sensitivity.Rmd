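---
title: "Driver-signal-informed drug-sensitivity prediction: methods and design notes"
author: "driverSigDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver-signal-informed drug-sensitivity prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

driverSigDR predicts the log-scale half-maximal inhibitory concentration
(LN IC50) of a drug acting on a cancer cell line from three feature blocks:

1. **Pathway activities.** Cancer driver genes are used as seeds for a
   random walk with restart (RWR) on a high-confidence protein interaction
   network: starting from the seed distribution $c^0$ (equal mass on mapped
   drivers), the walk iterates
   $c^{t+1} = (1-\beta)\,T\,c^t + \beta\,c^0$ with restart probability
   $\beta = 0.9$ and the column-stochastic transition matrix
   $T_{ij} = P_{ij}/\mathrm{deg}(j)$, until successive iterates differ by
   less than $10^{-10}$ in the max norm. The converged score of a gene
   measures how strongly the driver signal reaches it. The ranked score
   list is screened against a pathway collection with preranked GSEA; the
   pathways with enrichment score $> 0$ and FDR $< 0.2$ (both strict) form
   the signature. Each cell line's expression profile is then summarized as
   a per-pathway activity vector with single-sample GSEA (ssGSEA,
   rank-weighted with exponent $\alpha = 0.25$).
2. **Mutation embedding.** The binary driver-mutation profile of a cell is
   compressed by a 3-layer autoencoder (two hidden layers and a bottleneck,
   each dense layer followed by batch normalization and ReLU; the decoder
   mirrors the encoder and ends in a sigmoid so reconstructions lie in
   $(0,1)$).
3. **Drug embedding.** The 1024-bit folded circular (Morgan/ECFP4)
   fingerprint of the drug is compressed by a second autoencoder of the
   same design.

A feedforward regressor takes the concatenation of the activity vector and
the two bottleneck embeddings, passes it through two hidden layers of the
same width as its input (batch normalization + ReLU) and a single linear
output neuron, and is trained **end to end** together with both
autoencoders under the unified loss

$$\mathcal{L} \;=\; \mathrm{MSE}(S, S') \;+\; \lambda_C\,
\mathrm{BCE}(R_C, R_C') \;+\; \lambda_D\, \mathrm{BCE}(R_D, R_D'),
\qquad \lambda_C = \lambda_D = 1,$$

where $S, S'$ are observed and predicted LN IC50 and the BCE terms are the
mean binary cross-entropies of the two reconstructions. The reconstruction
terms regularize the embeddings toward information-preserving codes.

Trained models are interpreted with integrated gradients over the
predictor's input layer, and mutation-embedding dimensions are annotated
by correlating each dimension with gene expression across cells and
running preranked GSEA on the resulting correlation ranking.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `minSources` | 2 | distinct source databases required per PPI edge |
| `beta` | 0.9 | RWR restart probability; higher keeps mass nearer the seeds |
| `tol` | 1e-10 | max-norm convergence threshold of the RWR iteration |
| `maxIter` | 10000 | RWR safety cap (non-convergence is flagged, not an error) |
| `exponent` | 1 (`gsea`), 0 (characterization stage; see below) | GSEA weighting |
| `nPerm` | 1000 | permutation draws per gene set |
| `esMin`, `fdrMax` | 0, 0.2 | signature selection thresholds (strict) |
| `alpha` | 0.25 | ssGSEA rank-weighting exponent |
| autoencoder widths | grid {300,200,100} x {100,50,30} x {30,20,10} | selected by held-out reconstruction BCE |
| `lr`, `batchSize` | 1e-3, 1024 | Adam learning rate and minibatch size (grid {1e-2,1e-3,1e-4} x {256,512,1024}) |
| `maxEpochs`, `patience` | 100, 10 | early-stopping protocol on validation loss |
| `lambdaC`, `lambdaD` | 1, 1 | reconstruction weights in the unified loss |
| IG `steps`, baseline | 50, all-zeros | path resolution and reference point |
| annotation `fdrMax` | 0.01 | embedding-annotation cutoff |

# Design choices in detail

**Enrichment statistic for propagation rankings.** `gsea()` defaults to
the classic weighted statistic (exponent 1). The characterization stage,
however, calls it with exponent 0. The reason is quantitative: with
$\beta = 0.9$ the converged RWR scores are extremely heavy-tailed — the
seed genes retain most of the probability mass and non-neighbors sit many
orders of magnitude lower. Under exponent 1 the hit increments are then
dominated by whichever seeds a set happens to contain, so a fully enriched
pathway and a random set holding a single seed both reach running-sum
peaks near 1 and become indistinguishable from the permutation null. The
unweighted statistic scores the *positions* of all members and separates
planted pathways from size-matched random sets by orders of magnitude in
p-value. Both exponents remain available on every entry point.

**Permutation null and p-values.** The null for a set of size $m$ draws
random $m$-gene sets from the ranked universe (gene-label permutation; a
phenotype permutation does not exist for a preranked list). As in classic
GSEA the empirical p-value compares the observed score against
*same-signed* null values,
$p = (1 + \#\{ES_{null} \ge ES\}) / (1 + \#\{ES_{null} \ge 0\})$ for
positive scores and mirrored for negative ones. This keeps $p$ uniform
under the null; comparing against the full two-signed null would count
both tails and double the type-I rate. FDR is Benjamini–Hochberg across
the collection — simpler and monotone compared with the NES-based GSEA
FDR, at the cost of ignoring the dependence between sets.

**ssGSEA.** Genes are ranked within the sample (descending expression,
ties broken by input order after a stable sort); the gene at position $i$
carries rank value $N - i + 1$, hits are weighted by rank$^\alpha$
normalized over the set's hits, and the statistic is the sum over all
positions of the hit-minus-miss ECDF difference. Scores are reported raw;
a min–max normalization flag exists but is off by default. Constant
expression columns are rejected rather than silently ranked, and a set
covering every expressed gene is rejected because the miss distribution is
undefined.

**Neural training.** All networks are dense stacks on BLAS matrix
operations with manual backpropagation, verified against finite
differences in the test suite. Weights use seeded He-uniform
initialization; optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$).
Batch normalization uses biased batch variance in training and running
statistics (momentum 0.9) at inference, so evaluation is deterministic and
differentiable per sample; running-statistic freezing is also what makes
integrated gradients well defined. Early stopping monitors the validation
unified loss each epoch and returns the best-validation state. Given a
fixed seed, training histories are bitwise reproducible in a single-threaded
BLAS; checkpoints (weights + normalization statistics + config) reload to
bitwise-identical predictions.

**Integrated gradients.** Attributions are taken with respect to the
predictor's input layer (pathway activities plus the two embeddings), not
propagated back through the encoders, matching how per-pathway and
per-dimension scores are reported. The path integral uses the
right-Riemann rule with 50 steps by default and an all-zeros baseline. For
affine predictors the attribution $w_i x_i$ is exact at any step count;
completeness $\sum_i IG_i = F(x) - F(x')$ is verified to within 1% at 200
steps on trained nonlinear models.

**Splits and metrics.** Partition sizes use deterministic
largest-remainder rounding of the 8:1:1 fractions. The `both` strategy
partitions cells and drugs independently and keeps a pair only when both
endpoints agree, discarding (and counting) cross-partition pairs. Under
this strategy the validation block (10% of cells times 10% of drugs) is
tiny and statistically uninformative for early stopping — on the default
cohort its correlation with the training signal stays near zero while
doubly-unseen test performance is still improving, and the unified
validation loss additionally contains the drug autoencoder's
reconstruction of unseen fingerprints, which deteriorates monotonically
as that autoencoder fits the training drugs. `runFull()` therefore
monitors early stopping, for the both strategy only, on every pair that
involves a validation entity and no test entity (the val-cell x val-drug
block plus the singly-unseen val x train and train x val pairs). Training
data and the doubly-unseen test set are untouched, so the split's
disjointness guarantees are unchanged. The full pipeline also warm-starts
both autoencoders with a short reconstruction-only pretraining phase on
training-partition entities (`aeWarmEpochs`, default 20), mirroring the
two-stage design. The
sensitive class is the lowest observed LN IC50 quartile; the threshold is
the type-7 (linear-interpolation) 25th percentile, F1 treats sensitive as
the positive class, and AUROC ranks by negative prediction so that higher
score means more sensitive. Pearson correlation is reported as undefined
(NA) for constant observations rather than zero.

# The synthetic cohort

`simulateCohort()` generates every input the pipeline consumes from one
master seed through named substreams (network, decoys, drivers, activity,
expression, mutation, drugs, noise), so components can be regenerated
independently and reruns are bitwise identical. The default cohort — the
problem size used throughout the package's own verification — has 500
genes, 200 cell lines, 50 drugs and a complete 10,000-pair response grid.

* The gene network is a stochastic-block-style graph (average degree 8,
  80% of edges within 20 modules) made connected by chaining components.
  The 20 modules double as the planted pathways; 20 random decoy sets give
  the selection step true negatives.
* 40 driver genes are concentrated in 5 modules; only those 5 modules'
  latent activities enter the response. RWR from the drivers therefore
  genuinely enriches the planted pathways, making the whole
  characterization stage testable end to end.
* Expression is latent activity times a positive loading
  ($U(0.5, 1.5)$) plus unit Gaussian noise; mutations are Bernoulli with
  per-driver rates in $(0.05, 0.4)$; fingerprint bits are Bernoulli(0.1).
* LN IC50 = activity component + mutation latent + drug latent
  (all standardized, unit weights) + 0.3 x (activity x drug) interaction +
  Gaussian noise with standard deviation half the realized signal's. With
  this noise ratio an ordinary least-squares fit on the *true* latents
  attains held-out $R^2 \approx 0.8$ — the designed ceiling against which
  the learned model is judged.

What the generator does **not** emulate: realistic TPM distributions,
mutational signatures, chemically valid molecules (fingerprint bits are
abstract), dose-response curve fitting, or batch effects. Passing the
recovery suite therefore demonstrates that the pipeline's machinery is
correct and can extract planted signal at realistic noise levels — not
that the paper-scale biological performance transfers to any particular
real cohort.

# Verification problem sizes

The package verifies itself at desk scale: 100 random graphs (up to 50
nodes) against the closed-form RWR solve; 100 random enrichment instances
against an independent running-sum oracle plus a 200-set x 1000-permutation
calibration of the null; finite-difference gradient checks on small
networks; a 50-sample memorization check for autoencoder capacity
(full-batch training — batch normalization makes tiny-minibatch
memorization needlessly slow); and the full pipeline on the default
cohort, where held-out Pearson correlation reaches about 0.87 under the
mix split and about 0.6 under the doubly-unseen both split against the
noise ceiling of about 0.89, with the planted pathways recovered in the
signature. `scripts/acceptance.R` recomputes all of these from scratch.

# Known limitations

* The GSEA FDR ignores inter-set dependence (BH on empirical p-values);
  strongly overlapping collections will be conservative or anticonservative
  in the usual BH ways.
* The gene-sampling permutation null assumes exchangeable genes. Where
  genes are strongly co-expressed (as in the correlation-ranking
  annotation of embedding dimensions), structured rankings can enrich sets
  beyond what the null models — the same caveat applies to any preranked
  GSEA with a gene-label null.
* Batch normalization couples samples within a training minibatch; with
  very small minibatches optimization degrades (documented above), so the
  capacity checks train full-batch.
* Doubly-unseen (both-split) generalization at the default cohort scale
  rests on 5 held-out drugs; its test correlation is inherently
  high-variance across cohort seeds — singly-unseen performance is stable
  while particular unseen-drug panels can defeat the learned
  embedding-to-response mapping.
* Morgan fingerprints come from OpenBabel's ECFP implementation folded to
  1024 bits; bit positions are not interchangeable with RDKit's folding,
  so fingerprints from different toolkits must not be mixed in one model.
* Identifier matching is exact string equality after whitespace stripping;
  alias resolution is an input-preparation concern.
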
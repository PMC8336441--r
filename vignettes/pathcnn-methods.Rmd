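---
title: "Pathway images, survival CNNs and Grad-CAM interpretation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway images, survival CNNs and Grad-CAM interpretation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcnn)
```

# The problem

Gene-level multi-omics measurements (mRNA expression, copy number,
DNA methylation) are not grid-structured, so convolutional networks cannot
consume them directly, and deep models fitted to them are hard to interpret
biologically. `pathcnn` addresses both issues with a *pathway image*
representation: for each sample, each biological pathway contributes one
image row whose pixels are the first $q$ principal-component scores of the
pathway's member genes, computed separately within each omics type. With $P$
pathways, $O$ omics types and $q$ components, every sample becomes a fixed
$P \times Oq$ image on which a small CNN classifies long-term versus
non-long-term survivors, and gradient-based class activation maps point back
to the pathways driving the classification.

# Labelling

A sample is a long-term survivor (LTS) when its survival time exceeds a
threshold (default 2 years), regardless of censoring status — a patient
censored alive at 3 years survived more than 2. A death at or below the
threshold is non-LTS. A sample *censored* at or below the threshold is
uninformative for the dichotomy and is excluded from every later stage,
including PCA fitting and image assembly. Class imbalance is handled by
weighting the cross-entropy loss with $w_c = N / (2 n_c)$, so the weight
ratio equals the inverse class-size ratio.

# Pathway images

For pathway $i$ and one omics matrix, the member genes present in that
matrix are extracted (missing genes are simply dropped — no imputation),
mean-centered per gene, and decomposed by covariance PCA; the first $q$
score columns become that pathway's pixels for that omics type. Columns are
arranged omics-major: with the default three omics types and $q = 2$, the
six columns are PC1 and PC2 of expression, then of copy number, then of
methylation. Numerical choices:

* **Sign convention.** PCA signs are arbitrary; each component is flipped so
  that its largest-absolute loading is positive, ties resolved toward the
  first gene in sorted gene-id order. This makes images — and therefore
  activation maps — bit-reproducible and invariant to gene column order.
* **Centering only.** Within one omics block the units are homogeneous, so
  genes are centered but not scaled by default (`scale.` switches this).
* **Rank deficiency.** When a pathway has fewer usable genes than $q$ (or
  the data are rank-deficient), trailing score columns are zero with
  explained-variance ratio 0, keeping the image geometry fixed — the CNN
  needs a constant input shape.
* **Fitting cohort.** By default PCA (and the min–max normalization below)
  is fitted once on the full labeled cohort before cross-validation. This
  mirrors a build-the-representation-first workflow but leaks a small
  amount of unsupervised information across CV folds;
  `pca_within_fold = TRUE` refits both on the training samples of every
  split and is the statistically safer option. Both are provided because
  the choice is genuinely open; the default favors comparability and speed.
* **Scaling.** PC scores enter the network min–max normalized per pixel
  position to $[0, 1]$, with the minimum and maximum taken on a reference
  sample set (the training samples, when refitting within folds). Held-out
  values are clipped; a constant reference pixel maps to 0.

# Pathway ordering

CNN filters see local neighborhoods, so correlated pathways should sit on
adjacent rows. Pathway similarity is the Pearson correlation between
pathway feature vectors (each pathway's image row concatenated across all
samples, length $n O q$, on raw pre-normalization scores). The ordering is
greedy: the two most (signed) correlated pathways occupy the first two rows
— lower-index pathway first, since the rule does not orient the pair — and
each subsequent row takes the unselected pathway most correlated with the
previous row, ties broken by input order. Signed rather than absolute
correlation is maximized, as "most correlated" is read literally.
Zero-variance pathways correlate 0 with everything and sink to the end.
Globally optimal seriation is out of scope.

# The classifier

The network is deliberately small: conv(32, 3×3) + ReLU → conv(64, 3×3) +
ReLU → max-pool 4×2 → dropout 0.25 → flatten → dense(64) + ReLU → dropout
0.5 → softmax(2), trained with Adam (learning rate $10^{-4}$) for 30 epochs
in batches of 64 under class-weighted cross-entropy. An optional age
covariate, z-scored with training-fold statistics, is concatenated to the
flattened features just before the dense layer. Geometry details that
matter for interpretation:

* **Padding.** Both convolutions use `same` padding by default, so the last
  conv layer keeps the full image geometry and activation differences can
  resolve individual PC columns; `valid` is available but collapses the
  pooled width of a 6-column image to 1.
* **Pooling.** Valid/floor max pooling (remainder rows dropped), the
  convention of the framework family this architecture originates from: a
  146×6 image pools to 36×3 feature maps.
* **Snapshotting.** The only "tuning" on the validation set is selecting
  the epoch with the best validation AUC; all other hyperparameters are
  fixed. When a model is trained on all samples for interpretation there is
  no validation set and the final epoch is kept.
* **Determinism.** Weight initialization (Glorot uniform), shuffling and
  dropout all draw from seeds derived from a master seed via named
  substreams, so any run is exactly reproducible and inserting a stage does
  not shift another stage's draws.

The layers themselves are implemented in the package as im2col gathers
(compiled) feeding BLAS matrix multiplies, with an explicit backward pass;
this keeps the whole training path introspectable, which the gradient-based
interpretation relies on.

# Cross-validation protocol

Performance is estimated by stratified 5-fold cross-validation repeated 30
times (both counts configurable). Within a repeat, each fold serves once as
the test set (20%); the remaining samples are split 80/20 — again
stratified — into training and validation sets. A fresh model is trained
per split and its test AUC recorded; the protocol reports the mean and SD
over all repeats × folds. Stratification is used because with strong class
imbalance unstratified folds can lose a class entirely. AUC is computed by
pairwise concordance with ties counted one half, using the softmax LTS
probability as the score.

# Grad-CAM interpretation

For interpretation a model is retrained once on *all* labeled samples with
the age input removed, so the activation differences reflect omics signal
independent of age. For each sample and each class $c$, the neuron
importance of feature map $k$ is the spatial mean of the gradient of the
class score with respect to that map,
$w_k^c = \tfrac{1}{Z}\sum_{ij} \partial y^c / \partial A^k_{ij}$, and the
activation map is $L^c = \mathrm{ReLU}(\sum_k w_k^c A^k)$. Choices:

* $y^c$ is the **pre-softmax logit**; softmax probabilities saturate and
  their gradients vanish exactly where the model is confident
  (`score = "prob"` is available).
* Each class map is min–max normalized to $[0, 1]$ per sample **before**
  up-sampling (a constant map becomes all zeros), then up-sampled
  bilinearly with corner alignment to the input image size
  (nearest-neighbour available). With `same` padding the up-sampling is the
  identity.
* The per-sample difference map is $D_i = |L_i^{LTS} - L_i^{non\text{-}LTS}|$
  on the normalized maps, making $D_i$ scale-free in $[0, 1]$.

Each pixel's $D$ values are then compared between the true LTS and non-LTS
groups with a two-sided Wilcoxon rank-sum test — exact enumeration when the
smaller group has at most 10 samples and no ties occur, otherwise the
normal approximation with tie and continuity correction — and p-values are
Bonferroni-corrected over all pixels. A pixel identical in both groups gets
$p = 1$ by convention. Significant pixels (default adjusted $p < 0.001$;
the threshold is a parameter) are grouped into *hot spots* as 4-connected
components of the significance mask, single pixels included. Each
significant pixel is followed up with a Kaplan–Meier analysis: samples are
dichotomized at the median of the pixel's raw PC values (low: value ≤
median) and compared by a log-rank test.

# The synthetic cohort generator

No external data ship with the package; the generator produces cohorts with
known ground truth so every stage is testable. Gene values follow a
one-latent-factor-per-(pathway, omics) model
$x = \delta + \sqrt{\rho}\,F + \sqrt{1-\rho}\,\varepsilon$ with unit
marginal SD, where $\delta$ equals the effect size (in gene-SD units) only
for LTS samples on planted (pathway, omics) pairs. Consecutive pathways
share a fraction (`factor_overlap`, default 0.25) of their factors, giving
the row-ordering stage realistic adjacent correlation. Defaults emulate a
glioblastoma-like cohort: 20% long-term survivors; non-LTS survival drawn
from an exponential (rate 0.8/year) truncated below the 2-year threshold
and LTS survival as 2 years plus an Exp(0.5) tail, so group membership
respects the threshold by construction (a configurable label-noise fraction
relaxes this, default 0); 10% of samples censored, the censored short
survivors being exactly the short-follow-up cases the labelling rule must
exclude (about 5% of the cohort at the default split); ages overlapping
with SD 8 years around 48 (LTS) versus 61 (non-LTS), so age helps but does
not trivialize classification; 10% of genes missing per omics platform
(always keeping at least one gene per pathway so every block remains
decomposable).

What it does **not** emulate: segmented copy-number profiles, bounded
beta-distributed methylation values, batch effects, overlapping gene sets,
or heavy-tailed expression. Passing tests therefore demonstrate that the
pipeline recovers the signal structure it models — planted mean shifts
propagating through PCA, convolution and rank tests — not that it
reproduces any particular real-data result.

# Problem sizes used in the shipped checks

The package's own verification runs at deliberately modest sizes chosen to
exercise every code path: geometry checks build a 146-pathway, 3-omics,
q = 2 cohort of 40 samples; signal-recovery experiments use cohorts of 300
samples, 40 pathways and 4 planted (pathway, omics) pairs at effect size
2.0 across 10 generator seeds; null calibrations use effect-free cohorts of
160 samples (with the age shift also zeroed, since an informative age
covariate is itself signal) under 2 repeats of 5-fold CV and 20 label
permutations of the pixel tests. Gradient correctness is checked against
central finite differences on a fixed small network at points where the
max-pooling is differentiable (strictly positive feature maps; at tied
window maxima the subgradient is not unique and finite differences split
it).

# Known limitations

* The pathway-image construction is linear per pathway; nonlinear structure
  within a pathway is only captured downstream by the CNN.
* Hot spots require correlated pathways to be contiguous after the greedy
  ordering; signal split across distant rows yields separate (smaller)
  components.
* With `pca_within_fold = FALSE` (default), CV AUCs inherit a small
  optimistic bias from cohort-level PCA and normalization.
* The Bonferroni correction is conservative under the strong spatial
  correlation of neighbouring pixels; the hot-spot count is therefore
  conservative too.
* Training is CPU-bound and single-threaded apart from BLAS; the default
  30×5 protocol on a full-size cohort is minutes-to-hours work, and the
  package favors exact reproducibility over parallel speed.
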
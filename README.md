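# pathcnn

Interpretable convolutional networks on multi-omics **pathway images** for
long-term-survival classification and pathway discovery.

## The problem

Gene-level omics matrices (mRNA expression, copy number, DNA methylation)
are not grid-structured, so CNNs cannot consume them directly — and when
deep models are fitted to such data, it is hard to say *which biology*
drives a prediction. `pathcnn` addresses both problems:

1. **Pathway images.** For each sample, each of $P$ pathways contributes
   one image row. Within each omics type, the pathway's member genes are
   mean-centered and decomposed by PCA; the first $q$ score columns become
   pixels. Columns are omics-major, so with 3 omics types and $q = 2$ a
   sample is a $P \times 6$ image (e.g. $146 \times 6$ for a 146-pathway
   collection). Rows are ordered greedily so correlated pathways are
   adjacent, which lets convolutions exploit locality.
2. **A small CNN** — conv(32, 3×3)/ReLU → conv(64, 3×3)/ReLU → maxpool 4×2
   → dropout → dense(64) (+ optional age covariate) → softmax — classifies
   long-term survivors (LTS, survival > 2 years) against non-LTS, trained
   with Adam under class-weighted cross-entropy ($w_c = N / 2n_c$) and
   evaluated by stratified 5-fold cross-validation with 30 repeats.
3. **Grad-CAM interpretation.** A model retrained on all samples (age
   removed) yields, per sample, one class activation map per class:
   $w_k^c = \frac{1}{Z}\sum_{ij} \partial y^c / \partial A^k_{ij}$,
   $L^c = \mathrm{ReLU}(\sum_k w_k^c A^k)$, normalized to $[0,1]$ and
   up-sampled to the image size. Per-sample difference maps
   $D_i = |L_i^{LTS} - L_i^{non\text{-}LTS}|$ are compared pixel-wise
   between the true groups with Wilcoxon rank-sum tests, Bonferroni
   corrected; significant pixels form 4-connected **hot spots**, and each
   is followed up with a Kaplan–Meier median-split log-rank test.

A synthetic multi-omics generator with planted pathway-level survival
signal makes the whole pipeline testable without external data.

## Worked example

```r
library(pathcnn)

# a 200-sample cohort, 8 pathways, signal planted in pathway 1 (expression)
# and pathway 2 (copy number)
co <- generate_cohort(synthetic_config(
  n_samples = 200, n_pathways = 8, genes_per_pathway = 6,
  signal_pathways = tibble::tibble(pathway = c(1L, 2L),
                                   omics = c("EXP", "CNV")),
  effect_size = 2, seed = 33))

labels <- assign_labels(co$clinical, threshold_years = 2)
labels
#> <label_set: 40 LTS, 140 non-LTS, 20 excluded (follow-up <= 2 y)>

images <- build_pathway_images(co$omics, co$gene_sets, q = 2,
                               sample_ids = labels$sample_id)
images
#> <pathway_image_set: 180 samples, 8 pathways x 6 columns (EXP/CNV/MET, q=2)>

ord    <- greedy_order(pathway_correlation_matrix(images))
imgs   <- normalize_images(apply_order(images, ord))$images

# interpretation model: all samples, no age input
cfg   <- cnn_config(use_age = FALSE, batch_size = 16, seed = 2)
model <- train_model(build_cnn(dim(imgs$images)[2:3], cfg),
                     imgs$images, labels$label, snapshot = "final")

tests <- pixelwise_test(difference_maps(model, imgs, labels))
tests
#> <pixel_test_result: 48 pixels, 3 significant at adjusted p < 0.001>
find_hotspots(tests)
#> # A tibble: 3 x 6
#>   hotspot   row   col pathway     pixel      adjusted_p
#>     <int> <int> <int> <chr>       <chr>           <dbl>
#> 1       1     3     2 PATHWAY_001 EXP_PC2 0.00000000204
#> 2       1     4     2 PATHWAY_002 EXP_PC2 0.000605
#> 3       2     4     4 PATHWAY_002 CNV_PC2 0.000000853
```

The two planted pathways — and only they — surface in the hot spots: the
class-difference maps are largest where the planted mean shift enters the
images (the greedy ordering put the two correlated signal pathways on
adjacent rows 3 and 4), and the rank tests flag those pixels after
Bonferroni correction. A median split of the raw PC values of a hot pixel
separates survival:

```r
v <- images$images[, 1, 1]            # raw EXP PC1 of planted pathway 1
names(v) <- images$sample_ids
km_logrank_median_split(v, co$clinical)
#> <km_split: log-rank chisq 52.724, p = 3.838e-13 (90 low / 90 high)>
```

Cross-validated classification uses the same building blocks:

```r
cv <- repeated_cv(imgs, labels$label, n_repeats = 2, n_folds = 5,
                  config = cfg, seed = 7)
glance(cv)
#> # A tibble: 1 x 4
#>   mean_auc sd_auc n_repeats n_folds
#>      <dbl>  <dbl>     <dbl>   <dbl>
#> 1    0.868 0.0590         2       5
```

(The planted signal here is strong; an effect-free cohort calibrates to
chance-level AUC — see the methods vignette.) `run_pipeline()` chains every
stage from TSV/GMT inputs to a manifest of artifacts, and
`inst/cli/pathcnn.R` exposes `simulate`, `build-images`, `order`,
`train-cv`, `interpret` and `run` subcommands for shell use.

## Package layout

| Where | What |
| --- | --- |
| `R/synthetic.R` | cohort generator and frozen fixture |
| `R/io.R`, `R/containers.R` | GMT / TSV readers and writers, core types |
| `R/labels.R`, `R/pca.R`, `R/images.R`, `R/order.R` | labelling, per-pathway PCA, image assembly/normalization, greedy row ordering |
| `R/nn-primitives.R`, `R/cnn.R`, `R/cv.R`, `src/conv_ops.cpp` | the CNN (im2col + BLAS), training, repeated CV |
| `R/gradcam.R`, `R/interpret.R` | activation maps, difference maps, pixel tests, hot spots, KM follow-up |
| `R/pipeline.R`, `inst/cli/pathcnn.R` | end-to-end orchestration and CLI |
| `vignettes/pathcnn-methods.Rmd` | the full methods account |
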
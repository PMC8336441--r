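#' Pipeline configuration
#'
#' Collects paths and settings for an end-to-end run: label assignment,
#' per-pathway PCA, image assembly, correlation-based row ordering, min-max
#' normalization, repeated cross-validation, full-cohort retraining without
#' age, Grad-CAM difference maps, pixel-wise tests, hot spots and
#' Kaplan-Meier follow-up.
#'
#' @param omics named list of TSV paths, one per omics type (names are the
#'   omics tags, in display order).
#' @param gene_sets path to a GMT file.
#' @param clinical path to a clinical TSV.
#' @param outdir output directory.
#' @param q principal components per omics type (1-5 supported).
#' @param threshold_years survival threshold for labelling.
#' @param alpha significance level for the pixel tests.
#' @param n_repeats,n_folds cross-validation protocol.
#' @param model named list of [cnn_config()] overrides.
#' @param pca_within_fold if `TRUE`, PCA and normalization are refit on the
#'   training samples of every CV split (slower, leakage-free); by default
#'   they are fitted once on the full labeled cohort.
#' @param scale_genes passed to [pathway_pca()] as `scale.`.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(omics, gene_sets, clinical, outdir,
                            q = 2, threshold_years = 2, alpha = 0.001,
                            n_repeats = 30, n_folds = 5, model = list(),
                            pca_within_fold = FALSE, scale_genes = FALSE,
                            seed = 7) {
  assert_that(is_count(q) && q <= 5, "q must be in 1..5")
  structure(list(omics = omics, gene_sets = gene_sets, clinical = clinical,
                 outdir = outdir, q = as.integer(q),
                 threshold_years = threshold_years, alpha = alpha,
                 n_repeats = n_repeats, n_folds = n_folds, model = model,
                 pca_within_fold = isTRUE(pca_within_fold),
                 scale_genes = isTRUE(scale_genes), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes all artifacts plus a manifest
#' (`manifest.json`) with an md5 hash per file. Any stage error aborts with
#' a stage-named message.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param verbose print stage progress.
#' @return invisibly, a list with `status` (0 on success), the artifact
#'   `manifest` tibble, and the in-memory stage results.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  cf <- config
  say <- function(...) if (verbose) message(sprintf(...))
  if (!dir.exists(cf$outdir)) dir.create(cf$outdir, recursive = TRUE)
  interp_dir <- file.path(cf$outdir, "interpret")
  if (!dir.exists(interp_dir)) dir.create(interp_dir)

  say("stage read-inputs")
  inputs <- run_stage("read-inputs", {
    gene_sets <- read_gene_sets(cf$gene_sets)
    omics <- lapply(names(cf$omics), function(tag) read_omics_matrix(cf$omics[[tag]], tag))
    names(omics) <- names(cf$omics)
    clinical <- read_clinical(cf$clinical)
    list(gene_sets = gene_sets, omics = omics, clinical = clinical)
  })

  say("stage labels")
  labels <- run_stage("labels", {
    ls <- assign_labels(inputs$clinical, cf$threshold_years)
    shared <- Reduce(intersect, lapply(inputs$omics, rownames))
    keep <- ls$sample_id %in% shared
    structure(list(sample_id = ls$sample_id[keep], label = ls$label[keep],
                   excluded_ids = c(ls$excluded_ids, ls$sample_id[!keep]),
                   threshold_years = ls$threshold_years), class = "label_set")
  })
  ids <- labels$sample_id

  say("stage pathway-images (%d samples)", length(ids))
  raw_images <- run_stage("pathway-images",
    build_pathway_images(inputs$omics, inputs$gene_sets, q = cf$q,
                         sample_ids = ids, scale. = cf$scale_genes))

  say("stage pathway-order")
  ord <- run_stage("pathway-order", {
    corr <- pathway_correlation_matrix(raw_images)
    greedy_order(corr)
  })
  raw_images <- apply_order(raw_images, ord)

  say("stage normalize")
  norm <- run_stage("normalize", normalize_images(raw_images))
  images <- norm$images

  model_cf <- do.call(cnn_config, utils::modifyList(
    list(seed = derive_seed(cf$seed, "cnn")), cf$model))

  builder <- NULL
  if (cf$pca_within_fold) {
    builder <- function(train_ids) {
      im <- build_pathway_images(inputs$omics, inputs$gene_sets, q = cf$q,
                                 sample_ids = ids, scale. = cf$scale_genes,
                                 fit_sample_ids = train_ids)
      im <- apply_order(im, ord)
      normalize_images(im, reference_sample_ids = train_ids)$images
    }
  }

  say("stage cross-validation (%d repeats x %d folds)", cf$n_repeats, cf$n_folds)
  age <- inputs$clinical$age[match(ids, inputs$clinical$sample_id)]
  cv <- run_stage("cross-validation",
    repeated_cv(images, labels$label, age = age, n_repeats = cf$n_repeats,
                n_folds = cf$n_folds, config = model_cf,
                seed = derive_seed(cf$seed, "cv"), image_builder = builder))

  say("stage interpret-train (all samples, no age)")
  interp_cf <- model_cf
  interp_cf$use_age <- FALSE
  interp_cf$seed <- derive_seed(cf$seed, "interpret")
  interp_model <- run_stage("interpret-train", {
    m <- build_cnn(dim(images$images)[2:3], interp_cf)
    train_model(m, images$images, labels$label, snapshot = "final")
  })

  say("stage gradcam")
  diffs <- run_stage("gradcam", difference_maps(interp_model, images, labels))
  ptest <- run_stage("pixel-tests", pixelwise_test(diffs, alpha = cf$alpha))
  hotspots <- run_stage("hotspots", find_hotspots(ptest))

  say("stage km-followup (%d significant pixels)", nrow(hotspots))
  km <- run_stage("km-followup", {
    rows <- list()
    for (i in seq_len(nrow(hotspots))) {
      vals <- raw_images$images[, hotspots$row[i], hotspots$col[i]]
      names(vals) <- raw_images$sample_ids
      res <- tryCatch(km_logrank_median_split(vals, inputs$clinical),
                      error = function(e) NULL)
      rows[[i]] <- tibble::tibble(
        pathway = hotspots$pathway[i], pixel = hotspots$pixel[i],
        hotspot = hotspots$hotspot[i],
        logrank_chisq = if (is.null(res)) NA_real_ else res$statistic,
        logrank_p = if (is.null(res)) NA_real_ else res$p_value)
    }
    dplyr::bind_rows(rows)
  })

  say("stage write-artifacts")
  paths <- run_stage("write-artifacts", {
    p <- character()
    f <- file.path(cf$outdir, "labels.tsv")
    write.table(tidy(labels), f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- c(p, f)
    f <- file.path(cf$outdir, "images.rds"); saveRDS(images, f); p <- c(p, f)
    f <- file.path(cf$outdir, "order.txt"); write_order(ord, f); p <- c(p, f)
    f <- file.path(cf$outdir, "cv.json")
    jsonlite::write_json(list(mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
                              aucs = cv$aucs, n_repeats = cv$n_repeats,
                              n_folds = cv$n_folds,
                              config = unclass(model_cf)),
                         f, auto_unbox = TRUE, digits = NA)
    p <- c(p, f)
    f <- file.path(cf$outdir, "model.rds"); saveRDS(interp_model, f); p <- c(p, f)
    f <- file.path(interp_dir, "raw_p.tsv")
    write.table(data.frame(pathway = rownames(ptest$raw_p), ptest$raw_p,
                           check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- c(p, f)
    f <- file.path(interp_dir, "adjusted_p.tsv")
    write.table(data.frame(pathway = rownames(ptest$adjusted_p), ptest$adjusted_p,
                           check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- c(p, f)
    f <- file.path(interp_dir, "hotspots.json")
    jsonlite::write_json(hotspots, f, auto_unbox = TRUE, digits = NA)
    p <- c(p, f)
    f <- file.path(interp_dir, "km_logrank.tsv")
    write.table(km, f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- c(p, f)
    f <- file.path(cf$outdir, "config.yaml")
    yaml::write_yaml(unclass(cf), f)
    p <- c(p, f)
    p
  })
  manifest <- tibble::tibble(
    file = paths,
    md5 = unname(tools::md5sum(paths)),
    bytes = file.size(paths)
  )
  jsonlite::write_json(manifest, file.path(cf$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %d artifacts in %s", nrow(manifest), cf$outdir)
  invisible(list(status = 0L, manifest = manifest,
                 results = list(labels = labels, images = images,
                                raw_images = raw_images, order = ord, cv = cv,
                                model = interp_model, diffs = diffs,
                                pixel_tests = ptest, hotspots = hotspots, km = km)))
}

#' Generate a synthetic cohort and write it to disk
#'
#' Convenience wrapper combining [generate_cohort()] and [write_cohort()]:
#' writes one TSV per omics type, a GMT file, a clinical TSV and a
#' ground-truth JSON naming the planted signal pathways.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
simulate_cohort <- function(config, outdir) {
  write_cohort(generate_cohort(config), outdir)
}
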
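#' Configuration for the synthetic multi-omics cohort generator
#'
#' Describes a cohort with planted pathway-level survival signal. Gene values
#' follow a one-factor-per-(pathway, omics) model:
#' `x = delta + sqrt(rho) * F_pathway + sqrt(1 - rho) * noise`, where `delta`
#' equals `effect_size` only for long-term survivors on planted
#' (pathway, omics) pairs, so the marginal gene SD is 1 and the standardized
#' group difference on signal genes equals `effect_size`. A small overlap
#' between the latent factors of consecutive pathways (`factor_overlap`)
#' induces the cross-pathway correlation that row ordering exploits.
#'
#' Survival times respect the labelling threshold by construction: long-term
#' survivors draw `threshold + Exp(rate = 0.5)` years; the rest draw from an
#' exponential truncated to `(0, threshold)`. A `censor_rate` fraction of
#' samples is marked censored (`event = 0`); censored short survivors are the
#' deliberately generated short-follow-up cases that the labelling rule must
#' exclude. Age is drawn with SD `age_sd` around `age_base` for long-term
#' survivors and `age_base + age_shift` otherwise, so age is informative but
#' overlapping.
#'
#' @param n_samples,n_pathways,genes_per_pathway cohort dimensions
#'   (`genes_per_pathway >= 2`).
#' @param omics_types ordered character vector of omics tags.
#' @param signal_pathways data frame with columns `pathway` (1-based index)
#'   and `omics` (tag): the planted signal pairs. Empty by default.
#' @param effect_size standardized mean shift, in gene-SD units, applied to
#'   the long-term-survivor group on planted pairs.
#' @param within_pathway_rho latent-factor correlation in `[0, 1)` between
#'   genes of one pathway.
#' @param factor_overlap share of a pathway's factor borrowed from the next
#'   pathway's factor, in `[0, 1)`; induces adjacent-pathway correlation.
#' @param missing_gene_rate per-omics probability that a gene is absent from
#'   that platform's universe (at least one gene per pathway is always kept).
#' @param lts_fraction fraction of long-term survivors in `(0, 1)`.
#' @param censor_rate fraction of censored samples in `[0, 1)`.
#' @param label_noise fraction of samples whose survival time is redrawn from
#'   the other group's distribution (default 0: labels match planted signal).
#' @param age_base,age_shift,age_sd age model in years: long-term survivors
#'   average `age_base`, others `age_base + age_shift`, both with SD `age_sd`.
#' @param threshold_years survival threshold separating the groups.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 300,
                             n_pathways = 40,
                             genes_per_pathway = 20,
                             omics_types = c("EXP", "CNV", "MET"),
                             signal_pathways = NULL,
                             effect_size = 1,
                             within_pathway_rho = 0.3,
                             factor_overlap = 0.25,
                             missing_gene_rate = 0.1,
                             lts_fraction = 0.2,
                             censor_rate = 0.1,
                             label_noise = 0,
                             age_base = 48,
                             age_shift = 13,
                             age_sd = 8,
                             threshold_years = 2,
                             seed = 1) {
  assert_that(is_count(n_samples) && n_samples >= 4, "n_samples must be a count >= 4")
  assert_that(is_count(n_pathways) && n_pathways >= 1, "n_pathways must be a count")
  assert_that(is_count(genes_per_pathway) && genes_per_pathway >= 2,
              "genes_per_pathway must be >= 2")
  assert_that(is.character(omics_types) && length(omics_types) >= 1 &&
                !anyDuplicated(omics_types), "omics_types must be distinct tags")
  if (is.null(signal_pathways))
    signal_pathways <- tibble::tibble(pathway = integer(), omics = character())
  signal_pathways <- tibble::as_tibble(signal_pathways)
  assert_that(all(c("pathway", "omics") %in% names(signal_pathways)),
              "signal_pathways needs columns pathway and omics")
  assert_that(all(signal_pathways$pathway >= 1 & signal_pathways$pathway <= n_pathways),
              "signal pathway indices must lie in 1..n_pathways")
  assert_that(all(signal_pathways$omics %in% omics_types),
              "signal omics tags must be among omics_types")
  assert_that(is_fraction(within_pathway_rho), "within_pathway_rho must be in [0,1)")
  assert_that(is_fraction(factor_overlap), "factor_overlap must be in [0,1)")
  assert_that(is_fraction(missing_gene_rate), "missing_gene_rate must be in [0,1)")
  assert_that(is_fraction(lts_fraction) && lts_fraction > 0, "lts_fraction must be in (0,1)")
  assert_that(is_fraction(censor_rate), "censor_rate must be in [0,1)")
  assert_that(is_fraction(label_noise), "label_noise must be in [0,1)")
  assert_that(threshold_years > 0, "threshold_years must be positive")
  structure(list(
    n_samples = as.integer(n_samples), n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway), omics_types = omics_types,
    signal_pathways = signal_pathways, effect_size = effect_size,
    within_pathway_rho = within_pathway_rho, factor_overlap = factor_overlap,
    missing_gene_rate = missing_gene_rate, lts_fraction = lts_fraction,
    censor_rate = censor_rate, label_noise = label_noise,
    age_base = age_base, age_shift = age_shift, age_sd = age_sd,
    threshold_years = threshold_years, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic multi-omics cohort with planted survival signal
#'
#' Draws omics matrices, gene sets and a clinical table under the generative
#' model described in [synthetic_config()]. Identical configurations produce
#' bit-identical cohorts.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `omics` (named list of [omics_matrix()]),
#'   `gene_sets` (a [gene_set_collection()]), `clinical` (tibble with
#'   sample_id, survival_years, event, age) and `truth` (list with the true
#'   group per sample and the planted signal table).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_samples; P <- cf$n_pathways; g <- cf$genes_per_pathway
    sample_ids <- sprintf("S%04d", seq_len(n))
    pathway_names <- sprintf("PATHWAY_%03d", seq_len(P))
    gene_ids <- lapply(seq_len(P), function(p) sprintf("P%03d_G%03d", p, seq_len(g)))
    gene_sets <- gene_set_collection(stats::setNames(gene_ids, pathway_names))

    # group assignment (TRUE = long-term survivor)
    n_lts <- max(1L, round(cf$lts_fraction * n))
    is_lts <- rep(FALSE, n)
    is_lts[sample(n, n_lts)] <- TRUE

    rho <- cf$within_pathway_rho; w <- cf$factor_overlap
    omics <- list()
    for (tag in cf$omics_types) {
      # latent pathway factors, with overlap between consecutive pathways
      U <- matrix(rnorm(n * P), n, P)
      FF <- U
      if (P > 1 && w > 0)
        FF[, seq_len(P - 1)] <- sqrt(1 - w) * U[, seq_len(P - 1)] + sqrt(w) * U[, -1]
      sig_p <- cf$signal_pathways$pathway[cf$signal_pathways$omics == tag]
      vals <- matrix(0, n, P * g, dimnames = list(sample_ids, unlist(gene_ids)))
      for (p in seq_len(P)) {
        delta <- if (p %in% sig_p) cf$effect_size * is_lts else 0
        block <- delta + sqrt(rho) * FF[, p] +
          sqrt(1 - rho) * matrix(rnorm(n * g), n, g)
        vals[, (p - 1) * g + seq_len(g)] <- block
      }
      # per-omics missing genes; keep at least one gene per pathway
      drop <- runif(P * g) < cf$missing_gene_rate
      for (p in seq_len(P)) {
        idx <- (p - 1) * g + seq_len(g)
        if (all(drop[idx])) drop[idx[1]] <- FALSE
      }
      omics[[tag]] <- omics_matrix(vals[, !drop, drop = FALSE], tag)
    }

    # survival: group membership respects the threshold by construction
    thr <- cf$threshold_years
    flip <- runif(n) < cf$label_noise
    eff_lts <- xor(is_lts, flip)
    lam <- 0.8  # non-LTS hazard, per year: median ~ 0.9 y, glioblastoma-like
    u <- runif(n)
    t_short <- -log(1 - u * (1 - exp(-lam * thr))) / lam
    t_long <- thr + rexp(n, rate = 0.5)
    survival_years <- ifelse(eff_lts, t_long, t_short)
    censored <- rep(FALSE, n)
    n_cens <- round(cf$censor_rate * n)
    if (n_cens > 0) censored[sample(n, n_cens)] <- TRUE
    event <- as.integer(!censored)
    age <- cf$age_base + cf$age_shift * (!eff_lts) + rnorm(n, sd = cf$age_sd)

    clinical <- tibble::tibble(
      sample_id = sample_ids,
      survival_years = survival_years,
      event = event,
      age = age
    )
    list(
      omics = omics, gene_sets = gene_sets, clinical = clinical,
      truth = list(
        is_lts = stats::setNames(eff_lts, sample_ids),
        signal_pathways = dplyr::mutate(cf$signal_pathways,
                                        pathway_name = pathway_names[.data$pathway]),
        config = cf
      )
    )
  })
}

#' Small fixed cohort for exact regression tests
#'
#' A frozen 12-sample, 5-pathway, 4-genes-per-pathway cohort drawn from the
#' generator under a pinned configuration and seed. Every call returns
#' identical objects, and every pathway has at least one present gene in
#' every omics type.
#'
#' @return the same structure as [generate_cohort()].
#' @export
generate_fixture <- function() {
  cf <- synthetic_config(
    n_samples = 12, n_pathways = 5, genes_per_pathway = 4,
    signal_pathways = tibble::tibble(pathway = c(1L, 2L), omics = c("EXP", "CNV")),
    effect_size = 1.5, within_pathway_rho = 0.4, factor_overlap = 0.2,
    missing_gene_rate = 0.15, lts_fraction = 1 / 3, censor_rate = 1 / 12,
    seed = 20210712
  )
  generate_cohort(cf)
}

#' Write a generated cohort to disk as plain text
#'
#' Omics matrices go to `<tag>.tsv` (first column `sample_id`, remaining
#' columns gene symbols), gene sets to `gene_sets.gmt`, the clinical table to
#' `clinical.tsv`, and the planted ground truth to `truth.json`.
#'
#' @param cohort result of [generate_cohort()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) abort(sprintf("cannot create directory '%s'", outdir))
  }
  paths <- character()
  for (tag in names(cohort$omics)) {
    p <- file.path(outdir, paste0(tolower(tag), ".tsv"))
    write_omics_matrix(cohort$omics[[tag]], p)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "gene_sets.gmt")
  write_gmt(cohort$gene_sets, p); paths <- c(paths, p)
  p <- file.path(outdir, "clinical.tsv")
  write.table(cohort$clinical, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(
    signal_pathways = cohort$truth$signal_pathways,
    is_lts = as.list(cohort$truth$is_lts)
  ), p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
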
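#' Gene-level omics matrix
#'
#' A samples-by-genes numeric matrix tagged with its omics type
#' (e.g. `"EXP"` for mRNA expression, `"CNV"` for copy number,
#' `"MET"` for DNA methylation). Sample ids live in `rownames`,
#' gene ids in `colnames`.
#'
#' @param values numeric matrix, samples in rows, genes in columns, with
#'   unique row and column names.
#' @param omics_tag single string identifying the omics type.
#' @return an `omics_matrix` object (a numeric matrix with an `omics_tag`
#'   attribute).
#' @export
omics_matrix <- function(values, omics_tag) {
  assert_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  assert_that(is.character(omics_tag) && length(omics_tag) == 1, "omics_tag must be a single string")
  assert_that(nrow(values) >= 2, "an omics matrix needs at least 2 samples")
  assert_that(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "sample ids (rownames) must be present and unique")
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "gene ids (colnames) must be present and unique")
  structure(values, omics_tag = omics_tag, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix %s: %d samples x %d genes>\n",
              attr(x, "omics_tag"), nrow(x), ncol(x)))
  invisible(x)
}

omics_tag <- function(x) attr(x, "omics_tag")

#' Gene set collection
#'
#' An ordered, named collection of pathways, each a character vector of
#' member gene ids (the in-memory form of a GMT file).
#'
#' @param sets named list of character vectors; names are pathway names.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  assert_that(is.list(sets) && length(sets) > 0, "sets must be a non-empty list")
  nm <- names(sets)
  assert_that(!is.null(nm) && all(nzchar(nm)), "every pathway must be named")
  assert_that(!anyDuplicated(nm), "pathway names must be unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  assert_that(all(lengths(sets) > 0), "every gene set must be non-empty")
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d pathways, %d unique genes>\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble::tibble(
    pathway = rep(names(x), lengths(x)),
    gene = unlist(x, use.names = FALSE)
  )
}

# Validate a clinical table (sample_id, survival_years, event, age).
validate_clinical <- function(clinical) {
  need <- c("sample_id", "survival_years", "event")
  assert_that(is.data.frame(clinical) && all(need %in% names(clinical)),
              "clinical table needs columns sample_id, survival_years, event")
  assert_that(!anyDuplicated(clinical$sample_id), "sample_id must be unique")
  assert_that(all(clinical$event %in% c(0, 1)), "event must be 0 (censored) or 1 (death)")
  if (any(clinical$survival_years < 0))
    abort("negative survival time in clinical table")
  invisible(clinical)
}
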
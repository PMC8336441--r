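#' Read gene sets from a GMT file
#'
#' One gene set per non-empty line: pathway name, description, then member
#' genes, tab-separated. Duplicate genes within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  assert_that(file.exists(path), sprintf("gene set file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) abort(sprintf("'%s' contains no gene sets", path))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort(sprintf("malformed GMT line %d in '%s': expected at least 3 tab-separated fields", i, path))
    name <- fields[[1]]
    if (name %in% names(sets))
      abort(sprintf("duplicate pathway name '%s' at line %d of '%s'", name, i, path))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      abort(sprintf("gene set '%s' (line %d) has no genes", name, i))
    sets[[name]] <- genes
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#' @param gene_sets a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-level omics matrix from TSV
#'
#' Expects samples in rows: first column `sample_id`, remaining columns gene
#' symbols, numeric body. Parsing is strict: any non-numeric cell (including
#' `NA`) is an error naming its row and column — missing genes are handled
#' upstream by omitting the column, not by encoding missing values.
#'
#' @param path path to the TSV file.
#' @param omics_tag omics type tag to attach (e.g. `"EXP"`).
#' @param genes_in_rows if `TRUE`, the file is transposed on read (genes in
#'   rows, samples in columns).
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, omics_tag, genes_in_rows = FALSE) {
  assert_that(file.exists(path), sprintf("omics file '%s' does not exist", path))
  df <- tryCatch(
    read.delim(path, check.names = FALSE, colClasses = "character"),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  if (ncol(df) < 2) abort(sprintf("'%s' has no gene columns", path))
  if (nrow(df) == 0) abort(sprintf("'%s' has a header but no data rows", path))
  ids <- df[[1]]
  genes <- colnames(df)[-1]
  if (anyDuplicated(genes))
    abort(sprintf("duplicate gene column '%s' in '%s'",
                  genes[duplicated(genes)][1], path))
  if (anyDuplicated(ids))
    abort(sprintf("duplicate sample id '%s' in '%s'", ids[duplicated(ids)][1], path))
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) | body == "NA", arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort(sprintf("non-numeric cell '%s' at row %d (sample '%s'), column '%s' of '%s'",
                  body[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                  genes[bad[1, 2]], path))
  dimnames(num) <- list(ids, genes)
  if (genes_in_rows) {
    num <- t(num)
  }
  omics_matrix(num, omics_tag)
}

#' Write an omics matrix as TSV (first column sample_id)
#' @param omics an [omics_matrix()].
#' @param path output path.
#' @export
write_omics_matrix <- function(omics, path) {
  df <- data.frame(sample_id = rownames(omics), as.data.frame(unclass(omics)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Expects columns `sample_id`, `survival_years`, `event` (1 = death
#' observed, 0 = censored) and optionally `age`.
#'
#' @param path path to the TSV file.
#' @return a tibble.
#' @export
read_clinical <- function(path) {
  assert_that(file.exists(path), sprintf("clinical file '%s' does not exist", path))
  df <- tibble::as_tibble(read.delim(path, check.names = FALSE))
  validate_clinical(df)
  df
}
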
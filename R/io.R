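# Readers and writers for the pipeline's plain-text formats:
#  - expression: tab-separated, first row sample IDs, first column gene IDs
#  - annotation / survival: CSV keyed by sample_id

#' Read a gene x sample expression table
#'
#' Parses a tab-separated expression matrix (row 1 = sample IDs, column 1 =
#' gene IDs). Blank, `NA` and `NaN` cells become missing values. Ragged
#' rows, duplicate gene IDs and non-numeric cells are rejected with the
#' offending line numbers.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) {
    stop_pdacsig(paste0("file not found: ", path), "parse_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop_pdacsig("expression table needs a header row and >= 1 gene row",
                 "parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading cell for the gene-ID column
  n_samp_plus1 <- length(fields[[2]])
  if (length(header) == n_samp_plus1 - 1L) {
    samples <- header
  } else if (length(header) == n_samp_plus1) {
    samples <- header[-1]
  } else {
    stop_pdacsig("header width does not match data rows (line 1)",
                 "parse_error")
  }
  widths <- lengths(fields[-1])
  bad <- which(widths != n_samp_plus1)
  if (length(bad)) {
    stop_pdacsig(paste0("ragged rows at line(s): ",
                        paste(bad + 1L, collapse = ", ")), "parse_error")
  }
  genes <- vapply(fields[-1], `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)]
    stop_pdacsig(paste0("duplicate gene IDs: ",
                        paste(unique(dup), collapse = ", ")), "parse_error")
  }
  if (anyDuplicated(samples)) {
    stop_pdacsig("duplicate sample IDs in header", "parse_error")
  }
  cells <- lapply(fields[-1], `[`, -1L)
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (i in seq_along(cells)) {
    raw <- cells[[i]]
    missing_cell <- raw %in% c("", "NA", "NaN", "nan")
    val <- suppressWarnings(as.numeric(raw))
    bad_cell <- is.na(val) & !missing_cell
    if (any(bad_cell)) {
      stop_pdacsig(sprintf("non-numeric cell(s) at line %d: %s", i + 1L,
                           paste(raw[bad_cell], collapse = ", ")),
                   "parse_error")
    }
    val[missing_cell] <- NA_real_
    mat[i, ] <- val
  }
  mat
}

#' Write a gene x sample expression table
#'
#' @param mat genes x samples matrix.
#' @param path output path.
#' @export
write_expression_table <- function(mat, path) {
  check_expression_matrix(mat)
  utils::write.table(
    cbind(gene_id = rownames(mat), as.data.frame(mat)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation and survival CSVs
#'
#' Survival CSVs carry columns `sample_id`, `time_months`, `event` (1 =
#' death observed, 0 = censored); annotation CSVs carry `sample_id`,
#' `batch`, `class` and any additional clinical columns.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_survival_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(tab))) {
    stop_pdacsig(paste0("survival CSV must have columns: ",
                        paste(need, collapse = ", ")), "parse_error")
  }
  tab
}

#' @rdname read_survival_csv
#' @param tab data frame to write.
#' @export
write_survival_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_survival_csv
#' @export
read_annotation_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop_pdacsig("annotation CSV must have a sample_id column",
                 "parse_error")
  }
  tab
}

#' Write a simulated study to a directory
#'
#' Writes `expression.tsv`, `annotation.csv` and `survival.csv` in the
#' formats consumed by the pipeline readers.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_table(study$expression, file.path(dir, "expression.tsv"))
  utils::write.csv(study$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(study$survival)) {
    write_survival_csv(study$survival, file.path(dir, "survival.csv"))
  }
  invisible(dir)
}
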
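# Nearest-centroid single-sample predictor (SSP).
#
# A centroid is the per-gene mean profile of a class over the signature
# genes; a new sample is compared to the resected (nonmetastatic) centroid
# one sample at a time with distance (1 - Pearson correlation), and
# stratified into high/low risk by a survival-derived cut-point on that
# distance (cut-point 1 corresponds to correlation 0).

#' Build a class centroid over a gene signature
#'
#' @param mat genes x samples matrix.
#' @param samples sample IDs (or logical/integer index) of the class's
#'   derivation samples; must be nonempty.
#' @param genes signature gene IDs; all must be present in `mat`.
#' @param class_name label stored with the centroid (e.g. "resected").
#' @return Object of class `centroid`: `genes`, per-gene `means`,
#'   `class_name`, `n_samples`.
#' @export
build_centroid <- function(mat, samples, genes, class_name = "resected") {
  check_expression_matrix(mat)
  if (is.character(genes)) {
    missing_genes <- setdiff(genes, rownames(mat))
    if (length(missing_genes) > 0L) {
      stop_pdacsig(paste0("signature genes absent from matrix: ",
                          paste(missing_genes, collapse = ", ")),
                   "missing_genes")
    }
  }
  if (length(genes) == 0L) {
    stop_pdacsig("gene list must be nonempty", "invalid_input")
  }
  sub <- mat[genes, samples, drop = FALSE]
  if (ncol(sub) == 0L) {
    stop_pdacsig("sample subset must be nonempty", "invalid_input")
  }
  structure(
    list(genes = rownames(sub),
         means = stats::setNames(rowMeans(sub), rownames(sub)),
         class_name = class_name,
         n_samples = ncol(sub)),
    class = "centroid"
  )
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("'%s' centroid: %d signature genes, mean of %d samples\n",
              x$class_name, length(x$genes), x$n_samples))
  invisible(x)
}

#' Correlation and SSP distance of one sample profile to a centroid
#'
#' Computes the Pearson correlation r over the signature genes only, and
#' the single-sample-predictor distance 1 - r.
#'
#' @param profile named numeric vector of one sample's expression (must
#'   cover the signature genes) or an unnamed vector already aligned to the
#'   centroid's gene order.
#' @param centroid a [build_centroid()] result; needs >= 3 genes.
#' @return list with `r` and `distance`.
#' @export
correlate_to_centroid <- function(profile, centroid) {
  stopifnot(inherits(centroid, "centroid"))
  if (length(centroid$genes) < 3L) {
    stop_pdacsig("need >= 3 signature genes for a correlation",
                 "invalid_input")
  }
  if (!is.null(names(profile))) {
    missing_genes <- setdiff(centroid$genes, names(profile))
    if (length(missing_genes) > 0L) {
      stop_pdacsig(paste0("profile lacks signature genes: ",
                          paste(missing_genes, collapse = ", ")),
                   "missing_genes")
    }
    profile <- profile[centroid$genes]
  } else if (length(profile) != length(centroid$genes)) {
    stop_pdacsig("unnamed profile must match the signature length",
                 "invalid_input")
  }
  if (anyNA(profile)) {
    stop_pdacsig("profile has missing values over the signature",
                 "invalid_input")
  }
  if (stats::sd(profile) == 0 || stats::sd(centroid$means) == 0) {
    stop_pdacsig("zero variance over the signature: correlation undefined",
                 "undefined_correlation")
  }
  r <- stats::cor(as.numeric(profile), as.numeric(centroid$means))
  list(r = r, distance = 1 - r)
}

#' Assign a risk label from the SSP distance
#'
#' Distance strictly below the cut-point (correlation above 1 - cutpoint)
#' is low risk; distance at or above it is high risk. The default cut-point
#' of 1 corresponds to a Pearson correlation of zero, the survival-optimal
#' threshold for the resected-centroid predictor; ties at the cut-point go
#' to high risk (conservative toward poor prognosis).
#'
#' @param r Pearson correlation(s) to the resected centroid.
#' @param cutpoint distance cut-point in [0, 2].
#' @return character vector, "high" or "low".
#' @export
classify_risk <- function(r, cutpoint = 1) {
  if (!(length(cutpoint) == 1L && cutpoint >= 0 && cutpoint <= 2)) {
    stop_pdacsig("cutpoint must lie in [0, 2]", "invalid_input")
  }
  ifelse(1 - r < cutpoint, "low", "high")
}

#' Classify every sample of a matrix against a centroid
#'
#' @param mat genes x samples matrix covering the signature genes.
#' @param centroid the resected-class [build_centroid()].
#' @param cutpoint SSP distance cut-point (default 1, i.e. r = 0).
#' @return data frame with sample_id, r, distance, risk.
#' @export
classify_samples <- function(mat, centroid, cutpoint = 1) {
  check_expression_matrix(mat)
  calls <- lapply(colnames(mat), function(sid) {
    cc <- correlate_to_centroid(mat[, sid], centroid)
    data.frame(sample_id = sid, r = cc$r, distance = cc$distance,
               risk = classify_risk(cc$r, cutpoint),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Write / read a centroid as two-column text
#'
#' @param centroid a `centroid` object.
#' @param path file path.
#' @export
write_centroid <- function(centroid, path) {
  stopifnot(inherits(centroid, "centroid"))
  utils::write.table(
    data.frame(gene_id = centroid$genes, mean = as.numeric(centroid$means)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroid
#' @param class_name class label to attach on read.
#' @export
read_centroid <- function(path, class_name = "resected") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(
    list(genes = as.character(tab$gene_id),
         means = stats::setNames(as.numeric(tab$mean),
                                 as.character(tab$gene_id)),
         class_name = class_name,
         n_samples = NA_integer_),
    class = "centroid"
  )
}
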
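#' Lowess (MA) normalization of a two-color array
#'
#' Removes intensity-dependent dye bias from a two-color array by locally
#' weighted regression of M = log2(R/G) on A = (1/2) log2(R*G) and returning
#' the residuals M - fit(A). This is the global MA-lowess normalization
#' standard for Cy5/Cy3 reference designs.
#'
#' Spots with a nonpositive intensity in either channel have undefined M and
#' are returned as `NA`; at least 10 spots with both intensities positive
#' are required to fit the curve.
#'
#' @param array data frame with columns `gene_id`, `red_mean`, `green_mean`
#'   (per-spot mean channel intensities; red = Cy5 sample, green = Cy3
#'   common reference).
#' @param span lowess smoother span in (0, 1], default 0.3.
#' @return Named numeric vector of normalized log2 ratios, one per input
#'   spot (names = gene_id), `NA` where M is undefined.
#' @export
lowess_normalize <- function(array, span = 0.3) {
  if (!is.data.frame(array) ||
      !all(c("gene_id", "red_mean", "green_mean") %in% names(array))) {
    stop_pdacsig("array must have columns gene_id, red_mean, green_mean",
                 "invalid_input")
  }
  if (!(length(span) == 1L && span > 0 && span <= 1)) {
    stop_pdacsig("span must lie in (0, 1]", "invalid_input")
  }
  r <- array$red_mean
  g <- array$green_mean
  if (any(r < 0, na.rm = TRUE) || any(g < 0, na.rm = TRUE)) {
    stop_pdacsig("channel intensities must be nonnegative", "invalid_input")
  }
  if (all(r == 0, na.rm = TRUE) || all(g == 0, na.rm = TRUE)) {
    stop_pdacsig("one channel is identically zero; cannot normalize",
                 "normalization_failure")
  }
  ok <- is.finite(r) & is.finite(g) & r > 0 & g > 0
  if (sum(ok) < 10L) {
    stop_pdacsig("need at least 10 spots with both intensities > 0",
                 "normalization_failure")
  }
  M <- A <- rep(NA_real_, nrow(array))
  M[ok] <- log2(r[ok] / g[ok])
  A[ok] <- 0.5 * log2(r[ok] * g[ok])

  out <- rep(NA_real_, nrow(array))
  if (stats::sd(M[ok]) == 0 || stats::sd(A[ok]) == 0) {
    # constant M (pure dye bias) or constant A: the trend is the mean
    out[ok] <- M[ok] - mean(M[ok])
  } else {
    fit <- stats::lowess(A[ok], M[ok], f = span)
    trend <- stats::approx(fit$x, fit$y, xout = A[ok], rule = 2,
                           ties = mean)$y
    out[ok] <- M[ok] - trend
  }
  stats::setNames(out, as.character(array$gene_id))
}

spot_is_poor <- function(flag) {
  if (is.null(flag)) return(rep(FALSE, 0L))
  if (is.logical(flag)) return(!is.na(flag) & flag)
  !is.na(flag) & flag != 0
}

#' Intensity-based gene filtering across experiments
#'
#' A gene is retained iff, in at least `ceiling(fraction * n_experiments)`
#' experiments, at least one of its two channel mean intensities strictly
#' exceeds `threshold`. A gene flagged poor-quality in an experiment, or
#' absent from it, counts as failing that experiment. The default threshold
#' 10 and fraction 0.7 reproduce the "mean intensity greater than 10 in at
#' least 70% of experiments" rule used for reference-design arrays.
#'
#' @param experiments list of spot tables, each a data frame with columns
#'   `gene_id`, `red_mean`, `green_mean` and optionally `flag`
#'   (nonzero/`TRUE` = poor spot quality).
#' @param threshold positive intensity threshold (strict: exactly equal
#'   fails).
#' @param fraction required proportion of experiments in (0, 1].
#' @return Character vector of retained gene IDs, in first-appearance order.
#' @export
filter_genes <- function(experiments, threshold = 10, fraction = 0.7) {
  if (!is.list(experiments) || length(experiments) == 0L) {
    stop_pdacsig("experiments must be a nonempty list of spot tables",
                 "invalid_input")
  }
  if (!(length(threshold) == 1L && threshold > 0)) {
    stop_pdacsig("threshold must be positive", "invalid_input")
  }
  if (!(length(fraction) == 1L && fraction > 0 && fraction <= 1)) {
    stop_pdacsig("fraction must lie in (0, 1]", "invalid_input")
  }
  all_genes <- unique(unlist(lapply(experiments,
                                    function(e) as.character(e$gene_id))))
  passes <- stats::setNames(integer(length(all_genes)), all_genes)
  for (e in experiments) {
    gid <- as.character(e$gene_id)
    good <- pmax(e$red_mean, e$green_mean) > threshold
    if (!is.null(e$flag)) good <- good & !spot_is_poor(e$flag)
    good[is.na(good)] <- FALSE
    # first occurrence wins for duplicated probes within an experiment
    ok_gene <- tapply(good, factor(gid, levels = unique(gid)), any)
    hit <- names(ok_gene)[ok_gene]
    passes[hit] <- passes[hit] + 1L
  }
  need <- ceiling(fraction * length(experiments))
  names(passes)[passes >= need]
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Replaces each missing entry of a genes x samples matrix by the
#' inverse-distance-weighted average of the corresponding entries of the
#' `k` nearest gene rows, with distance the root-mean-square Euclidean
#' distance over columns observed in both rows. Neighbours must have an
#' observed value in the target column; exact-match neighbours (distance 0)
#' short-circuit to their plain average. Distance ties are broken by row
#' order, so results are deterministic. Observed entries are never altered.
#'
#' @param mat genes x samples numeric matrix, `NA` for missing.
#' @param k number of neighbours (default 10).
#' @return The matrix with all missing entries imputed.
#' @export
knn_impute <- function(mat, k = 10L) {
  check_expression_matrix(mat)
  if (!is_count(k)) stop_pdacsig("k must be a positive count", "invalid_input")
  if (!anyNA(mat)) return(mat)

  all_missing <- rowSums(!is.na(mat)) == 0L
  if (any(all_missing)) {
    stop_pdacsig(paste0("gene rows with all entries missing cannot be imputed: ",
                        paste(rownames(mat)[all_missing], collapse = ", ")),
                 "unimputable_row")
  }

  out <- mat
  target_rows <- which(rowSums(is.na(mat)) > 0L)
  for (i in target_rows) {
    x <- mat[i, ]
    diffsq <- sweep(mat, 2, x, "-")^2
    shared <- rowSums(!is.na(diffsq))
    d <- sqrt(rowMeans(diffsq, na.rm = TRUE))
    d[shared == 0L] <- Inf
    d[i] <- Inf
    miss_cols <- which(is.na(x))
    for (j in miss_cols) {
      cand <- which(!is.na(mat[, j]) & is.finite(d))
      if (length(cand) == 0L) {          # no usable neighbour: row mean
        out[i, j] <- mean(x, na.rm = TRUE)
        next
      }
      cand <- cand[order(d[cand], cand)]
      dc <- d[cand]
      if (dc[1] == 0) {
        zero <- cand[dc == 0]
        out[i, j] <- mean(mat[zero, j])
      } else {
        use <- cand[seq_len(min(k, length(cand)))]
        w <- 1 / d[use]
        out[i, j] <- sum(w * mat[use, j]) / sum(w)
      }
    }
  }
  out
}
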
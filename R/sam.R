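# Two-class unpaired significance analysis of microarrays (SAM).
#
# Per gene, d = (mean2 - mean1) / (s + s0), with s the pooled-standard-error
# scatter and s0 a small exchangeability ("fudge") factor chosen to make the
# coefficient of variation of d stable across the range of s.  Significance
# is calibrated by label permutations: ordered observed d are compared with
# the mean ordered permuted d, genes deviating by more than a threshold
# delta beyond the cut values are called, and the false discovery rate at
# each delta is the (pi0-scaled) average number of permuted exceedances over
# the observed call count (the original SAM convention; a median-based
# variant is available but is unstable when only a handful of genes are
# called, because the median permuted count is then often exactly zero).

sam_stat_parts <- function(mat, grp2) {
  n2 <- sum(grp2); n1 <- sum(!grp2)
  m2 <- rowMeans(mat[, grp2, drop = FALSE])
  m1 <- rowMeans(mat[, !grp2, drop = FALSE])
  ss1 <- rowSums((mat[, !grp2, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, grp2, drop = FALSE] - m2)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(num = m2 - m1, s = sqrt(a * (ss1 + ss2)))
}

#' SAM fudge factor s0
#'
#' Chooses the exchangeability factor s0 as the percentile of the per-gene
#' scatter values that minimizes the coefficient of variation of the median
#' absolute deviation of the d-statistic across windows of the scatter
#' distribution. When all scatters are (numerically) equal any s0 gives the
#' same coefficient of variation; by convention the 5th percentile of s
#' is returned.
#'
#' @param d_numerators per-gene mean differences.
#' @param scatters per-gene pooled standard errors (same length, >= 20).
#' @return s0 (nonnegative scalar) with attribute `alpha`, the selected
#'   percentile.
#' @export
compute_s0 <- function(d_numerators, scatters) {
  stopifnot(length(d_numerators) == length(scatters))
  if (length(scatters) < 20L) {
    stop_pdacsig("need >= 20 genes for stable scatter-quantile windows",
                 "invalid_input")
  }
  if (any(scatters < 0)) stop_pdacsig("scatters must be nonnegative",
                                      "invalid_input")
  if (diff(range(scatters)) < 1e-12 * max(1, max(scatters))) {
    s0 <- unname(stats::quantile(scatters, 0.05))
    attr(s0, "alpha") <- 0.05
    return(s0)
  }
  n <- length(scatters)
  nwin <- max(2L, min(100L, n %/% 10L))
  br <- unique(stats::quantile(scatters, seq(0, 1, length.out = nwin + 1)))
  win <- cut(scatters, br, include.lowest = TRUE)

  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(scatters, alphas)
  cv <- vapply(cand, function(s0) {
    d <- d_numerators / (scatters + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cv)
  s0 <- unname(cand[best])
  attr(s0, "alpha") <- alphas[best]
  s0
}

# positive/negative cut values at a given delta, from ordered d vs expected
# ordered d. Upper cut considers positive-d genes, lower cut negative-d.
sam_cuts <- function(d_sorted, dbar, delta) {
  diffs <- d_sorted - dbar
  up <- which(diffs >= delta & d_sorted >= 0)
  lo <- which(-diffs >= delta & d_sorted <= 0)
  list(cutup = if (length(up)) d_sorted[min(up)] else Inf,
       cutlow = if (length(lo)) d_sorted[max(lo)] else -Inf)
}

#' Two-class SAM with permutation-estimated FDR
#'
#' Runs unpaired two-class SAM on a complete (imputed) expression matrix.
#' The d-statistic contrasts the second class level against the first
#' (positive d = higher in the second level). The threshold delta is the
#' smallest value whose estimated median FDR is at or below `target_fdr`;
#' the selected genes are exactly those called at that delta.
#'
#' @param mat genes x samples numeric matrix, no missing values.
#' @param labels two-class sample labels (factor or character, length =
#'   ncol(mat)); each class needs >= 2 samples.
#' @param n_perm number of label permutations (all distinct assignments are
#'   enumerated when there are fewer than `n_perm`); values below 10 trigger
#'   a warning.
#' @param target_fdr target false discovery rate (default 0.05).
#' @param fdr_method how the permutation false-call count is summarized:
#'   `"mean"` (the original SAM convention, default) or `"median"`.
#' @param seed RNG seed for the permutation draw.
#' @return Object of class `sam_result` with per-gene `d`, `s`, `q_value`,
#'   the fudge factor `s0`, expected order statistics `dbar`, the chosen
#'   `delta`, `selected` gene IDs, `pi0`, the FDR scan table, and the
#'   permutation count actually used.
#' @export
sam_two_class <- function(mat, labels, n_perm = 1000L, target_fdr = 0.05,
                          seed = 1L, fdr_method = c("mean", "median")) {
  fdr_method <- match.arg(fdr_method)
  check_expression_matrix(mat)
  if (anyNA(mat)) {
    stop_pdacsig("matrix contains missing values; impute first",
                 "invalid_input")
  }
  labels <- as.factor(labels)
  if (length(labels) != ncol(mat)) {
    stop_pdacsig("labels must have one entry per sample", "invalid_input")
  }
  if (nlevels(droplevels(labels)) != 2L) {
    stop_pdacsig("labels must contain exactly two classes", "invalid_input")
  }
  labels <- droplevels(labels)
  grp2 <- labels == levels(labels)[2]
  if (sum(grp2) < 2L || sum(!grp2) < 2L) {
    stop_pdacsig("each class needs >= 2 samples", "invalid_input")
  }
  if (n_perm < 10L) warning("n_perm < 10: permutation FDR will be unstable")

  ng <- nrow(mat)
  n <- ncol(mat)
  obs <- sam_stat_parts(mat, grp2)
  s0 <- compute_s0(obs$num, obs$s)
  d <- obs$num / (obs$s + s0)

  # permutation set: enumerate all distinct assignments when feasible
  n2 <- sum(grp2)
  n_distinct <- choose(n, n2)
  perms <- with_seed(seed, {
    if (n_distinct <= n_perm) {
      idx <- utils::combn(n, n2)
      lapply(seq_len(ncol(idx)), function(j) {
        g <- rep(FALSE, n); g[idx[, j]] <- TRUE; g
      })
    } else {
      lapply(seq_len(n_perm), function(j) {
        g <- rep(FALSE, n); g[sample.int(n, n2)] <- TRUE; g
      })
    }
  })
  B <- length(perms)

  d_perm_sorted <- matrix(0, ng, B)
  for (b in seq_len(B)) {
    p <- sam_stat_parts(mat, perms[[b]])
    d_perm_sorted[, b] <- sort(p$num / (p$s + s0))
  }
  dbar <- rowMeans(d_perm_sorted)

  ord <- order(d)
  d_sorted <- d[ord]

  # pi0: fraction of genes whose d falls in the central half of the
  # permuted-d distribution, scaled (Storey-style, the SAM convention)
  qq <- stats::quantile(d_perm_sorted, c(0.25, 0.75))
  pi0 <- min(1, sum(d > qq[1] & d < qq[2]) / (0.5 * ng))

  deltas <- sort(unique(c(0, abs(d_sorted - dbar))))
  cutups <- cutlows <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    cuts <- sam_cuts(d_sorted, dbar, deltas[i])
    cutups[i] <- cuts$cutup
    cutlows[i] <- cuts$cutlow
  }
  # per-permutation counts of d outside (cutlow, cutup), via binary search
  # in each (sorted) permutation column; ties at the cut count as calls
  false_counts <- matrix(0, length(deltas), B)
  for (b in seq_len(B)) {
    col <- d_perm_sorted[, b]
    false_counts[, b] <- findInterval(cutlows, col) +
      (ng - findInterval(cutups, col, left.open = TRUE))
  }
  summarize <- if (fdr_method == "mean") rowMeans else {
    function(m) apply(m, 1, stats::median)
  }
  n_false <- summarize(false_counts)
  n_called <- vapply(seq_along(deltas), function(i) {
    sum(d >= cutups[i]) + sum(d <= cutlows[i])
  }, numeric(1))
  scan <- data.frame(
    delta = deltas, n_called = as.integer(n_called), n_false = n_false,
    fdr = ifelse(n_called == 0L, 0, pmin(1, pi0 * n_false / pmax(n_called, 1))),
    cutlow = cutlows, cutup = cutups)

  ok <- which(scan$fdr <= target_fdr)
  if (length(ok)) {
    sel_i <- min(ok)
    delta <- scan$delta[sel_i]
    cutup <- scan$cutup[sel_i]
    cutlow <- scan$cutlow[sel_i]
  } else {
    # no threshold attains the target FDR: nothing is called
    delta <- Inf
    cutup <- Inf
    cutlow <- -Inf
  }
  selected <- rownames(mat)[d >= cutup | d <= cutlow]

  # per-gene q: smallest scan FDR among deltas at which the gene is called
  q <- rep(1, ng)
  for (i in seq_len(nrow(scan))) {
    called_i <- d >= scan$cutup[i] | d <= scan$cutlow[i]
    q[called_i] <- pmin(q[called_i], scan$fdr[i])
  }

  structure(
    list(d = stats::setNames(d, rownames(mat)),
         s = stats::setNames(obs$s, rownames(mat)),
         s0 = as.numeric(s0),
         dbar = dbar,
         delta = delta,
         q_value = stats::setNames(q, rownames(mat)),
         selected = selected,
         pi0 = pi0,
         fdr_scan = scan,
         n_perm = B,
         target_fdr = target_fdr,
         fdr_method = fdr_method,
         class_levels = levels(labels),
         seed = seed),
    class = "sam_result"
  )
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM two-class result:", length(x$d), "genes,", x$n_perm,
      "permutations\n")
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, delta = %.4g (target FDR %.3g)\n",
              x$s0, x$pi0, x$delta, x$target_fdr))
  cat(sprintf("  %d genes selected (d > 0: %s over %s)\n", length(x$selected),
              x$class_levels[2], x$class_levels[1]))
  invisible(x)
}

#' Export a SAM result as a tab-separated table
#'
#' Writes one row per gene (gene_id, d, s, q_value, selected 0/1) preceded
#' by comment lines recording s0, delta, the permutation count and seed.
#'
#' @param result a [sam_two_class()] result.
#' @param path output file path.
#' @export
write_sam_result <- function(result, path) {
  stopifnot(inherits(result, "sam_result"))
  hdr <- sprintf("# s0=%.10g delta=%.10g n_perm=%d seed=%d pi0=%.6g",
                 result$s0, result$delta, result$n_perm, result$seed,
                 result$pi0)
  tab <- data.frame(gene_id = names(result$d),
                    d = as.numeric(result$d),
                    s = as.numeric(result$s),
                    q_value = as.numeric(result$q_value),
                    selected = as.integer(names(result$d) %in% result$selected))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
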
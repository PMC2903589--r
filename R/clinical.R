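# Contingency-table associations between the signature risk groups and
# clinicopathological variables, plus the immunohistochemistry scoring rule.

check_table <- function(table, what = "contingency table") {
  if (!is.matrix(table) || !is.numeric(table)) {
    stop_pdacsig(sprintf("%s must be a numeric matrix of counts", what),
                 "invalid_input")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop_pdacsig(sprintf("%s must hold nonnegative integer counts", what),
                 "invalid_input")
  }
  if (sum(table) == 0) {
    stop_pdacsig(sprintf("%s must have a positive total", what),
                 "invalid_input")
  }
  invisible(table)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' relative tolerance 1e-7). Used for signature-vs-binary-variable
#' associations (e.g. neoadjuvant therapy, margin status).
#'
#' @param table 2x2 integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  check_table(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop_pdacsig("table must be 2x2", "invalid_input")
  }
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test for an r x c table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' df = (r-1)(c-1); used for signature associations with variables of more
#' than two levels (T stage, grade).
#'
#' @param table r x c integer matrix, r,c >= 2, all margins positive.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_rxc <- function(table) {
  check_table(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop_pdacsig("table must be at least 2x2", "invalid_input")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_pdacsig("all row and column totals must be positive",
                 "invalid_input")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Immunohistochemistry I x P score
#'
#' Staining is scored as intensity I (integer 0 = no staining to 4 = strong
#' staining) times the proportion P of positive epithelial cells; a core is
#' considered positive only when more than 5% of cells express the marker
#' (P > 0.05), otherwise the staining is treated as negative and the score
#' forced to 0.
#'
#' @param I staining intensity, integer in 0..4.
#' @param P proportion of positive cells in [0, 1].
#' @return list with `score` in [0, 4] and logical `positive`.
#' @export
ihc_score <- function(I, P) {
  if (!(length(I) == 1L && I %in% 0:4)) {
    stop_pdacsig("I must be an integer in 0..4", "invalid_input")
  }
  if (!(length(P) == 1L && is.finite(P) && P >= 0 && P <= 1)) {
    stop_pdacsig("P must lie in [0, 1]", "invalid_input")
  }
  positive <- P > 0.05
  list(score = if (positive) I * P else 0, positive = positive)
}

#' Dichotomize scores at a cutoff
#'
#' Scores strictly above the cutoff are labelled "high", scores at or below
#' it "low". The default cutoff is the sample median (the convention used
#' for IHC score stratification, e.g. the 1.5 median cutoff).
#'
#' @param scores numeric scores.
#' @param cutoff scalar cutoff; defaults to `median(scores)`.
#' @return character vector of "high"/"low" labels, same order as input.
#' @export
dichotomize_by_median <- function(scores, cutoff = stats::median(scores)) {
  if (length(scores) == 0L) stop_pdacsig("scores must be nonempty",
                                         "invalid_input")
  ifelse(scores > cutoff, "high", "low")
}

#' Association tests between risk groups and clinical variables
#'
#' For each clinical variable, cross-tabulates risk group against the
#' variable (dropping, per variable, the samples with a missing value and
#' recording how many) and applies the Fisher exact test when the variable
#' has two levels or the Pearson chi-square test otherwise.
#'
#' @param risk character/factor risk labels (e.g. "high"/"low").
#' @param clinical data frame of clinical variables aligned with `risk`.
#' @return data frame with one row per variable: `variable`, `test`,
#'   `p`, `n_used`, `n_dropped`.
#' @export
association_tests <- function(risk, clinical) {
  if (!is.data.frame(clinical) || nrow(clinical) != length(risk)) {
    stop_pdacsig("clinical must be a data frame aligned with risk",
                 "invalid_input")
  }
  rows <- lapply(names(clinical), function(v) {
    x <- clinical[[v]]
    ok <- !is.na(x) & !is.na(risk)
    tab <- table(factor(x[ok]), factor(risk[ok]))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      return(data.frame(variable = v, test = "none", p = NA_real_,
                        n_used = sum(ok), n_dropped = sum(!ok)))
    }
    if (nrow(tab) == 2L && ncol(tab) == 2L) {
      data.frame(variable = v, test = "fisher",
                 p = fisher_exact_2x2(unclass(tab)[, , drop = FALSE]),
                 n_used = sum(ok), n_dropped = sum(!ok))
    } else {
      data.frame(variable = v, test = "chisq",
                 p = chi_square_rxc(unclass(tab)[, , drop = FALSE])$p,
                 n_used = sum(ok), n_dropped = sum(!ok))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
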
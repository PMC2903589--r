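# Distance-weighted discrimination (DWD) for systematic batch bias.
#
# DWD finds the linear direction w (||w|| <= 1) and intercept b minimizing
# sum_i 1/r_i + C * sum_i xi_i  subject to  r_i = y_i (w.x_i + b) + xi_i,
# r_i > 0, xi_i >= 0.  Eliminating xi analytically gives the equivalent
# smooth convex per-sample loss on the functional margin u = y (w.x + b):
#   V(u) = 1/u              for u >= 1/sqrt(C)
#   V(u) = 2*sqrt(C) - C*u  otherwise
# which we minimize over the unit ball by monotone projected gradient
# descent with backtracking.  Because the loss depends on w only through
# sample projections, the solve runs in the span of the samples
# (dimension <= n), then maps back to gene space.

dwd_loss <- function(u, C) {
  sC <- sqrt(C)
  ifelse(u >= 1 / sC, 1 / u, 2 * sC - C * u)
}

dwd_loss_grad <- function(u, C) {
  ifelse(u >= 1 / sqrt(C), -1 / u^2, -C)
}

#' Fit a DWD model separating two batches
#'
#' Fits distance-weighted discrimination between two expression batches
#' sharing an identical gene list, encoding batch membership as the class
#' label. The returned unit direction captures the systematic (location)
#' bias between the batches; its sign is fixed so the batch-B mean
#' projection is at least the batch-A mean projection.
#'
#' @param X_a,X_b genes x samples matrices with identical rownames; each
#'   batch needs >= 2 samples.
#' @param penalty positive penalty C; default `100 / median(between-batch
#'   pairwise distance)^2`, the standard data-driven heuristic.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the objective trace.
#' @return Object of class `dwd_model`: unit `direction` (named by gene),
#'   `intercept`, `penalty`, `batch_mean_proj` (named scalars for A and B),
#'   iterations and final objective.
#' @export
fit_dwd <- function(X_a, X_b, penalty = NULL, tol = 1e-7, max_iter = 20000L) {
  check_expression_matrix(X_a, "X_a")
  check_expression_matrix(X_b, "X_b")
  if (!identical(rownames(X_a), rownames(X_b))) {
    stop_pdacsig("batches must share an identical gene list (same order)",
                 "alignment_error")
  }
  if (ncol(X_a) < 2L || ncol(X_b) < 2L) {
    stop_pdacsig("each batch needs at least 2 samples", "invalid_input")
  }
  X <- cbind(X_a, X_b)
  y <- rep(c(-1, 1), c(ncol(X_a), ncol(X_b)))
  n <- ncol(X)

  if (is.null(penalty)) {
    cross <- as.matrix(stats::dist(t(X)))[seq_len(ncol(X_a)),
                                          ncol(X_a) + seq_len(ncol(X_b))]
    med <- stats::median(cross)
    if (med <= 0) med <- 1
    penalty <- 100 / med^2
  }
  if (penalty <= 0) stop_pdacsig("penalty must be positive", "invalid_input")
  C <- penalty

  # reduce to the span of the centered samples
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0)
  keep <- sv$d > max(sv$d[1], 1) * 1e-12
  if (!any(keep)) {
    stop_pdacsig("batches are identical; no direction to fit", "fit_failure")
  }
  Q <- sv$u[, keep, drop = FALSE]
  Z <- crossprod(Q, Xc)                 # r x n reduced coordinates

  obj <- function(beta, b) sum(dwd_loss(y * (drop(crossprod(Z, beta)) + b), C))
  grad <- function(beta, b) {
    u <- y * (drop(crossprod(Z, beta)) + b)
    g <- dwd_loss_grad(u, C) * y
    list(beta = drop(Z %*% g), b = sum(g))
  }
  project <- function(beta) {
    nb <- sqrt(sum(beta^2))
    if (nb > 1) beta / nb else beta
  }

  # initialize at the projected mean-difference direction
  mdiff <- rowMeans(Z[, y > 0, drop = FALSE]) - rowMeans(Z[, y < 0, drop = FALSE])
  nm <- sqrt(sum(mdiff^2))
  beta <- if (nm > 0) mdiff / nm else rep(1 / sqrt(nrow(Z)), nrow(Z))
  b <- -sum(beta * (rowMeans(Z[, y > 0, drop = FALSE]) +
                    rowMeans(Z[, y < 0, drop = FALSE]))) / 2

  f <- obj(beta, b)
  step <- 1 / max(1, C * sum(Z^2) / n)
  trace <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(beta, b)
    # monotone backtracking projected-gradient step
    repeat {
      beta_new <- project(beta - step * g$beta)
      b_new <- b - step * g$b
      f_new <- obj(beta_new, b_new)
      if (f_new <= f || step < 1e-16) break
      step <- step / 2
    }
    moved <- sqrt(sum((beta_new - beta)^2) + (b_new - b)^2)
    rel <- (f - f_new) / max(1, abs(f))
    beta <- beta_new; b <- b_new; f <- f_new
    trace <- c(trace, f)
    step <- step * 1.25
    if (rel < tol && moved < 1e2 * tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop_pdacsig(sprintf(
      "DWD solver did not converge in %d iterations (last objective %.6g, last relative change %.3g)",
      max_iter, f, rel), "fit_failure", trace = trace)
  }

  nb <- sqrt(sum(beta^2))
  if (nb == 0) stop_pdacsig("degenerate zero direction", "fit_failure")
  w <- drop(Q %*% (beta / nb))
  b_gene <- b / nb - sum(w * mu)        # intercept on the gene-space scale
  proj_a <- mean(crossprod(X_a, w))
  proj_b <- mean(crossprod(X_b, w))
  if (proj_b < proj_a) {
    w <- -w; b_gene <- -b_gene
    tmp <- proj_a; proj_a <- proj_b; proj_b <- tmp
  }
  structure(
    list(direction = stats::setNames(w, rownames(X_a)),
         intercept = b_gene,
         penalty = C,
         batch_mean_proj = c(A = proj_a, B = proj_b),
         iterations = it,
         objective = f,
         objective_trace = trace),
    class = "dwd_model"
  )
}

#' @export
print.dwd_model <- function(x, ...) {
  cat("DWD model:", length(x$direction), "genes; penalty C =",
      format(x$penalty, digits = 4), "\n")
  cat("  batch mean projections: A =", format(x$batch_mean_proj["A"], digits = 4),
      " B =", format(x$batch_mean_proj["B"], digits = 4), "\n")
  invisible(x)
}

#' Remove a systematic batch bias by translation along the DWD direction
#'
#' Translates every batch along the fitted direction so each batch's mean
#' projection onto the direction becomes zero. Within-batch deviations from
#' the batch mean are untouched (pure translation), so all within-batch
#' distances and covariances are preserved exactly.
#'
#' @param matrices a single genes x samples matrix or a list of them, one
#'   per batch; gene lists must match the model.
#' @param model a fitted [fit_dwd()] model.
#' @return Adjusted matrix or list of matrices (matching the input shape).
#' @export
dwd_adjust <- function(matrices, model) {
  stopifnot(inherits(model, "dwd_model"))
  single <- is.matrix(matrices)
  if (single) matrices <- list(matrices)
  out <- lapply(matrices, function(X) {
    check_expression_matrix(X)
    if (!identical(rownames(X), names(model$direction))) {
      stop_pdacsig("matrix gene list does not match the DWD model",
                   "alignment_error")
    }
    w <- model$direction
    m <- mean(crossprod(X, w))
    X - outer(w, rep(m, ncol(X)))
  })
  if (single) out[[1]] else out
}

#' Principal-component sample projection
#'
#' Projects samples onto the leading principal axes of the gene-centered
#' expression matrix — the PC1 x PC2 diagnostic used to inspect batch
#' structure before and after adjustment.
#'
#' @param mat genes x samples matrix.
#' @param n_components number of components, at most `min(genes, samples)`.
#' @return samples x n_components score matrix with a `var_explained`
#'   attribute (proportion of variance per returned component).
#' @export
pca_project <- function(mat, n_components = 2L) {
  check_expression_matrix(mat)
  if (ncol(mat) < 2L) stop_pdacsig("need >= 2 samples", "invalid_input")
  if (!is_count(n_components) || n_components > min(dim(mat))) {
    stop_pdacsig("n_components must be a count <= min(genes, samples)",
                 "invalid_input")
  }
  p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  attr(scores, "var_explained") <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  scores
}
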
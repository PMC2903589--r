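#' Configuration for a synthetic two-cohort expression study
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' emulate the study design the pipeline assumes: two cohorts of 15 primary
#' tumors each (one from patients with localized disease, one from patients
#' with metastatic disease), each with 15 matched normal pancreas samples,
#' a small set of truly class-differential genes, a systematic per-gene
#' batch offset between the cohorts, and censored overall-survival times
#' whose hazard depends on the true risk label.
#'
#' @param n_genes number of genes (rows) simulated.
#' @param n_per_class samples per class per cohort (15 mirrors the
#'   derivation cohorts; raise it for validation-cohort simulations).
#' @param n_de_genes number of truly differential genes; must not exceed
#'   `n_genes`.
#' @param effect_size mean log2-ratio shift of differential genes in the
#'   metastatic-cohort tumors relative to the localized-cohort tumors.
#'   The default 1.5 is three times the default `noise_sd`.
#' @param batch_shift magnitude of the per-gene systematic offset added to
#'   every sample of cohort B (sign drawn once per gene).
#' @param noise_sd within-class standard deviation of the additive Gaussian
#'   noise on log2 ratios.
#' @param baseline_hazard event rate per month for low-risk samples; the
#'   default `log(2)/20` gives a 20-month median survival, typical of
#'   resected pancreatic ductal adenocarcinoma.
#' @param hazard_ratio_true multiplicative hazard for high-risk samples
#'   (default 4, the magnitude reported for validated six-gene signatures
#'   in this disease).
#' @param censor_rate expected fraction of records censored.
#' @param seed integer RNG seed; identical seed and configuration give
#'   bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000L,
                       n_per_class = 15L,
                       n_de_genes = 6L,
                       effect_size = 1.5,
                       batch_shift = 1,
                       noise_sd = 0.5,
                       baseline_hazard = log(2) / 20,
                       hazard_ratio_true = 4,
                       censor_rate = 0.3,
                       seed = 1L) {
  if (!is_count(n_genes) || !is_count(n_per_class)) {
    stop_pdacsig("n_genes and n_per_class must be positive counts",
                 "invalid_config")
  }
  if (!(length(n_de_genes) == 1L && n_de_genes >= 0 &&
        n_de_genes == floor(n_de_genes))) {
    stop_pdacsig("n_de_genes must be a nonnegative count", "invalid_config")
  }
  if (n_de_genes > n_genes) {
    stop_pdacsig("n_de_genes must not exceed n_genes", "invalid_config")
  }
  if (batch_shift < 0 || noise_sd < 0 || baseline_hazard < 0 ||
      censor_rate < 0 || censor_rate >= 1) {
    stop_pdacsig("rates and standard deviations must be nonnegative (censor_rate < 1)",
                 "invalid_config")
  }
  if (hazard_ratio_true <= 0) {
    stop_pdacsig("hazard_ratio_true must be positive", "invalid_config")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_per_class = as.integer(n_per_class),
         n_de_genes = as.integer(n_de_genes),
         effect_size = effect_size,
         batch_shift = batch_shift,
         noise_sd = noise_sd,
         baseline_hazard = baseline_hazard,
         hazard_ratio_true = hazard_ratio_true,
         censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# exponential survival with independent exponential censoring calibrated so
# each sample is censored with probability censor_rate
simulate_survival_times <- function(rate, censor_rate) {
  n <- length(rate)
  t_event <- stats::rexp(n, rate)
  if (censor_rate <= 0) {
    return(data.frame(time_months = t_event, event = rep(1L, n)))
  }
  cens_rate <- rate * censor_rate / (1 - censor_rate)
  t_cens <- stats::rexp(n, cens_rate)
  data.frame(time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Simulate paired derivation cohorts with a batch offset
#'
#' Generates two cohorts (A, localized/nonmetastatic; B, metastatic), each
#' containing `n_per_class` tumors and `n_per_class` matched normal samples
#' over the same genes. Cohort B receives a per-gene systematic offset of
#' magnitude `batch_shift` (random sign, drawn once per gene, shared by all
#' cohort-B samples — the location bias that distance-weighted
#' discrimination models). `n_de_genes` randomly chosen genes additionally
#' receive a mean shift of `effect_size` (random sign per gene) in cohort-B
#' tumors only; normals carry the batch offset but never the class effect.
#'
#' @param config a [sim_config()].
#' @return An object of class `simulated_study`: a list with `expression`
#'   (genes x samples matrix of log2 ratios), `annotation` (data frame with
#'   sample_id, batch, tissue, class), `survival` (data frame with
#'   sample_id, time_months, event for the tumor samples), and `truth`
#'   (list with `de_genes`, the indices and IDs of the differential genes,
#'   and per-gene signed effects).
#' @export
simulate_derivation_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    npc <- config$n_per_class
    genes <- gene_ids(ng)

    baseline <- stats::rnorm(ng, 0, 1)
    batch_offset <- config$batch_shift * sample(c(-1, 1), ng, replace = TRUE)
    de_idx <- sort(sample.int(ng, config$n_de_genes))
    de_sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    class_effect <- numeric(ng)
    class_effect[de_idx] <- config$effect_size * de_sign

    groups <- list(
      A_tumor  = list(batch = "A", tissue = "tumor",  class = "nonmetastatic",
                      mean = baseline),
      A_normal = list(batch = "A", tissue = "normal", class = NA_character_,
                      mean = baseline),
      B_tumor  = list(batch = "B", tissue = "tumor",  class = "metastatic",
                      mean = baseline + batch_offset + class_effect),
      B_normal = list(batch = "B", tissue = "normal", class = NA_character_,
                      mean = baseline + batch_offset)
    )

    mats <- vector("list", length(groups))
    ann <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      ids <- sprintf("%s%s_%02d", g$batch,
                     if (g$tissue == "tumor") "T" else "N", seq_len(npc))
      m <- matrix(stats::rnorm(ng * npc, 0, config$noise_sd), ng, npc) + g$mean
      dimnames(m) <- list(genes, ids)
      mats[[i]] <- m
      ann[[i]] <- data.frame(sample_id = ids, batch = g$batch,
                             tissue = g$tissue, class = g$class,
                             stringsAsFactors = FALSE)
    }
    expression <- do.call(cbind, mats)
    annotation <- do.call(rbind, ann)
    rownames(annotation) <- NULL

    # overall survival for tumor samples: metastatic-class patients carry
    # the elevated hazard
    tumor <- annotation$tissue == "tumor"
    rate <- config$baseline_hazard *
      config$hazard_ratio_true^(annotation$class[tumor] == "metastatic")
    surv <- cbind(sample_id = annotation$sample_id[tumor],
                  simulate_survival_times(rate, config$censor_rate))

    structure(
      list(expression = expression,
           annotation = annotation,
           survival = surv,
           truth = list(de_genes = de_idx,
                        de_gene_ids = genes[de_idx],
                        de_effect = class_effect[de_idx],
                        batch_offset = batch_offset)),
      class = "simulated_study"
    )
  })
}

#' Simulate an independent validation cohort around a centroid
#'
#' Generates a cohort of `2 * n_per_class` tumor samples whose signature-gene
#' profiles are drawn either around the supplied centroid (low-risk pattern)
#' or around its reflection about the centroid mean (high-risk,
#' anti-correlated pattern), plus Gaussian noise everywhere. Each sample's
#' *true* risk label is then assigned from the sign of its realized Pearson
#' correlation to the centroid (negative or zero correlation = high risk),
#' and overall survival is drawn from an exponential model with hazard
#' `baseline_hazard * hazard_ratio_true^(high risk)` under independent
#' exponential censoring calibrated to `censor_rate`.
#'
#' @param config a [sim_config()]; `n_per_class` is the intended size of
#'   each risk arm.
#' @param centroid a [build_centroid()] result (class `centroid`); its gene
#'   list must be contained in the simulated gene universe.
#' @return A `simulated_study` whose `truth` element carries `risk`
#'   (high/low per sample) and the realized correlation `r`.
#' @export
simulate_validation_cohort <- function(config, centroid) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(centroid, "centroid") || length(centroid$means) == 0L) {
    stop_pdacsig("centroid must be a nonempty 'centroid' object",
                 "invalid_input")
  }
  ng <- config$n_genes
  genes <- gene_ids(ng)
  missing_genes <- setdiff(centroid$genes, genes)
  if (length(missing_genes) > 0L) {
    stop_pdacsig(paste0("centroid genes absent from simulated universe: ",
                        paste(missing_genes, collapse = ", ")),
                 "invalid_input")
  }
  with_seed(config$seed + 1L, {
    n <- 2L * config$n_per_class
    ids <- sprintf("V_%03d", seq_len(n))
    baseline <- stats::rnorm(ng, 0, 1)
    expr <- matrix(stats::rnorm(ng * n, 0, config$noise_sd), ng, n) + baseline
    dimnames(expr) <- list(genes, ids)

    # intended pattern: first half follow the centroid, second half its
    # reflection about the centroid mean (anti-correlated)
    cen <- centroid$means
    reflected <- 2 * mean(cen) - cen
    intended_low <- rep(c(TRUE, FALSE), each = config$n_per_class)
    sig_rows <- match(centroid$genes, genes)
    for (j in seq_len(n)) {
      pattern <- if (intended_low[j]) cen else reflected
      expr[sig_rows, j] <- pattern + stats::rnorm(length(sig_rows), 0,
                                                  config$noise_sd)
    }

    r <- apply(expr[sig_rows, , drop = FALSE], 2, stats::cor, y = cen)
    risk <- ifelse(r > 0, "low", "high")   # r <= 0 (distance >= 1) is high risk

    rate <- config$baseline_hazard *
      config$hazard_ratio_true^(risk == "high")
    surv <- cbind(sample_id = ids,
                  simulate_survival_times(rate, config$censor_rate))
    annotation <- data.frame(sample_id = ids, batch = "V", tissue = "tumor",
                             class = NA_character_, stringsAsFactors = FALSE)

    structure(
      list(expression = expr, annotation = annotation, survival = surv,
           truth = list(risk = stats::setNames(risk, ids),
                        r = stats::setNames(r, ids))),
      class = "simulated_study"
    )
  })
}

#' Inject missing values completely at random
#'
#' Masks a fraction of entries of an expression matrix with `NA`, for
#' exercising k-nearest-neighbour imputation on data with a known truth.
#'
#' @param mat genes x samples numeric matrix.
#' @param rate expected fraction of entries masked (default 2%).
#' @param seed RNG seed.
#' @return The matrix with masked entries set to `NA`.
#' @export
inject_missing <- function(mat, rate = 0.02, seed = 1L) {
  check_expression_matrix(mat)
  stopifnot(rate >= 0, rate < 1)
  with_seed(seed, {
    mask <- stats::runif(length(mat)) < rate
    mat[mask] <- NA_real_
    mat
  })
}
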
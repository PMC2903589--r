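# End-to-end derivation -> training -> test pipeline driver.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the full signature pipeline. The
#' defaults are the values used throughout this class of study: intensity
#' filter threshold 10 in at least 70% of experiments, KNN imputation with
#' k = 10, SAM at a target FDR of 5%, and an SSP distance cut-point learned
#' on the training set and frozen before the test set is touched.
#'
#' @param filter_threshold spot mean-intensity threshold (strict >).
#' @param filter_fraction required fraction of experiments passing.
#' @param knn_k neighbours for imputation.
#' @param sam_fdr target median FDR for signature selection.
#' @param sam_n_perm label permutations for SAM.
#' @param dwd_penalty DWD penalty C; `NULL` = data-driven default.
#' @param cutpoint_min_group minimum group size for the cut-point scan.
#' @param ties Cox tie handling, "efron" or "breslow".
#' @param seed integer seed used for every stochastic stage.
#' @param output_dir if non-`NULL`, artifacts are written here.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_threshold = 10,
                            filter_fraction = 0.7,
                            knn_k = 10L,
                            sam_fdr = 0.05,
                            sam_n_perm = 1000L,
                            dwd_penalty = NULL,
                            cutpoint_min_group = 5L,
                            ties = "efron",
                            seed = 1L,
                            output_dir = NULL) {
  structure(
    list(filter_threshold = filter_threshold,
         filter_fraction = filter_fraction,
         knn_k = as.integer(knn_k),
         sam_fdr = sam_fdr,
         sam_n_perm = as.integer(sam_n_perm),
         dwd_penalty = dwd_penalty,
         cutpoint_min_group = as.integer(cutpoint_min_group),
         ties = match.arg(ties, c("efron", "breslow")),
         seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_pdacsig(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), "pipeline_failure")
  })
}

#' Run the full signature derivation / training / test pipeline
#'
#' Executes the workflow: impute missing values, DWD-adjust the two
#' derivation cohorts against each other (anchored on tumor-normal pairs
#' when the annotation marks tissue), run two-class SAM on the derivation
#' tumors to select the signature, build the resected (nonmetastatic) and
#' metastatic centroids; then DWD-adjust the training cohort toward the
#' adjusted derivation data, compute each training sample's SSP distance to
#' the resected centroid, and learn the survival-optimal distance cut-point;
#' finally apply the frozen cut-point to the test cohort (never
#' re-optimized) and report risk calls, Kaplan-Meier curves, the log-rank
#' test, a multivariable Cox fit (signature + any supplied clinical
#' covariates) and risk-vs-clinical association tests.
#'
#' @param derivation_a,derivation_b the two derivation cohorts: lists with
#'   `expression` (genes x samples matrix) and `annotation` (data frame with
#'   sample_id, tissue, ...). Cohort A is the nonmetastatic/resected class.
#' @param training list with `expression` and `survival` (data frame
#'   sample_id, time_months, event).
#' @param test optional list like `training`, optionally with `clinical`
#'   (data frame of covariates, rownames or `sample_id` column aligned to
#'   samples).
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with elements `signature`,
#'   `sam`, `centroids`, `training` (calls + cutpoint), `test` (calls, KM,
#'   log-rank, Cox, associations; `NULL` when no test cohort was supplied),
#'   `config`, and `status`.
#' @export
run_pipeline <- function(derivation_a, derivation_b, training, test = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  impute_if_needed <- function(mat) {
    if (anyNA(mat)) knn_impute(mat, config$knn_k) else mat
  }
  Xa <- pipeline_stage("impute", impute_if_needed(derivation_a$expression))
  Xb <- pipeline_stage("impute", impute_if_needed(derivation_b$expression))

  # DWD between derivation cohorts, anchored on tumor-normal pairs when
  # tissue annotation is present, otherwise on all samples
  pick_anchor <- function(X, ann) {
    if (!is.null(ann) && "tissue" %in% names(ann)) {
      ids <- ann$sample_id[ann$tissue %in% c("tumor", "normal")]
      X[, intersect(colnames(X), ids), drop = FALSE]
    } else X
  }
  model <- pipeline_stage("batch_dwd", {
    fit_dwd(pick_anchor(Xa, derivation_a$annotation),
            pick_anchor(Xb, derivation_b$annotation),
            penalty = config$dwd_penalty)
  })
  adj <- pipeline_stage("batch_dwd", dwd_adjust(list(Xa, Xb), model))
  Xa_adj <- adj[[1]]; Xb_adj <- adj[[2]]

  tumors_of <- function(X, ann) {
    if (!is.null(ann) && "tissue" %in% names(ann)) {
      X[, intersect(colnames(X), ann$sample_id[ann$tissue == "tumor"]),
        drop = FALSE]
    } else X
  }
  Ta <- tumors_of(Xa_adj, derivation_a$annotation)
  Tb <- tumors_of(Xb_adj, derivation_b$annotation)

  sam <- pipeline_stage("sam_de", {
    sam_two_class(cbind(Ta, Tb),
                  rep(c("nonmetastatic", "metastatic"),
                      c(ncol(Ta), ncol(Tb))),
                  n_perm = config$sam_n_perm,
                  target_fdr = config$sam_fdr,
                  seed = config$seed)
  })
  signature <- sam$selected
  if (length(signature) == 0L) {
    stop_pdacsig("pipeline stage 'sam_de' failed: no genes selected at the target FDR",
                 "pipeline_failure")
  }

  centroids <- pipeline_stage("centroid", list(
    resected = build_centroid(Ta, colnames(Ta), signature, "resected"),
    metastatic = build_centroid(Tb, colnames(Tb), signature, "metastatic")
  ))

  # training: adjust toward the (already adjusted) derivation space, then
  # learn the cut-point on SSP distances
  adjust_cohort <- function(X) {
    ref <- cbind(Xa_adj, Xb_adj)
    m <- fit_dwd(ref, X, penalty = config$dwd_penalty)
    dwd_adjust(X, m)
  }
  train_adj <- pipeline_stage("train_adjust",
                              adjust_cohort(impute_if_needed(training$expression)))
  train_calls0 <- pipeline_stage("train_classify",
                                 classify_samples(train_adj[signature, ,
                                                            drop = FALSE],
                                                  centroids$resected,
                                                  cutpoint = 1))
  train_surv <- training$survival[match(train_calls0$sample_id,
                                        training$survival$sample_id), ]
  cutpoint <- pipeline_stage("xtile_cutpoint", {
    xtile_cutpoint(train_calls0$distance, train_surv,
                   min_group = config$cutpoint_min_group)
  })
  train_calls <- transform(train_calls0,
                           risk = classify_risk(r, cutpoint$cutpoint))

  report <- list(
    signature = signature,
    sam = sam,
    dwd_model = model,
    centroids = centroids,
    training = list(calls = train_calls, cutpoint = cutpoint),
    test = NULL,
    config = config,
    status = "training_only"
  )

  if (!is.null(test)) {
    test_adj <- pipeline_stage("test_adjust",
                               adjust_cohort(impute_if_needed(test$expression)))
    # frozen cut-point from the training stage; never re-optimized
    calls <- pipeline_stage("test_classify",
                            classify_samples(test_adj[signature, ,
                                                      drop = FALSE],
                                             centroids$resected,
                                             cutpoint = cutpoint$cutpoint))
    surv <- test$survival[match(calls$sample_id, test$survival$sample_id), ]
    km <- lapply(split(surv, calls$risk), km_estimate)
    lr <- if (length(unique(calls$risk)) >= 2L) {
      logrank_test(surv, calls$risk)
    } else NULL
    covars <- data.frame(signature_high = as.integer(calls$risk == "high"))
    if (!is.null(test$clinical)) covars <- cbind(covars, test$clinical)
    cox <- tryCatch(cox_fit(surv, covars, ties = config$ties),
                    error = function(e) e)
    assoc <- if (!is.null(test$clinical)) {
      association_tests(calls$risk, test$clinical)
    } else NULL
    report$test <- list(calls = calls, km = km, logrank = lr, cox = cox,
                        associations = assoc)
    report$status <- "complete"
  }
  class(report) <- "pipeline_report"

  if (!is.null(config$output_dir)) write_pipeline_report(report)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Signature pipeline report (", x$status, ")\n", sep = "")
  cat("  signature:", length(x$signature), "genes:",
      paste(utils::head(x$signature, 10), collapse = ", "), "\n")
  cat(sprintf("  training cut-point: distance %.3f (naive p %.4g)\n",
              x$training$cutpoint$cutpoint, x$training$cutpoint$naive_p))
  if (!is.null(x$test)) {
    tab <- table(x$test$calls$risk)
    cat("  test risk groups:", paste(sprintf("%s = %d", names(tab), tab),
                                     collapse = ", "), "\n")
    if (!is.null(x$test$logrank)) {
      cat(sprintf("  test log-rank p = %.4g\n", x$test$logrank$p))
    }
  }
  invisible(x)
}

#' Write pipeline artifacts to the configured output directory
#'
#' Writes the SAM table, the centroids, the risk calls, the cut-point and
#' a JSON manifest echoing the configuration and seed.
#'
#' @param report a `pipeline_report` whose config has a non-`NULL`
#'   `output_dir`.
#' @return the output directory, invisibly.
#' @export
write_pipeline_report <- function(report) {
  dir <- report$config$output_dir
  stopifnot(!is.null(dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sam_result(report$sam, file.path(dir, "sam_result.tsv"))
  write_centroid(report$centroids$resected,
                 file.path(dir, "centroid_resected.tsv"))
  write_centroid(report$centroids$metastatic,
                 file.path(dir, "centroid_metastatic.tsv"))
  utils::write.csv(report$training$calls,
                   file.path(dir, "training_risk_calls.csv"),
                   row.names = FALSE, quote = FALSE)
  summary_list <- list(
    status = report$status,
    signature = report$signature,
    cutpoint = report$training$cutpoint$cutpoint,
    cutpoint_naive_p = report$training$cutpoint$naive_p,
    cutpoint_corrected_p = report$training$cutpoint$corrected_p,
    config = report$config[setdiff(names(report$config), "output_dir")]
  )
  if (!is.null(report$test)) {
    utils::write.csv(report$test$calls,
                     file.path(dir, "test_risk_calls.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(report$test$logrank)) {
      summary_list$test_logrank_p <- report$test$logrank$p
    }
    if (inherits(report$test$cox, "cox_fit")) {
      summary_list$test_cox <- cbind(covariate =
                                       rownames(report$test$cox$table),
                                     report$test$cox$table)
    }
    if (!is.null(report$test$associations)) {
      summary_list$test_associations <- report$test$associations
    }
  }
  jsonlite::write_json(summary_list, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
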
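test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_de_genes = 50, n_genes = 10), class = "invalid_config")
  expect_error(sim_config(noise_sd = -1), class = "invalid_config")
  expect_error(sim_config(hazard_ratio_true = 0), class = "invalid_config")
  expect_error(sim_config(n_per_class = 0), class = "invalid_config")
})

test_that("identical seed and config give bit-identical studies", {
  cfg <- sim_config(n_genes = 50, n_per_class = 5, seed = 99)
  s1 <- simulate_derivation_sets(cfg)
  s2 <- simulate_derivation_sets(cfg)
  expect_identical(s1, s2)
  cen <- build_centroid(s1$expression, s1$annotation$sample_id[1:3],
                        rownames(s1$expression)[1:5])
  expect_identical(simulate_validation_cohort(cfg, cen),
                   simulate_validation_cohort(cfg, cen))
})

test_that("spiked genes carry the largest class mean differences", {
  cfg <- sim_config(n_genes = 200, n_per_class = 15, n_de_genes = 6,
                    effect_size = 3, noise_sd = 0.5, batch_shift = 0,
                    seed = 11)
  st <- simulate_derivation_sets(cfg)
  tum <- derivation_tumors(st)
  diff <- abs(rowMeans(tum$mat[, tum$labels == "metastatic"]) -
              rowMeans(tum$mat[, tum$labels == "nonmetastatic"]))
  top6 <- order(diff, decreasing = TRUE)[1:6]
  expect_setequal(top6, st$truth$de_genes)
})

test_that("normals carry the batch offset but not the class effect", {
  cfg <- sim_config(n_genes = 400, n_per_class = 40, n_de_genes = 5,
                    effect_size = 3, batch_shift = 2, noise_sd = 0.2,
                    seed = 12)
  st <- simulate_derivation_sets(cfg)
  ann <- st$annotation
  nA <- st$expression[, ann$sample_id[ann$batch == "A" & ann$tissue == "normal"]]
  nB <- st$expression[, ann$sample_id[ann$batch == "B" & ann$tissue == "normal"]]
  shift_hat <- rowMeans(nB) - rowMeans(nA)
  # per-gene normal-vs-normal shift tracks the drawn batch offset, with no
  # extra displacement at the differential genes
  expect_lt(max(abs(shift_hat - st$truth$batch_offset)), 0.25)
})

test_that("null configuration gives uncorrelated samples", {
  cfg <- sim_config(n_genes = 500, n_per_class = 10, n_de_genes = 0,
                    effect_size = 0, batch_shift = 0, noise_sd = 1, seed = 13)
  st <- simulate_derivation_sets(cfg)
  cc <- cor(st$expression - rowMeans(st$expression))
  off <- cc[upper.tri(cc)]
  # row-centering with n samples induces a known -1/(n-1) artifact on
  # otherwise independent columns; beyond that, samples are uncorrelated
  expect_lt(abs(mean(off) + 1 / (ncol(st$expression) - 1)), 0.02)
})

test_that("validation cohort truth follows the correlation-sign rule", {
  cfg <- sim_config(n_genes = 100, n_per_class = 30, seed = 14)
  der <- simulate_derivation_sets(cfg)
  cen <- build_centroid(der$expression,
                        der$annotation$sample_id[der$annotation$tissue == "tumor" &
                                                 der$annotation$batch == "A"],
                        der$truth$de_gene_ids)
  val <- simulate_validation_cohort(cfg, cen)
  r <- apply(val$expression[cen$genes, ], 2, cor, y = cen$means)
  expect_identical(unname(val$truth$risk), unname(ifelse(r > 0, "low", "high")))
  expect_error(simulate_validation_cohort(cfg, list()), class = "invalid_input")
})

test_that("censoring is calibrated and censor_rate 0 gives all events", {
  cfg0 <- sim_config(n_genes = 20, n_per_class = 150, censor_rate = 0,
                     seed = 15)
  der <- simulate_derivation_sets(cfg0)
  expect_true(all(der$survival$event == 1L))

  cfg <- sim_config(n_genes = 20, n_per_class = 150, censor_rate = 0.3,
                    seed = 16)
  der2 <- simulate_derivation_sets(cfg)
  frac <- mean(der2$survival$event == 0L)
  expect_lt(abs(frac - 0.3), 0.10)
})

test_that("log-rank between true risk groups is null-calibrated when HR = 1", {
  set.seed(17)
  ps <- vapply(1:120, function(i) {
    cfg <- sim_config(n_genes = 40, n_per_class = 50, n_de_genes = 4,
                      hazard_ratio_true = 1, seed = 5000 + i)
    der <- simulate_derivation_sets(cfg)
    cen <- build_centroid(der$expression,
                          der$annotation$sample_id[der$annotation$tissue == "tumor" &
                                                   der$annotation$batch == "A"],
                          der$truth$de_gene_ids)
    val <- simulate_validation_cohort(cfg, cen)
    logrank_test(val$survival, val$truth$risk[val$survival$sample_id])$p
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.88)
})

test_that("inject_missing masks approximately the requested fraction", {
  m <- make_matrix(rnorm(5000), 100, 50)
  mm <- inject_missing(m, rate = 0.05, seed = 3)
  expect_lt(abs(mean(is.na(mm)) - 0.05), 0.02)
  obs <- !is.na(mm)
  expect_identical(mm[obs], m[obs])
})
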
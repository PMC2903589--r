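sim_tumors <- function(n_genes = 200, n_per_class = 15, n_de = 0,
                       effect = 0, noise = 1, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, n_per_class = n_per_class,
                    n_de_genes = n_de, effect_size = effect,
                    noise_sd = noise, batch_shift = 0, seed = seed)
  derivation_tumors(simulate_derivation_sets(cfg))
}

test_that("compute_s0 handles the degenerate equal-scatter case", {
  s <- rep(2, 50)
  num <- rnorm(50)
  s0 <- compute_s0(num, s)
  expect_equal(as.numeric(s0), 2)      # 5th percentile of a constant
  expect_error(compute_s0(rnorm(5), rep(1, 5)), class = "invalid_input")
})

test_that("compute_s0 stabilizes variance-inflated low-scatter genes", {
  set.seed(31)
  # low-scatter genes have inflated d when s0 = 0
  s <- c(runif(300, 0.01, 0.05), runif(300, 1, 2))
  num <- c(rnorm(300, 0, 0.5), rnorm(300, 0, 2))
  s0 <- compute_s0(num, s)
  expect_gt(as.numeric(s0), 0)
  cv_at <- function(s0v) {
    d <- num / (s + s0v)
    win <- cut(s, quantile(s, seq(0, 1, length.out = 21)),
               include.lowest = TRUE)
    v <- tapply(d, win, mad)
    sd(v) / mean(v)
  }
  expect_lt(cv_at(as.numeric(s0)), cv_at(0))
})

test_that("s0 is scale-equivariant", {
  set.seed(32)
  s <- runif(100, 0.1, 2)
  num <- rnorm(100)
  s0 <- compute_s0(num, s)
  s0c <- compute_s0(3 * num, 3 * s)
  expect_equal(as.numeric(s0c), 3 * as.numeric(s0), tolerance = 1e-10)
})

test_that("swapping class labels negates d and keeps the selected set", {
  tum <- sim_tumors(n_genes = 150, n_de = 5, effect = 2, noise = 0.5,
                    seed = 33)
  r1 <- sam_two_class(tum$mat, tum$labels, n_perm = 50, seed = 2)
  flipped <- ifelse(tum$labels == "metastatic", "zz_other", "aa_first")
  r2 <- sam_two_class(tum$mat, flipped, n_perm = 50, seed = 2)
  expect_equal(unname(r2$d), -unname(r1$d), tolerance = 1e-12)
  expect_setequal(r2$selected, r1$selected)
})

test_that("duplicating every sample of a 2v2 design rescales d by sqrt(3)", {
  set.seed(34)
  m <- make_matrix(rnorm(30 * 4), 30, 4)
  lab <- c("x", "x", "y", "y")
  parts1 <- pdacsig:::sam_stat_parts(m, lab == "y")
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("s%02d", 1:8)
  parts2 <- pdacsig:::sam_stat_parts(m2, rep(lab == "y", 2))
  # group means unchanged; the pooled scatter contracts by exactly sqrt(3),
  # so with the (scale-equivariant) s0 refit the statistic rescales
  expect_equal(parts2$num, parts1$num, tolerance = 1e-12)
  expect_equal(parts2$s, parts1$s / sqrt(3), tolerance = 1e-12)
})

test_that("SAM is reproducible under a fixed seed and warns on tiny n_perm", {
  tum <- sim_tumors(n_genes = 60, seed = 35)
  r1 <- sam_two_class(tum$mat, tum$labels, n_perm = 40, seed = 9)
  r2 <- sam_two_class(tum$mat, tum$labels, n_perm = 40, seed = 9)
  expect_identical(r1[c("d", "s0", "delta", "q_value", "selected")],
                   r2[c("d", "s0", "delta", "q_value", "selected")])
  expect_warning(sam_two_class(tum$mat, tum$labels, n_perm = 5, seed = 1),
                 "n_perm")
})

test_that("q-values are proper and the selected set matches the stated delta", {
  tum <- sim_tumors(n_genes = 150, n_de = 5, effect = 2, noise = 0.5,
                    seed = 36)
  r <- sam_two_class(tum$mat, tum$labels, n_perm = 60, seed = 3)
  expect_true(all(r$q_value >= 0 & r$q_value <= 1))
  row <- r$fdr_scan[match(r$delta, r$fdr_scan$delta), ]
  called <- names(r$d)[r$d >= row$cutup | r$d <= row$cutlow]
  expect_setequal(r$selected, called)
  # selected count is nonincreasing in delta across the scan
  expect_true(all(diff(r$fdr_scan$n_called) <= 0))
})

test_that("selection is monotone as the target FDR tightens", {
  tum <- sim_tumors(n_genes = 200, n_de = 8, effect = 1.5, noise = 0.5,
                    seed = 37)
  sizes <- vapply(c(0.25, 0.10, 0.05, 0.01), function(f) {
    length(sam_two_class(tum$mat, tum$labels, n_perm = 60, target_fdr = f,
                         seed = 4)$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("SAM separates spiked genes from null genes (small replicate check)", {
  hits <- vapply(1:5, function(i) {
    tum <- sim_tumors(n_genes = 500, n_de = 6, effect = 1.5, noise = 0.5,
                      seed = 400 + i)
    cfg <- sim_config(n_genes = 500, n_per_class = 15, n_de_genes = 6,
                      effect_size = 1.5, noise_sd = 0.5, batch_shift = 0,
                      seed = 400 + i)
    truth <- simulate_derivation_sets(cfg)$truth$de_gene_ids
    res <- sam_two_class(tum$mat, tum$labels, n_perm = 60, seed = 5)
    all(truth %in% res$selected)
  }, logical(1))
  expect_true(all(hits))
})

test_that("single-class labels and missing values are rejected", {
  tum <- sim_tumors(n_genes = 30, seed = 38)
  expect_error(sam_two_class(tum$mat, rep("a", ncol(tum$mat))),
               class = "invalid_input")
  m <- tum$mat
  m[1, 1] <- NA
  expect_error(sam_two_class(m, tum$labels), class = "invalid_input")
})

test_that("SAM results round-trip through the exported table", {
  tum <- sim_tumors(n_genes = 50, seed = 39)
  r <- sam_two_class(tum$mat, tum$labels, n_perm = 30, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sam_result(r, path)
  tab <- read.delim(path, comment.char = "#")
  expect_equal(tab$d, unname(r$d), tolerance = 1e-6)
  expect_equal(tab$gene_id[tab$selected == 1], r$selected)
})
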
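# shared fixtures, built in code at test time

# small expression matrix with standard dimnames
make_matrix <- function(values, n_genes, n_samples,
                        genes = sprintf("g%02d", seq_len(n_genes)),
                        samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_genes, n_samples, dimnames = list(genes, samples))
}

# spot-level table for preprocess tests
make_spots <- function(red, green, gene_id = sprintf("g%02d", seq_along(red)),
                       flag = NULL) {
  d <- data.frame(gene_id = gene_id, red_mean = red, green_mean = green,
                  stringsAsFactors = FALSE)
  if (!is.null(flag)) d$flag <- flag
  d
}

# exponential two-group survival data with a known hazard ratio
make_exp_survival <- function(n, hr, high = rep(c(FALSE, TRUE), length.out = n),
                              baseline = log(2) / 20, censor_rate = 0) {
  rate <- baseline * hr^high
  t_event <- rexp(n, rate)
  if (censor_rate > 0) {
    t_cens <- rexp(n, rate * censor_rate / (1 - censor_rate))
    rec <- data.frame(time_months = pmin(t_event, t_cens),
                      event = as.integer(t_event <= t_cens))
  } else {
    rec <- data.frame(time_months = t_event, event = rep(1L, n))
  }
  list(records = rec, high = high)
}

# independent brute-force oracle for the two-sided Fisher exact test:
# enumerate every 2x2 table with the observed margins and sum the
# hypergeometric probabilities not exceeding the observed one
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tumor-sample expression and class labels from a simulated derivation study
derivation_tumors <- function(study) {
  ann <- study$annotation
  ids <- ann$sample_id[ann$tissue == "tumor"]
  list(mat = study$expression[, ids, drop = FALSE],
       labels = ann$class[match(ids, ann$sample_id)])
}
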
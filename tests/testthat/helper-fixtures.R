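# Small in-code fixtures shared across test files.

# samples x lipids matrix with given values (vectors recycled by column)
make_matrix <- function(values, samples, lipids, units = "pmol") {
  m <- matrix(values, nrow = length(samples), ncol = length(lipids),
              dimnames = list(samples, lipids))
  lipidome_matrix(m, units = units)
}

# complete two-group mol% matrix with log-normal noise and planted log2
# effects (named vector, group2 relative to group1)
make_two_group <- function(n1 = 10, n2 = 10,
                           lipids = sprintf("PC [%d:1]", seq(20, 98, 2)),
                           effects = NULL, sigma = 0.2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  base <- stats::runif(length(lipids), 3, 6)
  lab <- rep(c("g1", "g2"), c(n1, n2))
  lm2 <- matrix(rep(base, each = n), n, length(lipids),
                dimnames = list(sprintf("S%02d", seq_len(n)), lipids))
  if (!is.null(effects))
    lm2[lab == "g2", names(effects)] <-
      sweep(lm2[lab == "g2", names(effects), drop = FALSE], 2, effects, "+")
  lm2 <- lm2 + matrix(stats::rnorm(n * length(lipids), 0, sigma), n)
  amounts <- lipidome_matrix(2^lm2, units = "pmol")
  list(matrix = normalize_relative(amounts), labels = factor(lab))
}

# intensity records data frame
make_records <- function(name, sample_id, intensity, ppm = 0,
                         ion_mode = "positive") {
  data.frame(name = name, sample_id = sample_id, intensity = intensity,
             mass_error_ppm = ppm, ion_mode = ion_mode,
             stringsAsFactors = FALSE)
}

# brute-force AUC oracle: exhaustive pairwise comparison with half-credit ties
auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
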
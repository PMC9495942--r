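# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (loops, pair counting, enumeration) and
# never call the package's own code paths.

options(mirbias.quiet = TRUE)

# Pearson chi-square recomputed element by element from the formula.
chi2_brute <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Permutation p-value by literally shuffling category labels over items and
# recounting the table. Slow; for small B triangulation only.
chi2_perm_labels <- function(tab, B, seed) {
  withr::with_seed(seed, {
    rows <- rep(seq_len(nrow(tab)), rowSums(tab))
    cols <- rep.int(rep(seq_len(ncol(tab)), nrow(tab)), as.vector(t(tab)))
    obs <- chi2_brute(tab)
    hits <- 0
    for (b in seq_len(B)) {
      t_b <- table(rows, sample(cols))
      if (chi2_brute(t_b) >= obs - 1e-12) hits <- hits + 1
    }
    (1 + hits) / (B + 1)
  })
}

# AUC by exhaustive pair counting, ties worth 1/2.
auc_pairs <- function(cases, controls) {
  s <- 0
  for (x in cases) {
    for (y in controls) {
      s <- s + (x > y) + 0.5 * (x == y)
    }
  }
  s / (length(cases) * length(controls))
}

# Random r x c count table with roughly uniform cell probabilities.
random_table <- function(n, nrow = 2, ncol = 3) {
  p <- rgamma(nrow * ncol, shape = 2)
  matrix(as.vector(stats::rmultinom(1, n, p / sum(p))), nrow, ncol)
}

expect_no_hit_rate_above <- function(rate, nominal, n_rep, k_se = 2) {
  expect_lte(rate, nominal + k_se * sqrt(nominal * (1 - nominal) / n_rep))
}
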
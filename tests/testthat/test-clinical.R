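balanced_2x2 <- data.frame(
  y = c(1, 3, 2, 4, 5, 7, 10, 12),
  disease = rep(c("control", "case"), each = 4),
  phase = rep(rep(c("follicular", "luteal"), each = 2), 2)
)

test_that("balanced two-way ANOVA reproduces the hand decomposition", {
  # cell means 2, 3, 6, 11; grand mean 5.5
  # SS_A = 72, SS_B = 18, SS_AB = 8, SS_resid = 8, SS_total = 106
  tab <- two_way_anova(balanced_2x2, y, disease, phase)
  ss <- setNames(tab$sumsq, tab$term)
  expect_equal(ss[["disease"]], 72)
  expect_equal(ss[["phase"]], 18)
  expect_equal(ss[["disease:phase"]], 8)
  expect_equal(ss[["Residuals"]], 8)
  expect_equal(sum(tab$sumsq), 106, tolerance = 1e-12)
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(attr(tab, "ss_type"), "I (classical, balanced)")
})

test_that("SS additivity holds on random balanced designs", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(2:6, 1)
      d <- expand.grid(A = letters[1:3], B = LETTERS[1:2])
      d <- d[rep(seq_len(nrow(d)), each = n), ]
      d$y <- rnorm(nrow(d))
      tab <- two_way_anova(d, y, A, B)
      total <- sum((d$y - mean(d$y))^2)
      expect_equal(sum(tab$sumsq), total, tolerance = 1e-9 * total)
    }
  })
})

test_that("additive means with zero noise give zero interaction SS", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  d <- d[rep(1:4, each = 3), ]
  d$y <- 2 * (d$A == "a2") + 5 * (d$B == "b2") + 1
  tab <- suppressWarnings(two_way_anova(d, y, A, B))  # perfect fit by design
  expect_equal(tab$sumsq[tab$term == "A:B"], 0, tolerance = 1e-12)
})

test_that("unbalanced designs use Type II sums of squares", {
  withr::with_seed(8, {
    d <- data.frame(
      A = sample(c("a1", "a2"), 40, TRUE, prob = c(0.7, 0.3)),
      B = sample(c("b1", "b2"), 40, TRUE),
      y = rnorm(40)
    )
    tab <- two_way_anova(d, y, A, B)
    expect_equal(attr(tab, "ss_type"), "II")
    # Type II SS for A = increment over the B-only model
    ss_a <- sum(stats::residuals(lm(y ~ B, d))^2) -
      sum(stats::residuals(lm(y ~ A + B, d))^2)
    expect_equal(tab$sumsq[tab$term == "A"], ss_a, tolerance = 1e-9)
  })

  bad <- data.frame(A = c("a", "a", "b"), B = c("x", "y", "x"),
                    y = c(1, 2, 3))
  expect_error(two_way_anova(bad, y, A, B), "empty design cell")
})

test_that("factorial null p-values are approximately uniform", {
  withr::with_seed(91, {
    ps <- replicate(200, {
      d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
      d <- d[rep(1:4, each = 5), ]
      d$y <- rnorm(20)
      tab <- two_way_anova(d, y, A, B)
      tab$p_value[tab$term == "A:B"]
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
    expect_no_hit_rate_above(mean(ps < 0.05), 0.05, 200, k_se = 3)
  })
})

test_that("two-group SNK reduces to the pooled two-sample t-test", {
  withr::with_seed(14, {
    d <- data.frame(y = c(rnorm(8), rnorm(8, 1)),
                    g = rep(c("ctrl", "endo"), each = 8))
    snk <- snk_posthoc(d, y, g)
    expect_equal(nrow(snk), 1)
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(snk$adjusted_p, tt$p.value, tolerance = 1e-9)
  })
})

test_that("SNK makes no claims on identical group means", {
  d <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  snk <- snk_posthoc(d, y, g)
  expect_true(all(snk$adjusted_p > 0.9))
  expect_true(all(snk$adjusted_p <= 1))
  expect_error(snk_posthoc(d[d$g == "a", ], y, g), "2 groups")
})

test_that("SNK familywise error under the complete null stays at nominal", {
  withr::with_seed(63, {
    rej <- replicate(600, {
      d <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
      any(snk_posthoc(d, y, g)$adjusted_p < 0.05)
    })
    expect_no_hit_rate_above(mean(rej), 0.05, 600)
  })
})

test_that("SNK adjusted p never falls below Tukey's for middle pairs", {
  withr::with_seed(44, {
    d <- data.frame(y = rnorm(40, rep(c(0, 0.5, 1, 3), each = 10)),
                    g = rep(c("a", "b", "c", "d"), each = 10))
    snk <- snk_posthoc(d, y, g)
    tuk <- snk_posthoc(d, y, g, method = "Tukey")
    m <- merge(snk, tuk, by = "comparison")
    expect_true(all(m$adjusted_p.x <= m$adjusted_p.y + 1e-12))
  })
})

test_that("Spearman rho equals rank-Pearson and handles the worked example", {
  r <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_equal(r$method, "exact permutation")

  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$rho, -1)

  withr::with_seed(2, {
    for (i in 1:15) {
      n <- sample(6:30, 1)
      x <- sample(1:8, n, TRUE)  # ties on both sides
      y <- x + sample(1:8, n, TRUE)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      expect_equal(spearman_cor(x, y)$rho,
                   stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    }
  })
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "zero variance")
  expect_error(spearman_cor(1:2, 2:1), "3 complete pairs")
})

test_that("Spearman p-values track the reference implementation", {
  withr::with_seed(19, {
    # large-n t-approximation branch
    x <- rnorm(40); y <- x + rnorm(40, 0, 2)
    ours <- spearman_cor(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)

    # exact branch against full enumeration by cor.test (no ties, n <= 9)
    x8 <- sample(100, 8); y8 <- sample(100, 8)
    ours8 <- spearman_cor(x8, y8)
    ref8 <- stats::cor.test(x8, y8, method = "spearman", exact = TRUE)
    expect_equal(ours8$p_value, ref8$p.value, tolerance = 1e-9)
  })
})

test_that("cohort tests choose Welch, chi-square or Fisher appropriately", {
  withr::with_seed(10, {
    meta <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:64),
      group = rep(c("control", "case"), c(27, 37)),
      age = c(rnorm(27, 30, 5), rnorm(37, 32, 5)),
      hormonal = c(rep(1, 22), rep(0, 5), rep(1, 16), rep(0, 21)),
      nrs_pain = sample(0:10, 64, TRUE)
    )
    res <- cohort_table_tests(meta)
    expect_setequal(res$feature, c("age", "hormonal", "nrs_pain"))
    expect_equal(res$test[res$feature == "age"], "Welch t")
    expect_equal(res$test[res$feature == "hormonal"], "chi-square")
    # [[22,16],[5,21]] reconstruction: prints as 0.002 to one significant figure
    p <- res$p_value[res$feature == "hormonal"]
    expect_gte(p, 0.0015)
    expect_lt(p, 0.0025)
  })
})

test_that("sparse qualitative features fall back to the exact hypergeometric test", {
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    group = rep(c("case", "control"), each = 10),
    feat = c(rep(1, 1), rep(0, 9), rep(1, 8), rep(0, 2))
  )
  res <- cohort_table_tests(meta)
  expect_equal(res$test, "Fisher exact")
  # two-tailed hypergeometric sum for table [[1,9],[8,2]]
  m <- 9; n <- 11; k <- 10
  probs <- stats::dhyper(0:9, m, n, k)
  p_exact <- sum(probs[probs <= stats::dhyper(1, m, n, k) * (1 + 1e-7)])
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)

  # missing values excluded and counted
  meta$feat[1:3] <- NA
  expect_equal(cohort_table_tests(meta)$n_missing, 3)
  expect_error(cohort_table_tests(meta[meta$group == "case", ]), "two groups")
})

test_that("Kruskal-Wallis gate and Dunn comparisons behave across designs", {
  withr::with_seed(30, {
    # far-shifted group: gate opens, its comparisons are the significant ones
    d <- data.frame(y = c(rnorm(12), rnorm(12), rnorm(12, 8)),
                    g = rep(c("a", "b", "c"), each = 12))
    kd <- kruskal_dunn(d, y, g)
    expect_lt(kd$kw$p_value, 0.05)
    ph <- kd$posthoc
    expect_true(all(ph$adjusted_p[grepl("c", ph$comparison)] < 0.05))
    expect_gt(ph$adjusted_p[ph$comparison == "a - b"], 0.05)

    # null data: gate usually closed
    d0 <- data.frame(y = rnorm(36), g = rep(c("a", "b", "c"), each = 12))
    kd0 <- kruskal_dunn(d0, y, g)
    if (kd0$kw$p_value >= 0.05) expect_null(kd0$posthoc)

    # two groups: KW chi-square equals the tie-corrected rank-sum test
    d2 <- data.frame(y = c(rnorm(10), rnorm(10, 1)),
                     g = rep(c("a", "b"), each = 10))
    kw <- kruskal_dunn(d2, y, g)$kw
    wt <- stats::wilcox.test(y ~ g, data = d2, exact = FALSE, correct = FALSE)
    expect_equal(kw$p_value, wt$p.value, tolerance = 1e-9)

    d$g[d$g == "b"] <- "a"
    expect_no_error(kruskal_dunn(d, y, g))
    expect_error(kruskal_dunn(data.frame(y = 1, g = factor("a", c("a", "b"))),
                              y, g), "empty group")
  })
})

test_that("Monte-Carlo Dunnett matches the reference multivariate-t answer", {
  skip_if_not_installed("multcomp")
  withr::with_seed(50, {
    d <- data.frame(
      y = rnorm(40, rep(c(0, 0.8, 0.2, 0), each = 10)),
      g = factor(rep(c("scrambled", "a1", "a2", "a3"), each = 10),
                 levels = c("scrambled", "a1", "a2", "a3"))
    )
    ours <- dunnett_posthoc(d, y, g, control = "scrambled", B = 2e5, seed = 1)
    fit <- stats::aov(y ~ g, data = d)
    ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    ref_p <- as.numeric(ref$test$pvalues)
    ord <- match(paste(levels(d$g)[-1], "- scrambled"), ours$comparison)
    expect_equal(ours$adjusted_p[ord], ref_p, tolerance = 0.01)
  })
})

test_that("Dunnett adjusted p is monotone in |t| and needs a control arm", {
  withr::with_seed(52, {
    d <- data.frame(y = rnorm(40, rep(c(0, 0.3, 1, 2), each = 10)),
                    g = rep(c("scrambled", "a1", "a2", "a3"), each = 10))
    res <- dunnett_posthoc(d, y, g, control = "scrambled", B = 5e4, seed = 2)
    ord <- order(abs(res$statistic))
    expect_false(is.unsorted(rev(res$adjusted_p[ord])))
    expect_true(all(res$adjusted_p >= 0 & res$adjusted_p <= 1))
  })
  expect_error(dunnett_posthoc(data.frame(y = 1:4, g = c("a", "a", "b", "b")),
                               y, g, control = "zz"), "not present")
})

test_that("transfection analysis recovers a planted knockdown at high estradiol", {
  planted <- data.frame(arm = "mimic_both", dose = 1e-6, effect = 0.6)
  hits <- 0; reductions <- numeric(0)
  for (i in 1:12) {
    tf <- simulate_transfection(n_patients = 10, arm_effects = planted,
                                seed = 900 + i)
    res <- transfection_analysis(tf, B = 2e4, seed = i)
    pd <- res$per_dose
    high <- pd[pd$dose == 1e-6, ]
    dn <- high$dunnett[[1]]
    if (!is.null(dn)) {
      sig <- dn$comparison[dn$adjusted_p < 0.05]
      if (identical(sig, "mimic_both - scrambled")) hits <- hits + 1
      reductions <- c(reductions,
                      1 - 2^dn$estimate[dn$comparison == "mimic_both - scrambled"])
    }
  }
  expect_gte(hits, 7)  # majority of replicates flag only the planted arm
  expect_equal(mean(reductions), 0.4, tolerance = 0.12)
})

test_that("transfection null keeps per-dose ANOVAs at or below nominal", {
  ps <- unlist(lapply(1:60, function(i) {
    tf <- simulate_transfection(n_patients = 10,
                                arm_effects = c(scrambled = 1, mimic_let7b = 1,
                                                mimic_miR92a = 1, mimic_both = 1),
                                seed = 4000 + i)
    transfection_analysis(tf, B = 1000, seed = i)$per_dose$p_value
  }))
  expect_no_hit_rate_above(mean(ps < 0.05), 0.05, length(ps))
})

test_that("transfection analysis validates its design", {
  tf <- simulate_transfection(n_patients = 2, seed = 1)
  broken <- tf[!(tf$arm == "scrambled" & tf$patient_id == "p01" &
                   tf$cell_type == "epithelial" & tf$dose == 0), ]
  expect_error(transfection_analysis(broken), "missing scrambled arm")
  expect_error(transfection_analysis(tf[, -2]), "missing")

  # single-patient design still fits (patient term dropped)
  tf1 <- simulate_transfection(n_patients = 1, seed = 2)
  expect_no_error(transfection_analysis(tf1, B = 500, seed = 3))
})

test_that("two-arm Dunnett agrees with the two-sample t-test", {
  withr::with_seed(71, {
    d <- data.frame(y = c(rnorm(12), rnorm(12, 0.9)),
                    g = rep(c("scrambled", "mimic"), each = 12))
    res <- dunnett_posthoc(d, y, g, control = "scrambled", B = 2e5, seed = 5)
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(res$adjusted_p, tt$p.value, tolerance = 0.01)
  })
})
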
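#' Two-way factorial ANOVA (disease x cycle phase)
#'
#' Tests both main effects and their interaction, e.g. disease group and
#' menstrual-cycle phase on a plasma delta-Ct response. Balanced complete
#' designs use the classical sum-of-squares decomposition; unbalanced designs
#' use Type II sums of squares, the conventional default when no effect
#' hierarchy is pre-specified.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names (strings or bare names) of
#'   the numeric response and the two factors.
#' @return A tibble with one row per term (`factor_a`, `factor_b`,
#'   `factor_a:factor_b`, `Residuals`): `term`, `sumsq`, `df`, `statistic`,
#'   `p_value`. Attribute `ss_type` records the decomposition used and
#'   `response` the analyzed column.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  rv <- rlang::as_name(rlang::ensym(response))
  fa <- rlang::as_name(rlang::ensym(factor_a))
  fb <- rlang::as_name(rlang::ensym(factor_b))
  d <- data.frame(
    y = data[[rv]],
    A = factor(data[[fa]]),
    B = factor(data[[fb]])
  )
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$A)) < 2 || nlevels(droplevels(d$B)) < 2) {
    abort("both factors need at least 2 observed levels")
  }
  d$A <- droplevels(d$A)
  d$B <- droplevels(d$B)
  cells <- table(d$A, d$B)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(paste0(
      "empty design cell: ", fa, " = ", rownames(cells)[idx[1]],
      ", ", fb, " = ", colnames(cells)[idx[2]]
    ))
  }
  fit <- lm(y ~ A * B, data = d)
  balanced <- length(unique(as.vector(cells))) == 1L
  if (balanced) {
    tab <- anova(fit)
    ss_type <- "I (classical, balanced)"
  } else {
    tab <- car::Anova(fit, type = 2)
    ss_type <- "II"
  }
  out <- tibble::tibble(
    term = rownames(tab),
    sumsq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
  out$term <- sub("^A:B$", paste0(fa, ":", fb), out$term)
  out$term <- sub("^A$", fa, out$term)
  out$term <- sub("^B$", fb, out$term)
  structure(out, ss_type = ss_type, response = rv)
}

#' Student-Newman-Keuls post-hoc comparisons
#'
#' Stepwise multiple comparisons on ordered group means using the
#' studentized-range distribution: a pair of means is declared different only
#' if every stretch of ordered means containing the pair has a significant
#' range test at its own stretch size. The reported adjusted p for a pair is
#' the maximum studentized-range p over all containing stretches, which makes
#' the stepwise accept/reject logic readable off a single column. With two
#' groups the procedure reduces to the pooled-variance two-sample t-test.
#' Tukey HSD (every pair tested at the full family size) is available as a
#' more conservative cross-check.
#'
#' @param data A data frame.
#' @param response,group Column names (strings or bare names).
#' @param method `"SNK"` (default) or `"Tukey"`.
#' @return A tibble, one row per pair: `comparison`, `estimate` (difference
#'   of means in response units), `statistic` (studentized range q),
#'   `adjusted_p`, `method`.
#' @export
snk_posthoc <- function(data, response, group, method = c("SNK", "Tukey")) {
  method <- match.arg(method)
  rv <- rlang::as_name(rlang::ensym(response))
  gv <- rlang::as_name(rlang::ensym(group))
  d <- data.frame(y = data[[rv]], g = factor(data[[gv]]))
  d <- d[complete.cases(d), ]
  d$g <- droplevels(d$g)
  k <- nlevels(d$g)
  if (k < 2) abort("need at least 2 groups")
  fit <- aov(y ~ g, data = d)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  means <- tapply(d$y, d$g, mean)
  ns <- tapply(d$y, d$g, length)
  ord <- order(means)
  m <- means[ord]
  n <- ns[ord]
  labs <- names(m)

  q_of <- function(i, j) {
    # Tukey-Kramer standard error for possibly unequal n
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) Inf else abs(m[j] - m[i]) / se
  }
  rows <- list()
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      if (method == "SNK") {
        # max p over all containing stretches [s, t]
        p <- 0
        for (s in seq_len(a)) {
          for (t in seq(b, k)) {
            r <- t - s + 1
            p <- max(p, ptukey(q_of(s, t), r, df, lower.tail = FALSE))
          }
        }
      } else {
        p <- ptukey(q_of(a, b), k, df, lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = paste(labs[b], "-", labs[a]),
        estimate = unname(m[b] - m[a]),
        statistic = q_of(a, b),
        adjusted_p = min(1, p),
        method = method
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Spearman rank correlation
#'
#' The correlation of midranks: identical to the Pearson correlation computed
#' on the rank vectors, which handles ties and binary codings (e.g. an
#' infertility indicator against a plasma level). The p-value uses the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`; for n <= 9 complete
#' pairs an exact permutation p over all n! orderings is computed instead.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in x or y")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- permutations_of(n)
    # cor is a monotone transform of sum(rx_perm * ry) at fixed margins
    sums <- perms_apply_sum(perms, rx, ry)
    obs <- sum(rx * ry)
    mu <- mean(sums)
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  p <- nrow(sub)
  out <- matrix(NA_integer_, n * p, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[((i - 1) * p + 1):(i * p), ] <- cbind(i, matrix(rest[sub], p, n - 1))
  }
  out
}

perms_apply_sum <- function(perms, rx, ry) {
  # sum over positions of rx[perm] * ry, vectorized over permutations
  as.vector(matrix(rx[perms], nrow(perms), ncol(perms)) %*% ry)
}

#' Cohort-table descriptive tests
#'
#' Per-feature two-group tests in the style of a clinical Table 1:
#' quantitative features are compared with Welch's t-test; qualitative
#' features with the Pearson chi-square test of contingency (no continuity
#' correction), switching to Fisher's exact test when any expected count
#' falls below 5. Missing values are excluded per feature and their count
#' reported. Numeric columns with at most two distinct values (0/1 codings)
#' are treated as qualitative.
#'
#' @param meta Sample metadata tibble with a group column.
#' @param group_col Name of the two-level grouping column.
#' @param features Character vector of feature columns; default all columns
#'   except `sample_id` and the group column.
#' @param categorical Extra columns to force into the qualitative branch.
#' @return A tibble per tested feature: `feature`, `type`, `test`,
#'   `statistic` (NA for Fisher), `p_value`, `n_used`, `n_missing`.
#' @export
cohort_table_tests <- function(meta, group_col = "group", features = NULL,
                               categorical = NULL) {
  g <- factor(meta[[group_col]])
  if (nlevels(droplevels(g)) != 2) abort("exactly two groups are required")
  if (is.null(features)) {
    features <- setdiff(names(meta), c("sample_id", group_col))
  }
  purrr::map_dfr(features, function(f) {
    v <- meta[[f]]
    keep <- !is.na(v) & !is.na(g)
    n_missing <- sum(!keep)
    vv <- v[keep]
    gg <- droplevels(g[keep])
    if (min(table(gg)) < 2) {
      mb_log("cohort_table_tests: skipped '", f, "' (<2 observations per group)")
      return(NULL)
    }
    is_quant <- is.numeric(vv) && length(unique(vv)) > 2 && !(f %in% categorical)
    if (is_quant) {
      ht <- t.test(vv ~ gg)
      tibble::tibble(feature = f, type = "quantitative", test = "Welch t",
                     statistic = unname(ht$statistic), p_value = ht$p.value,
                     n_used = length(vv), n_missing = n_missing)
    } else {
      tab <- table(gg, factor(vv))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2) {
        mb_log("cohort_table_tests: skipped '", f, "' (single observed level)")
        return(NULL)
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ht <- fisher.test(tab)
        tibble::tibble(feature = f, type = "qualitative", test = "Fisher exact",
                       statistic = NA_real_, p_value = ht$p.value,
                       n_used = length(vv), n_missing = n_missing)
      } else {
        res <- chi2_contingency(unclass(tab))
        tibble::tibble(feature = f, type = "qualitative", test = "chi-square",
                       statistic = res$statistic, p_value = res$p_value,
                       n_used = length(vv), n_missing = n_missing)
      }
    }
  })
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis across k groups; when the multigroup test is
#' significant at `alpha` (the gate for pairwise testing) and k >= 3, Dunn's
#' z-tests on mean pooled ranks are run for every pair with Bonferroni
#' adjustment.
#'
#' @param data A data frame.
#' @param response,group Column names (strings or bare names).
#' @param alpha Gate level for running the post-hoc stage.
#' @return A list with `kw` (one-row tibble `statistic`, `df`, `p_value`) and
#'   `posthoc` (tibble `comparison`, `estimate` = mean-rank difference,
#'   `statistic` = z, `adjusted_p`, `method`; `NULL` when the gate is not
#'   passed or k < 3).
#' @export
kruskal_dunn <- function(data, response, group, alpha = 0.05) {
  rv <- rlang::as_name(rlang::ensym(response))
  gv <- rlang::as_name(rlang::ensym(group))
  g_raw <- data[[gv]]
  d <- data.frame(y = data[[rv]],
                  g = if (is.factor(g_raw)) g_raw else factor(g_raw))
  d <- d[complete.cases(d), ]
  if (any(table(d$g) == 0)) {
    abort(paste0("empty group: ",
                 paste(levels(d$g)[table(d$g) == 0], collapse = ", ")))
  }
  d$g <- droplevels(d$g)
  kw <- kruskal.test(y ~ g, data = d)
  out <- list(
    kw = tibble::tibble(statistic = unname(kw$statistic),
                        df = unname(kw$parameter), p_value = kw$p.value),
    posthoc = NULL
  )
  k <- nlevels(d$g)
  if (kw$p.value < alpha && k >= 3) {
    N <- nrow(d)
    r <- rank(d$y)
    rbar <- tapply(r, d$g, mean)
    ns <- tapply(r, d$g, length)
    ties <- table(d$y)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    sig2 <- N * (N + 1) / 12 - tie_corr
    pairs <- utils::combn(levels(d$g), 2)
    ncomp <- ncol(pairs)
    out$posthoc <- purrr::map_dfr(seq_len(ncomp), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      z <- (rbar[[a]] - rbar[[b]]) /
        sqrt(sig2 * (1 / ns[[a]] + 1 / ns[[b]]))
      tibble::tibble(
        comparison = paste(a, "-", b),
        estimate = rbar[[a]] - rbar[[b]],
        statistic = z,
        adjusted_p = min(1, 2 * stats::pnorm(-abs(z)) * ncomp),
        method = "Dunn (Bonferroni)"
      )
    })
  }
  out
}

#' Dunnett many-to-one comparisons by seeded Monte Carlo
#'
#' Compares every treatment arm against a shared control with familywise
#' adjustment. The adjusted p-value of arm i is `P(max_j |T_j| >= |t_i|)`
#' under the joint null, estimated from `B` Monte-Carlo draws of the
#' correlated t-statistics (shared control mean and shared variance
#' estimate), which converges to the multivariate-t Dunnett probability.
#' With a single treatment arm the procedure reduces to the pooled two-sample
#' t-test up to Monte-Carlo error.
#'
#' @param data A data frame.
#' @param response,group Column names (strings or bare names).
#' @param control Label of the control arm.
#' @param B Number of Monte-Carlo draws.
#' @param seed Optional seed for the draw.
#' @return A tibble per treatment arm: `comparison`, `estimate` (mean
#'   difference vs control), `statistic` (t), `df`, `adjusted_p`, `method`.
#' @export
dunnett_posthoc <- function(data, response, group, control = "scrambled",
                            B = 1e5, seed = NULL) {
  rv <- rlang::as_name(rlang::ensym(response))
  gv <- rlang::as_name(rlang::ensym(group))
  d <- data.frame(y = data[[rv]], g = factor(data[[gv]]))
  d <- d[complete.cases(d), ]
  d$g <- droplevels(d$g)
  if (!control %in% levels(d$g)) {
    abort(paste0("control arm '", control, "' not present"))
  }
  arms <- setdiff(levels(d$g), control)
  if (length(arms) == 0) abort("no treatment arm to compare")
  ns <- tapply(d$y, d$g, length)
  means <- tapply(d$y, d$g, mean)
  N <- nrow(d)
  k <- nlevels(d$g)
  df <- N - k
  if (df < 1) abort("no residual degrees of freedom")
  mse <- sum((d$y - means[d$g])^2) / df
  if (mse == 0) abort("zero residual variance: comparisons are degenerate")
  tstat <- unname((means[arms] - means[[control]]) /
    sqrt(mse * (1 / ns[arms] + 1 / ns[[control]])))

  maxT <- with_seed_maybe(seed, {
    z0 <- rnorm(B, 0, sqrt(1 / ns[[control]]))
    s <- sqrt(rchisq(B, df) / df)
    m <- matrix(0, B, length(arms))
    for (j in seq_along(arms)) {
      zj <- rnorm(B, 0, sqrt(1 / ns[[arms[j]]]))
      m[, j] <- abs(zj - z0) / (s * sqrt(1 / ns[[arms[j]]] + 1 / ns[[control]]))
    }
    do.call(pmax, as.data.frame(m))
  })
  tibble::tibble(
    comparison = paste(arms, "-", control),
    estimate = unname(means[arms] - means[[control]]),
    statistic = unname(tstat),
    df = df,
    adjusted_p = vapply(abs(tstat), function(t) mean(maxT >= t), numeric(1)),
    method = "Dunnett (Monte Carlo)"
  )
}

#' Factorial analysis of a mimic-transfection experiment
#'
#' Stage 1 fits the additive factorial model
#' `log2(rel_expr) ~ patient + cell_type + dose + arm` on expression values
#' normalized to the scrambled-control arm within each
#' patient x cell-type x dose block, and reports each term plus the overall
#' model F. Stage 2 runs, per estradiol dose, a one-way ANOVA across
#' transfection arms, followed — only when that ANOVA is significant at
#' `alpha` — by Monte-Carlo Dunnett comparisons of each mimic arm against
#' the scrambled control.
#'
#' @param expr Transfection tibble with columns `patient_id`, `cell_type`,
#'   `arm`, `dose` and the response (see [simulate_transfection()]).
#' @param response Name of the response column (default `rel_expr`).
#' @param log2_scale Analyze on log2 scale (default; multiplicative effects
#'   become additive and the scrambled arm sits at 0).
#' @param alpha Gate level for the per-dose Dunnett stage.
#' @param B,seed Monte-Carlo settings for [dunnett_posthoc()].
#' @return A list with `three_factor` (tibble of terms incl. `model` row and
#'   `Residuals`) and `per_dose` (tibble `dose`, `statistic`, `df1`, `df2`,
#'   `p_value`, list-column `dunnett`, `NULL` where gated off). Attribute
#'   `scale` records the analyzed scale.
#' @export
transfection_analysis <- function(expr, response = "rel_expr",
                                  log2_scale = TRUE, alpha = 0.05,
                                  B = 1e5, seed = NULL) {
  need <- c("patient_id", "cell_type", "arm", "dose", response)
  miss <- setdiff(need, names(expr))
  if (length(miss) > 0) abort(paste0("expr is missing: ", paste(miss, collapse = ", ")))
  blocks <- dplyr::summarise(
    dplyr::group_by(expr, .data$patient_id, .data$cell_type, .data$dose),
    has_scr = any(.data$arm == "scrambled"), .groups = "drop"
  )
  if (any(!blocks$has_scr)) {
    b <- blocks[!blocks$has_scr, ][1, ]
    abort(paste0("missing scrambled arm in block: patient ", b$patient_id,
                 ", ", b$cell_type, ", dose ", b$dose))
  }
  d <- data.frame(
    y = if (log2_scale) log2(expr[[response]]) else expr[[response]],
    patient = factor(expr$patient_id),
    cell_type = factor(expr$cell_type),
    dose = factor(expr$dose),
    arm = factor(expr$arm)
  )
  terms_keep <- c("patient", "cell_type", "dose", "arm")[
    vapply(d[c("patient", "cell_type", "dose", "arm")],
           function(v) nlevels(droplevels(v)) > 1, logical(1))
  ]
  fit <- lm(stats::reformulate(terms_keep, "y"), data = d)
  tab <- anova(fit)
  fstat <- summary(fit)$fstatistic
  three_factor <- dplyr::bind_rows(
    tibble::tibble(
      term = "model",
      sumsq = sum(tab[rownames(tab) != "Residuals", "Sum Sq"]),
      df = sum(tab[rownames(tab) != "Residuals", "Df"]),
      statistic = unname(fstat[1]),
      p_value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    ),
    tibble::tibble(
      term = rownames(tab), sumsq = tab[["Sum Sq"]], df = tab[["Df"]],
      statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]]
    )
  )

  doses <- sort(unique(expr$dose))
  per_dose <- purrr::map_dfr(seq_along(doses), function(i) {
    dd <- d[d$dose == as.character(doses[i]), ]
    dd$arm <- droplevels(dd$arm)
    one <- anova(lm(y ~ arm, data = dd))
    p <- one[["Pr(>F)"]][1]
    dn <- NULL
    if (is.finite(p) && p < alpha) {
      dn <- dunnett_posthoc(dd, y, arm, control = "scrambled", B = B,
                            seed = if (is.null(seed)) NULL else seed + i)
    }
    tibble::tibble(
      dose = doses[i], statistic = one[["F value"]][1],
      df1 = one[["Df"]][1], df2 = one[["Df"]][2], p_value = p,
      dunnett = list(dn)
    )
  })
  structure(list(three_factor = three_factor, per_dose = per_dose),
            scale = if (log2_scale) "log2" else "linear")
}
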
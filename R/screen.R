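#' Categorize induction ratios
#'
#' A gene is *downregulated* when its lesion/eutopic induction ratio is below
#' 0.5, *upregulated* above 2.0, and *unchanged* otherwise. The boundaries
#' 0.5 and 2.0 belong to the unchanged category: the outer categories are
#' defined by strict inequalities.
#'
#' @param ratio Numeric vector of induction ratios (> 0, finite).
#' @param down,up Category thresholds, `0 < down < up`.
#' @return `classify_ratio()`: a factor with levels `down`, `unchanged`, `up`.
#' @examples
#' classify_ratio(c(0.0084, 0.5, 1, 2, 3))
#' @export
classify_ratio <- function(ratio, down = 0.5, up = 2.0) {
  stopifnot(down > 0, down < up)
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort("induction ratios must be finite and > 0")
  }
  factor(
    dplyr::case_when(ratio < down ~ "down", ratio > up ~ "up",
                     TRUE ~ "unchanged"),
    levels = c("down", "unchanged", "up")
  )
}

#' @rdname classify_ratio
#' @param expression Expression tibble (`gene_id`, `induction_ratio`).
#' @return `classify_genes()`: the expression tibble with a `category` column.
#' @export
classify_genes <- function(expression, down = 0.5, up = 2.0) {
  dplyr::mutate(
    tibble::as_tibble(expression),
    category = classify_ratio(.data$induction_ratio, down = down, up = up)
  )
}

#' Build a miRNA's 2x3 enrichment contingency table
#'
#' Counts the miRNA's targets and the genome background over the three
#' expression categories. The background is the deterministic whole-genome
#' complement (every categorized gene not in the target set) unless a random
#' background was materialized upstream. Targets absent from the expression
#' table are excluded (their count is logged): an interaction atlas is wider
#' than any one transcriptome.
#'
#' @param atlas Atlas tibble (`mirna_id`, `gene_id`).
#' @param expression Expression tibble, or the output of [classify_genes()].
#' @param mirna_id The miRNA to tabulate.
#' @inheritParams classify_ratio
#' @return A 2x3 integer matrix with rows `in_set`, `background` and columns
#'   `down`, `unchanged`, `up`; attribute `n_missing` counts targets not in
#'   the expression table.
#' @export
build_contingency <- function(atlas, expression, mirna_id,
                              down = 0.5, up = 2.0) {
  if (!mirna_id %in% atlas$mirna_id) {
    abort(paste0("miRNA '", mirna_id, "' is not in the atlas"))
  }
  if (nrow(expression) == 0) abort("expression table is empty")
  if (!"category" %in% names(expression)) {
    expression <- classify_genes(expression, down = down, up = up)
  }
  targets <- atlas_targets(atlas, mirna_id)
  in_expr <- targets[targets %in% expression$gene_id]
  n_missing <- length(targets) - length(in_expr)
  if (n_missing > 0) {
    mb_log("build_contingency(", mirna_id, "): ", n_missing,
           " target(s) absent from the expression table")
  }
  if (length(in_expr) == 0) {
    abort(paste0("miRNA '", mirna_id,
                 "' is untestable: no target overlaps the expression table"))
  }
  lv <- c("down", "unchanged", "up")
  in_row <- table(factor(
    expression$category[expression$gene_id %in% in_expr], levels = lv))
  all_row <- table(factor(expression$category, levels = lv))
  tab <- rbind(in_set = as.integer(in_row),
               background = as.integer(all_row) - as.integer(in_row))
  colnames(tab) <- lv
  attr(tab, "n_missing") <- n_missing
  tab
}

#' Pearson chi-square test of contingency
#'
#' The screen's test statistic: `sum((O - E)^2 / E)` with expected counts from
#' the independence model `E = rowsum * colsum / n`, `df = (r-1)(c-1)`, and
#' the p-value from the upper tail of the chi-square distribution. No
#' continuity correction is applied. When any expected count is below 5 the
#' result is flagged (`low_expected`), and a seeded Monte-Carlo p-value
#' conditional on the table margins can be requested instead of the
#' asymptotic one. For two-row tables an `"exact"` conditional p is also
#' available: it enumerates every table with the observed margins, weights
#' each by its multivariate-hypergeometric probability and sums over tables
#' whose statistic reaches the observed one — the deterministic limit of the
#' label-shuffling permutation test.
#'
#' @param tab An r x c matrix of non-negative counts with positive row and
#'   column totals.
#' @param p_method `"asymptotic"` (default), `"monte_carlo"`, or `"exact"`
#'   (two-row tables only).
#' @param B Number of Monte-Carlo tables when `p_method = "monte_carlo"`.
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `min_expected`,
#'   `low_expected`, `p_method`.
#' @export
chi2_contingency <- function(tab, p_method = c("asymptotic", "monte_carlo",
                                               "exact"),
                             B = 20000, seed = NULL) {
  p_method <- match.arg(p_method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    abort("contingency table must contain finite non-negative counts")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) {
    abort(paste0("degenerate margin: row ",
                 paste(which(rs == 0), collapse = ", "), " has zero total"))
  }
  if (any(cs == 0)) {
    abort(paste0("degenerate margin: column ",
                 paste(which(cs == 0), collapse = ", "), " has zero total"))
  }
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p_asym <- pchisq(stat, df, lower.tail = FALSE)
  p <- p_asym
  if (p_method == "monte_carlo") {
    p <- with_seed_maybe(seed, {
      sims <- stats::r2dtable(B, rs, cs)
      stats_b <- vapply(sims, function(o) sum((o - expected)^2 / expected),
                        numeric(1))
      (1 + sum(stats_b >= stat - 1e-12)) / (B + 1)
    })
  } else if (p_method == "exact") {
    if (nrow(tab) != 2) abort("exact p is implemented for two-row tables only")
    p <- chi2_exact_2xc(rs, cs, expected, stat)
  }
  tibble::tibble(
    statistic = stat, df = df, p_value = p,
    min_expected = min(expected), low_expected = min(expected) < 5,
    p_method = p_method
  )
}

# Exact conditional p for a 2 x c table: enumerate every first row compatible
# with the margins; P(row1) is multivariate hypergeometric. The first c-1
# cells are expanded on a grid and the last cell is implied, so the whole
# enumeration is vectorized; feasible for c <= 4 at n in the hundreds.
chi2_exact_2xc <- function(rs, cs, expected, stat_obs) {
  cc <- length(cs)
  n <- sum(rs)
  free <- lapply(cs[-cc], function(cj) 0:min(cj, rs[1]))
  if (prod(lengths(free)) > 5e6) abort("table too large for exact enumeration")
  grid <- as.matrix(expand.grid(free))
  last <- rs[1] - rowSums(grid)
  ok <- last >= 0 & last <= cs[cc]
  grid <- grid[ok, , drop = FALSE]
  row1 <- cbind(grid, last[ok])
  logw <- -lchoose(n, rs[1])
  stat <- numeric(nrow(row1))
  for (j in seq_len(cc)) {
    logw <- logw + lchoose(cs[j], row1[, j])
    stat <- stat + (row1[, j] - expected[1, j])^2 / expected[1, j] +
      (cs[j] - row1[, j] - expected[2, j])^2 / expected[2, j]
  }
  min(1, sum(exp(logw[stat >= stat_obs - 1e-7])))
}

#' Bonferroni adjustment
#'
#' Familywise correction `min(1, m * p)` for `m` tests.
#'
#' @param p_raw Raw p-values in \[0, 1\].
#' @param m Number of tests in the family (>= 1).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  pmin(1, m * p_raw)
}

#' Run the miRNA expression-bias enrichment screen
#'
#' For every miRNA in the atlas whose target set overlaps the expression
#' table, tests whether its targets are biased across the
#' down / unchanged / up categories relative to the genome background
#' (Pearson chi-square, no continuity correction), applies a Bonferroni
#' correction with `m` equal to the number of testable miRNAs, and ranks by
#' raw p-value (ties broken by larger tested-target count, then id).
#' Expression categories with zero genes overall are dropped from every
#' table before testing (the degrees of freedom shrink accordingly).
#'
#' @param atlas Atlas tibble (`mirna_id`, `gene_id`).
#' @param expression Expression tibble (`gene_id`, `induction_ratio`).
#' @param alpha Familywise significance level for the `significant` flag.
#' @param top_n Number of rows the report/print shows (the full ranked table
#'   is always returned).
#' @inheritParams classify_ratio
#' @param background `"whole"` uses the deterministic whole-genome
#'   complement; `"random"` draws `background_n` non-target genes per miRNA.
#' @param background_n Size of the random background (required when
#'   `background = "random"`).
#' @param annotations Optional tibble (`mirna_id`, `annotation`) of literature
#'   flags joined onto the result; never computed.
#' @param seed Seed for the random background draw.
#' @return A tibble of class `mirna_screen`, ranked, with columns `rank`,
#'   `mirna_id`, `n_down`, `n_unchanged`, `n_up`, `statistic`, `df`,
#'   `p_value`, `p_bonf`, `significant`, `low_expected`, `annotation`.
#'   Attributes: `m_tested`, `n_untestable`, `alpha`, `top_n`, `thresholds`,
#'   `background`.
#' @export
run_screen <- function(atlas, expression, alpha = 0.05, top_n = 24,
                       down = 0.5, up = 2.0,
                       background = c("whole", "random"), background_n = NULL,
                       annotations = NULL, seed = NULL) {
  background <- match.arg(background)
  stopifnot(alpha > 0, alpha < 1, top_n >= 1)
  if (background == "random" && is.null(background_n)) {
    abort("background = 'random' requires background_n")
  }
  classified <- classify_genes(expression, down = down, up = up)
  mirnas <- atlas_mirnas(atlas)

  with_seed_maybe(seed, {
    rows <- purrr::map(mirnas, function(m) {
      tab <- tryCatch(
        build_contingency(atlas, classified, m, down = down, up = up),
        error = function(e) NULL
      )
      if (is.null(tab)) return(NULL)
      if (background == "random") {
        non_targets <- setdiff(classified$gene_id, atlas_targets(atlas, m))
        bg <- classified[classified$gene_id %in%
                           sample(non_targets, min(background_n,
                                                   length(non_targets))), ]
        bg_row <- table(factor(bg$category, levels = colnames(tab)))
        tab["background", ] <- as.integer(bg_row)
      }
      keep <- colSums(tab) > 0
      if (sum(keep) < 2) return(NULL)  # no contrast left to test
      res <- chi2_contingency(tab[, keep, drop = FALSE])
      tibble::tibble(
        mirna_id = m,
        n_down = tab["in_set", "down"],
        n_unchanged = tab["in_set", "unchanged"],
        n_up = tab["in_set", "up"],
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        low_expected = res$low_expected
      )
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) abort("no testable miRNA in the atlas/expression cross")
    n_untestable <- length(mirnas) - nrow(out)
    if (n_untestable > 0) {
      mb_log("run_screen: ", n_untestable, " untestable miRNA(s) skipped")
    }
    m_tested <- nrow(out)
    out$p_bonf <- bonferroni(out$p_value, m_tested)
    out$significant <- out$p_bonf <= alpha
    out$n_targets <- out$n_down + out$n_unchanged + out$n_up
    out <- dplyr::arrange(out, .data$p_value, dplyr::desc(.data$n_targets),
                          .data$mirna_id)
    out$rank <- seq_len(nrow(out))
    if (!is.null(annotations)) {
      out <- dplyr::left_join(out, annotations[c("mirna_id", "annotation")],
                              by = "mirna_id")
    } else {
      out$annotation <- NA_character_
    }
    out <- out[c("rank", "mirna_id", "n_down", "n_unchanged", "n_up",
                 "n_targets", "statistic", "df", "p_value", "p_bonf",
                 "significant", "low_expected", "annotation")]
    structure(out,
      class = c("mirna_screen", class(out)),
      m_tested = m_tested, n_untestable = n_untestable,
      alpha = alpha, top_n = top_n,
      thresholds = c(down = down, up = up), background = background
    )
  })
}

#' @export
print.mirna_screen <- function(x, ...) {
  top_n <- attr(x, "top_n") %||% 24L
  cat("miRNA expression-bias screen: ", attr(x, "m_tested"),
      " miRNAs tested, ", sum(x$significant),
      " significant at Bonferroni alpha = ", attr(x, "alpha"), "\n", sep = "")
  print(tibble::as_tibble(head(x, top_n)), ...)
  if (nrow(x) > top_n) cat("... and", nrow(x) - top_n, "more rows\n")
  invisible(x)
}

#' Significant rows of a screen
#'
#' @param screen A `mirna_screen` result.
#' @param alpha Familywise level; defaults to the level the screen was run at.
#' @return The subset of rows with `p_bonf <= alpha`, in rank order.
#' @export
screen_hits <- function(screen, alpha = attr(screen, "alpha")) {
  tibble::as_tibble(screen)[screen$p_bonf <= alpha, ]
}

#' Aggregate genes over the screen's hit miRNAs
#'
#' Lists the genes targeted by at least `k` distinct hit miRNAs, with the
#' hit count and each gene's induction ratio — the step that surfaces genes
#' under convergent miRNA pressure (e.g. a gene targeted by 10 or more of the
#' reported miRNAs).
#'
#' @param atlas Atlas tibble.
#' @param hits A `mirna_screen` tibble (or any subset of its rows, e.g.
#'   [screen_hits()] or the top-n report).
#' @param expression Expression tibble supplying the induction ratios.
#' @param k Minimum number of distinct targeting hit miRNAs.
#' @return A tibble `gene_id`, `n_targeting_hits`, `induction_ratio`, sorted
#'   by count descending; may be empty.
#' @export
aggregate_genes <- function(atlas, hits, expression, k = 10) {
  stopifnot(k >= 1)
  if (nrow(hits) == 0) abort("hits is empty")
  sub <- atlas[atlas$mirna_id %in% hits$mirna_id, ]
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(sub), .data$gene_id),
    n_targeting_hits = dplyr::n_distinct(.data$mirna_id), .groups = "drop"
  )
  counts <- counts[counts$n_targeting_hits >= k, ]
  out <- dplyr::left_join(counts, expression[c("gene_id", "induction_ratio")],
                          by = "gene_id")
  dplyr::arrange(out, dplyr::desc(.data$n_targeting_hits), .data$gene_id)
}

#' Which hit miRNAs target a given gene?
#'
#' @inheritParams aggregate_genes
#' @param gene_id A single gene identifier.
#' @return Character vector of hit miRNA ids targeting the gene, in screen
#'   rank order; empty if none do.
#' @export
mirnas_targeting <- function(atlas, hits, gene_id) {
  stopifnot(length(gene_id) == 1L, nzchar(gene_id))
  hits <- dplyr::arrange(tibble::as_tibble(hits), .data$rank)
  targeting <- unique(atlas$mirna_id[atlas$gene_id == gene_id])
  hits$mirna_id[hits$mirna_id %in% targeting]
}

#' @export
tidy.mirna_screen <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mirna_screen <- function(x, ...) {
  tibble::tibble(
    m_tested = attr(x, "m_tested"),
    n_untestable = attr(x, "n_untestable"),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    min_p_bonf = min(x$p_bonf)
  )
}
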
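#' Build a biomarker panel score from delta-Ct values
#'
#' The per-sample score is the (sign-oriented) sum of delta-Ct over the panel
#' assays. Because Ct decreases when expression increases, markers
#' *overexpressed* in cases have smaller delta-Ct there; the default
#' orientation therefore negates the summed delta-Ct so that larger scores
#' are more case-like. Samples missing any panel assay are dropped with a
#' logged count.
#'
#' @param dct Delta-Ct tibble with a `group` column.
#' @param assays Character vector of panel assay ids (>= 1).
#' @param direction `-1` (default): score = -sum(delta_ct); `+1`: raw sum,
#'   for markers underexpressed in cases.
#' @return A tibble `sample_id`, `score`, `group`.
#' @export
panel_score <- function(dct, assays, direction = -1) {
  if (length(assays) == 0) abort("assay list is empty")
  stopifnot(direction %in% c(-1, 1))
  if (!"group" %in% names(dct)) abort("dct must carry a 'group' column")
  d <- dct[dct$assay_id %in% assays, ]
  missing_assays <- setdiff(assays, unique(d$assay_id))
  if (length(missing_assays) > 0) {
    abort(paste0("assay(s) not present in dct: ",
                 paste(missing_assays, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(d[c("sample_id", "group", "assay_id", "delta_ct")],
                             names_from = "assay_id", values_from = "delta_ct")
  complete <- complete.cases(wide[assays])
  if (any(!complete)) {
    mb_log("panel_score: dropped ", sum(!complete),
           " sample(s) missing a panel assay")
  }
  wide <- wide[complete, ]
  tibble::tibble(
    sample_id = wide$sample_id,
    score = direction * rowSums(wide[assays]),
    group = wide$group
  )
}

#' Empirical ROC evaluation of a score
#'
#' Builds the empirical ROC over all distinct score thresholds, computes the
#' AUC by the trapezoid rule (ties traversed diagonally, so the AUC equals
#' the normalized Mann-Whitney U statistic with ties counted 1/2), a 95%
#' confidence interval from the DeLong placement-value variance, the
#' Youden-optimal cutoff (maximizing sensitivity + specificity - 1), and the
#' cutoff's operating characteristics: sensitivity, specificity, predictive
#' values at the observed prevalence, and likelihood ratios.
#'
#' @param scores A tibble with columns `score` and `group` (e.g. from
#'   [panel_score()]), or a numeric vector if `labels` is given.
#' @param labels Optional vector of group labels matching a numeric `scores`.
#' @param positive Label of the positive (case) class.
#' @param conf_level Confidence level of the DeLong interval.
#' @return An object of class `roc_report`: a list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`; classification rule is score >= threshold),
#'   `auc`, `ci` (lo, hi), `cutoff`, `sens`, `spec`, `ppv`, `npv`, `lr_pos`,
#'   `lr_neg`, `n_case`, `n_control`, `degenerate` (all scores identical:
#'   AUC 0.5, no CI). Use [tidy()] for the curve, [glance()] for the metrics
#'   and [autoplot()] for the plot.
#' @examples
#' roc_eval(c(2, 3, 4, 1, 2, 3), rep(c("case", "control"), each = 3))$auc
#' @export
roc_eval <- function(scores, labels = NULL, positive = "case",
                     conf_level = 0.95) {
  if (is.data.frame(scores)) {
    labels <- scores$group
    sample_ids <- scores$sample_id
    scores <- scores$score
  } else {
    sample_ids <- NULL
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  is_case <- labels == positive
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("need at least one case and one control")
  if (any(!is.finite(scores))) abort("scores must be finite")

  x <- scores[is_case]
  y <- scores[!is_case]

  # tie-aware empirical curve: thresholds descending, rule score >= t
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(y >= t), numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr)
  )
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- dplyr::bind_rows(curve,
      tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)

  degenerate <- length(unique(scores)) == 1L
  if (degenerate) {
    ci <- c(NA_real_, NA_real_)
  } else {
    # DeLong: placement values of each case over controls and vice versa
    psi <- function(a, b) (a > b) + 0.5 * (a == b)
    v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
    v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
    var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(var_auc)))
  }

  j <- curve$tpr - curve$fpr
  finite <- is.finite(curve$threshold)
  best <- which(finite)[which.max(j[finite])]
  if (length(best) == 0) best <- 1L
  sens <- curve$tpr[best]
  spec <- 1 - curve$fpr[best]
  prev <- n1 / (n1 + n0)
  ppv_den <- sens * prev + (1 - spec) * (1 - prev)
  npv_den <- spec * (1 - prev) + (1 - sens) * prev
  structure(
    list(
      curve = curve, auc = auc, ci = ci, conf_level = conf_level,
      cutoff = curve$threshold[best], sens = sens, spec = spec,
      ppv = if (ppv_den > 0) sens * prev / ppv_den else NA_real_,
      npv = if (npv_den > 0) spec * (1 - prev) / npv_den else NA_real_,
      lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
      lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
      n_case = n1, n_control = n0, degenerate = degenerate,
      sample_ids = sample_ids
    ),
    class = "roc_report"
  )
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf(
    "ROC report: AUC %.3f (%d%% CI %.3f-%.3f), n = %d cases / %d controls\n",
    x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2], x$n_case, x$n_control))
  cat(sprintf(
    "Youden cutoff %.3g: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f, LR+ %.2f, LR- %.2f\n",
    x$cutoff, x$sens, x$spec, x$ppv, x$npv, x$lr_pos, x$lr_neg))
  if (x$degenerate) cat("(degenerate: all scores identical, CI unavailable)\n")
  invisible(x)
}

#' @export
tidy.roc_report <- function(x, ...) x$curve

#' @export
glance.roc_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_lo = x$ci[1], ci_hi = x$ci[2], cutoff = x$cutoff,
    sens = x$sens, spec = x$spec, ppv = x$ppv, npv = x$npv,
    lr_pos = x$lr_pos, lr_neg = x$lr_neg,
    n_case = x$n_case, n_control = x$n_control, degenerate = x$degenerate
  )
}

#' @export
autoplot.roc_report <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::annotate("text", x = 0.65, y = 0.1,
      label = sprintf("AUC %.3f (%.2f-%.2f)", object$auc,
                      object$ci[1], object$ci[2])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Compare biomarker panels evaluated on the same samples
#'
#' @param reports A named list of [roc_eval()] reports built on the same
#'   sample set.
#' @param allow_unpaired Permit reports whose underlying sample sets differ
#'   (e.g. because of panel-specific missingness).
#' @return A tibble, one row per panel with the [glance()] metrics, ordered
#'   by AUC descending.
#' @export
compare_panels <- function(reports, allow_unpaired = FALSE) {
  stopifnot(is.list(reports), length(reports) >= 1)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- paste0("panel_", seq_along(reports))
  }
  ids <- purrr::map(reports, "sample_ids")
  if (!allow_unpaired && length(reports) > 1 && !any(vapply(ids, is.null, logical(1)))) {
    base <- sort(ids[[1]])
    same <- vapply(ids, function(i) identical(sort(i), base), logical(1))
    if (!all(same)) {
      abort("panels were evaluated on different sample sets; set allow_unpaired = TRUE to override")
    }
  }
  out <- purrr::map_dfr(reports, glance, .id = "panel")
  dplyr::arrange(out, dplyr::desc(.data$auc))
}
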
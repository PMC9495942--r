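#' Compute per-sample delta-Ct values
#'
#' `delta_ct = Ct_target - mean(Ct of the reference assays)` for each sample.
#' Multiple reference assays (e.g. two stably expressed normalizer miRNAs)
#' are combined by the arithmetic mean of their Cts, i.e. the geometric mean
#' on the expression scale. Samples missing any reference Ct are dropped with
#' a logged count; missing target Cts stay missing for that (sample, assay).
#'
#' @param ct Long Ct tibble (`sample_id`, `assay_id`, `role`, `ct`), e.g.
#'   from [read_ct_table()] or [simulate_ct_study()].
#' @param meta Optional sample metadata joined onto the result by `sample_id`.
#' @return A tibble `sample_id`, `assay_id`, `delta_ct` (cycles), one row per
#'   retained sample and target assay, plus any metadata columns.
#' @export
delta_ct <- function(ct, meta = NULL) {
  refs <- unique(ct$assay_id[ct$role == "reference"])
  if (length(refs) == 0) abort("no reference assay in the Ct table")
  ref_means <- dplyr::summarise(
    dplyr::group_by(ct[ct$role == "reference", ], .data$sample_id),
    ref_ct = mean(.data$ct), n_ref = sum(!is.na(.data$ct)),
    .groups = "drop"
  )
  incomplete <- ref_means$sample_id[!is.finite(ref_means$ref_ct)]
  if (length(incomplete) > 0) {
    mb_log("delta_ct: dropped ", length(incomplete),
           " sample(s) with missing reference Ct")
  }
  ref_means <- ref_means[is.finite(ref_means$ref_ct), ]
  out <- dplyr::inner_join(ct[ct$role == "target", ],
                           ref_means[c("sample_id", "ref_ct")],
                           by = "sample_id")
  out$delta_ct <- out$ct - out$ref_ct
  out <- out[c("sample_id", "assay_id", "delta_ct")]
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, tibble::as_tibble(meta), by = "sample_id")
  }
  tibble::as_tibble(out)
}

#' Relative quantification by the 2^-delta-delta-Ct model
#'
#' Per assay: `delta_delta_ct = mean(delta_ct | case) - mean(delta_ct |
#' control)` and `fold = 2^-delta_delta_ct`, with a two-sample t-test on the
#' delta-Ct (log2 expression) scale. Complete cases per assay; a group with
#' fewer than 2 observations for an assay is an error.
#'
#' @param dct Delta-Ct tibble carrying a `group` column (see [delta_ct()]
#'   with `meta`).
#' @param case,control Group labels defining the contrast.
#' @param var_equal Use the classical pooled-variance t-test (default, the
#'   convention of the qPCR literature) or Welch.
#' @return A tibble, one row per assay: `assay_id`, `delta_delta_ct`, `fold`,
#'   `p_value`, `n_case`, `n_control`, `degenerate` (TRUE when the t-test is
#'   undefined because all residuals are zero).
#' @export
fold_change <- function(dct, case = "case", control = "control",
                        var_equal = TRUE) {
  if (!"group" %in% names(dct)) abort("dct must carry a 'group' column")
  dct <- dct[!is.na(dct$delta_ct) & dct$group %in% c(case, control), ]
  purrr::map_dfr(split(dct, dct$assay_id), function(d) {
    x <- d$delta_ct[d$group == case]
    y <- d$delta_ct[d$group == control]
    if (length(x) < 2 || length(y) < 2) {
      abort(paste0("assay '", d$assay_id[1],
                   "': each group needs >= 2 samples (got ",
                   length(x), " / ", length(y), ")"))
    }
    ddct <- mean(x) - mean(y)
    # zero residual variance: no test statistic exists. If the groups are
    # also identical there is exactly no effect (p = 1); otherwise the
    # result is flagged variance-degenerate with an undefined p.
    degen <- stats::sd(x) == 0 && stats::sd(y) == 0
    p <- if (degen) {
      if (ddct == 0) 1 else NA_real_
    } else {
      t.test(x, y, var.equal = var_equal)$p.value
    }
    degen <- degen && ddct != 0
    tibble::tibble(
      assay_id = d$assay_id[1], delta_delta_ct = ddct, fold = 2^(-ddct),
      p_value = p, n_case = length(x), n_control = length(y),
      degenerate = degen
    )
  })
}

#' Paired lesion-versus-eutopic tissue contrast
#'
#' For tissue designs where each patient contributes both the endometriotic
#' lesion and their own eutopic endometrium, the contrast is the
#' within-patient difference of delta-Ct, tested with a paired t-test, and
#' the fold change is `2^-mean(paired difference)`. Patients missing either
#' tissue are dropped with a logged count.
#'
#' @param dct Delta-Ct tibble with columns `patient_id` and `tissue` in
#'   addition to `sample_id`, `assay_id`, `delta_ct`.
#' @param lesion,eutopic Labels of the two tissues in the `tissue` column.
#' @return A tibble per assay: `assay_id`, `delta_delta_ct` (mean paired
#'   lesion - eutopic difference), `fold`, `p_value`, `n_pairs`,
#'   `degenerate` (zero-variance differences: fold reported, p undefined).
#' @export
paired_tissue_contrast <- function(dct, lesion = "lesion",
                                   eutopic = "eutopic") {
  for (col in c("patient_id", "tissue")) {
    if (!col %in% names(dct)) abort(paste0("dct must carry a '", col, "' column"))
  }
  dct <- dct[!is.na(dct$delta_ct) & dct$tissue %in% c(lesion, eutopic), ]
  purrr::map_dfr(split(dct, dct$assay_id), function(d) {
    wide <- tidyr::pivot_wider(d[c("patient_id", "tissue", "delta_ct")],
                               names_from = "tissue", values_from = "delta_ct")
    n_unpaired <- sum(!complete.cases(wide))
    if (n_unpaired > 0) {
      mb_log("paired_tissue_contrast(", d$assay_id[1], "): dropped ",
             n_unpaired, " unpaired patient(s)")
    }
    wide <- wide[complete.cases(wide), ]
    if (nrow(wide) < 2) {
      abort(paste0("assay '", d$assay_id[1], "': fewer than 2 complete pairs"))
    }
    diffs <- wide[[lesion]] - wide[[eutopic]]
    degen <- stats::sd(diffs) == 0
    p <- if (degen) {
      if (mean(diffs) == 0) 1 else NA_real_
    } else {
      t.test(diffs)$p.value
    }
    degen <- degen && mean(diffs) != 0
    tibble::tibble(
      assay_id = d$assay_id[1], delta_delta_ct = mean(diffs),
      fold = 2^(-mean(diffs)), p_value = p, n_pairs = nrow(wide),
      degenerate = degen
    )
  })
}
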
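#' Simulate a target atlas and lesion transcriptome for the enrichment screen
#'
#' Generates the two inputs of the expression-bias screen with known ground
#' truth. Gene categories are drawn from `background_props`
#' (down / unchanged / up); each gene then receives an induction ratio drawn
#' log-uniformly within its category interval — down: (0.01, 0.5),
#' unchanged: \[0.5, 2\], up: (2, `up_max`). Target sets are sampled without
#' replacement; for a *planted* miRNA, downregulated genes are weighted by the
#' given odds ratio, so its target set is enriched in the down category.
#' Unplanted miRNAs sample uniformly, i.e. carry no signal.
#'
#' @param n_genes Number of genes in the simulated transcriptome.
#' @param n_mirnas Number of miRNAs in the atlas (ids `mir001`, `mir002`, ...).
#' @param target_size_range Integer range (min, max) of target-set sizes,
#'   drawn uniformly per miRNA.
#' @param background_props Proportions (down, unchanged, up); must sum to 1.
#' @param planted Named numeric vector of enrichment odds ratios (>= 1) for
#'   the down category, named by miRNA id; `NULL` for an all-null screen.
#' @param up_max Upper bound of the upregulated ratio interval.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list with `atlas` (tibble `mirna_id`, `gene_id`), `expression`
#'   (tibble `gene_id`, `induction_ratio`) and `truth` (tibble `mirna_id`,
#'   `odds_ratio`, 1 for unplanted miRNAs).
#' @export
simulate_screen_inputs <- function(n_genes = 2000, n_mirnas = 50,
                                   target_size_range = c(50, 150),
                                   background_props = c(0.2, 0.7, 0.1),
                                   planted = NULL, up_max = 100,
                                   seed = NULL) {
  target_size_range <- as.numeric(target_size_range)
  stopifnot(n_genes >= 1, n_mirnas >= 1, length(target_size_range) == 2,
            target_size_range[1] >= 1,
            target_size_range[1] <= target_size_range[2])
  if (target_size_range[2] > n_genes) {
    abort("target_set_size max exceeds the number of genes")
  }
  p <- as.numeric(background_props)
  if (length(p) != 3 || any(p <= 0) || any(p >= 1) || abs(sum(p) - 1) > 1e-12) {
    abort("background_props must be three proportions in (0,1) summing to 1")
  }
  if (!is.null(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted)))) {
      abort("planted must be a named vector (names are miRNA ids)")
    }
    if (any(planted < 1)) abort("planted odds ratios must be >= 1")
  }

  with_seed_maybe(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
    if (!is.null(planted) && !all(names(planted) %in% mirna_ids)) {
      abort("planted names must be among the simulated miRNA ids (mir001, ...)")
    }
    category <- sample(c("down", "unchanged", "up"), n_genes,
                       replace = TRUE, prob = p)
    lo <- c(down = 0.01, unchanged = 0.5, up = 2)[category]
    hi <- c(down = 0.5, unchanged = 2, up = up_max)[category]
    ratio <- exp(runif(n_genes, log(lo), log(hi)))
    expression <- tibble::tibble(gene_id = gene_ids, induction_ratio = ratio)

    size_choices <- seq.int(target_size_range[1], target_size_range[2])
    sizes <- if (length(size_choices) == 1) {
      rep.int(size_choices, n_mirnas)  # sample(<scalar>) would mean 1:n
    } else {
      sample(size_choices, n_mirnas, replace = TRUE)
    }
    pairs <- purrr::map2(mirna_ids, sizes, function(m, sz) {
      or <- if (!is.null(planted) && m %in% names(planted)) planted[[m]] else 1
      w <- ifelse(category == "down", or, 1)
      tibble::tibble(mirna_id = m, gene_id = sample(gene_ids, sz, prob = w))
    })
    atlas <- dplyr::bind_rows(pairs)
    truth <- tibble::tibble(
      mirna_id = mirna_ids,
      odds_ratio = ifelse(mirna_ids %in% names(planted %||% numeric()),
                          unname(planted[mirna_ids]), 1)
    )
    truth$odds_ratio[is.na(truth$odds_ratio)] <- 1
    list(atlas = atlas, expression = expression, truth = truth)
  })
}

#' Default assay panel for a simulated plasma qPCR study
#'
#' One reference assay (U6-like) and two target miRNAs whose planted group
#' effects mirror the overexpression reported for circulating markers in
#' ovarian endometrioma: roughly 30-fold (-log2(30) ~ -4.9 cycles) and 4-fold
#' (-2 cycles) in cases. Effects are on the Ct scale, so negative shifts mean
#' overexpression.
#'
#' @return A tibble with columns `assay_id`, `role`, `baseline_ct`,
#'   `group_effect`, `phase_effect`, `interaction_effect` (all in cycles).
#' @export
plasma_assay_panel <- function() {
  tibble::tibble(
    assay_id = c("U6", "let-7b-5p", "miR-92a-3p"),
    role = c("reference", "target", "target"),
    baseline_ct = c(20, 30, 31),
    group_effect = c(0, -log2(30), -2),
    phase_effect = c(0, 0, 0),
    interaction_effect = c(0, 0, 0)
  )
}

#' Simulate a two-group plasma Ct study
#'
#' Each Ct value is
#' `baseline + group_effect * [case] + phase_effect * [luteal] +
#' interaction_effect * [case & luteal] + N(0, noise_sd^2)`.
#' Reference assays receive technical noise but no group/phase effects.
#' Cycle phases are assigned half follicular / half luteal within each group,
#' mirroring a cohort balanced over the menstrual cycle.
#'
#' @param n_cases,n_controls Samples per group (>= 2 each).
#' @param assays Assay definition tibble, see [plasma_assay_panel()]. Rows
#'   with `role == "reference"` must have zero effects.
#' @param noise_sd Gaussian technical noise on the Ct scale, in cycles (> 0).
#' @param seed Optional integer seed.
#' @return A list with `ct` (long tibble `sample_id`, `assay_id`, `role`,
#'   `ct`) and `meta` (tibble `sample_id`, `group`, `cycle_phase`).
#' @export
simulate_ct_study <- function(n_cases = 50, n_controls = 50,
                              assays = plasma_assay_panel(),
                              noise_sd = 1, seed = NULL) {
  stopifnot(n_cases >= 2, n_controls >= 2)
  if (!is.finite(noise_sd) || noise_sd <= 0) abort("noise_sd must be > 0")
  need <- c("assay_id", "role", "baseline_ct", "group_effect",
            "phase_effect", "interaction_effect")
  miss <- setdiff(need, names(assays))
  if (length(miss) > 0) abort(paste0("assays is missing: ", paste(miss, collapse = ", ")))
  ref <- assays$role == "reference"
  if (any(ref & (assays$group_effect != 0 | assays$phase_effect != 0 |
                 assays$interaction_effect != 0))) {
    abort("reference assays must carry zero group/phase/interaction effects")
  }

  with_seed_maybe(seed, {
    meta <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n_cases + n_controls)),
      group = rep(c("case", "control"), c(n_cases, n_controls)),
      cycle_phase = c(
        rep(c("follicular", "luteal"), length.out = n_cases),
        rep(c("follicular", "luteal"), length.out = n_controls)
      )
    )
    grid <- tidyr::crossing(meta, assays)
    is_case <- as.numeric(grid$group == "case")
    is_lut <- as.numeric(grid$cycle_phase == "luteal")
    grid$ct <- grid$baseline_ct +
      grid$group_effect * is_case +
      grid$phase_effect * is_lut +
      grid$interaction_effect * is_case * is_lut +
      rnorm(nrow(grid), 0, noise_sd)
    ct <- grid[c("sample_id", "assay_id", "role", "ct")]
    ct <- dplyr::arrange(ct, .data$sample_id, .data$assay_id)
    list(ct = ct, meta = meta)
  })
}

#' Simulate a miRNA-mimic transfection experiment
#'
#' Emulates a fully crossed design: patients x cell types (epithelial,
#' stromal) x transfection arms (scrambled control plus miRNA mimics) x
#' estradiol doses (0, 1e-8, 1e-6 M). The measured expression of the target
#' gene is `patient_effect * arm_effect * dose_effect * lognormal noise`;
#' `rel_expr` is the value normalized to the scrambled arm within each
#' patient x cell-type x dose block, which is what the downstream factorial
#' analysis consumes.
#'
#' @param n_patients Number of patient blocks (>= 1).
#' @param arm_effects Either a named numeric vector of multiplicative effects
#'   per arm (applied at every dose; its names define the design arms), or a
#'   data frame with columns `arm`, `dose`, `effect` for dose-specific
#'   effects, in which case `arms` defines the design and unlisted
#'   combinations default to 1. The scrambled arm always has effect 1.
#' @param arms Design arms used with a data-frame `arm_effects`.
#' @param dose_effects Numeric vector of multiplicative estradiol effects,
#'   one per dose in `doses`.
#' @param doses Estradiol doses in molar units.
#' @param cell_types Cell types cultured separately from each biopsy.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @param patient_cv Between-patient coefficient of variation.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample_id`, `patient_id`, `cell_type`,
#'   `arm`, `dose`, `value` (raw) and `rel_expr` (scrambled-normalized).
#' @export
simulate_transfection <- function(n_patients = 10,
                                  arm_effects = c(scrambled = 1,
                                                  mimic_let7b = 1,
                                                  mimic_miR92a = 1,
                                                  mimic_both = 1),
                                  dose_effects = c(1, 1, 0.7),
                                  doses = c(0, 1e-8, 1e-6),
                                  arms = c("scrambled", "mimic_let7b",
                                           "mimic_miR92a", "mimic_both"),
                                  cell_types = c("epithelial", "stromal"),
                                  noise_cv = 0.2, patient_cv = 0.2,
                                  seed = NULL) {
  stopifnot(n_patients >= 1, length(dose_effects) == length(doses),
            noise_cv > 0, patient_cv >= 0)
  if (is.data.frame(arm_effects)) {
    need <- c("arm", "dose", "effect")
    if (!all(need %in% names(arm_effects))) {
      abort("data-frame arm_effects needs columns arm, dose, effect")
    }
    if (!all(arm_effects$arm %in% arms)) {
      abort("arm_effects lists an arm not in the design arms")
    }
    eff_tbl <- tibble::as_tibble(arm_effects[need])
    if (any(eff_tbl$arm == "scrambled" & eff_tbl$effect != 1)) {
      abort("the scrambled arm must have effect 1.0")
    }
  } else {
    arms <- names(arm_effects)
    eff_tbl <- tidyr::crossing(
      tibble::tibble(arm = arms, base = unname(arm_effects)),
      dose = doses
    )
    eff_tbl$effect <- eff_tbl$base
    eff_tbl <- eff_tbl[c("arm", "dose", "effect")]
  }
  if (!"scrambled" %in% arms) abort("arm_effects must include a 'scrambled' arm")
  scr <- eff_tbl$effect[eff_tbl$arm == "scrambled"]
  if (any(scr != 1)) abort("the scrambled arm must have effect 1.0")

  with_seed_maybe(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    sdpat <- if (patient_cv > 0) sqrt(log(1 + patient_cv^2)) else 0
    patient_ids <- sprintf("p%02d", seq_len(n_patients))
    pat_eff <- setNames(exp(rnorm(n_patients, 0, sdpat)), patient_ids)
    design <- tidyr::crossing(
      patient_id = patient_ids, cell_type = cell_types,
      arm = factor(arms, levels = arms), dose = doses
    )
    design$arm <- as.character(design$arm)
    design <- dplyr::left_join(design, eff_tbl, by = c("arm", "dose"))
    design$effect[is.na(design$effect)] <- 1
    design$value <- pat_eff[design$patient_id] * design$effect *
      exp(rnorm(nrow(design), 0, sdlog))
    design <- dplyr::group_by(design, .data$patient_id, .data$cell_type, .data$dose)
    design <- dplyr::mutate(
      design,
      rel_expr = .data$value / .data$value[.data$arm == "scrambled"]
    )
    design <- dplyr::ungroup(design)
    design$sample_id <- sprintf("t%04d", seq_len(nrow(design)))
    design[c("sample_id", "patient_id", "cell_type", "arm", "dose",
             "value", "rel_expr")]
  })
}
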
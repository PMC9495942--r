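#' Read a miRNA -> target-gene atlas
#'
#' Parses a two-column delimited table of (miRNA id, gene id) pairs, the
#' layout of a target-interaction atlas export. Duplicate pairs are dropped
#' (with a message giving the count); identifiers are matched later by exact,
#' case-sensitive string equality.
#'
#' @param path Path to a delimited text file with columns `mirna_id` and
#'   `gene_id`. Lines starting with `#` are ignored.
#' @param delim Field delimiter; tab by default.
#' @param header Does the file carry a header line? The column *names* in the
#'   header are not interpreted; only the order (miRNA, gene) matters.
#' @return A tibble with columns `mirna_id`, `gene_id`, one row per unique
#'   pair, every miRNA having at least one target.
#' @seealso [write_atlas()], [atlas_mirnas()], [atlas_targets()]
#' @export
read_atlas <- function(path, delim = "\t", header = TRUE) {
  raw <- read_checked(path, delim, header,
    col_names = c("mirna_id", "gene_id"),
    col_types = readr::cols(
      mirna_id = readr::col_character(),
      gene_id = readr::col_character()
    )
  )
  validate_nonempty_strings(raw, path, header)
  n0 <- nrow(raw)
  out <- dplyr::distinct(raw, .data$mirna_id, .data$gene_id)
  if (nrow(out) < n0) {
    mb_log("read_atlas: dropped ", n0 - nrow(out), " duplicate pair(s)")
  }
  out
}

#' Read a gene induction-ratio table
#'
#' The induction ratio is the lesion/eutopic expression ratio of a gene, a
#' strictly positive dimensionless number (e.g. 0.0084 for a gene repressed
#' more than 100-fold in the lesion).
#'
#' @inheritParams read_atlas
#' @return A tibble with columns `gene_id` (unique) and `induction_ratio`
#'   (finite, > 0).
#' @export
read_expression <- function(path, delim = "\t", header = TRUE) {
  raw <- read_checked(path, delim, header,
    col_names = c("gene_id", "induction_ratio"),
    col_types = readr::cols(
      gene_id = readr::col_character(),
      induction_ratio = readr::col_double()
    )
  )
  off <- if (header) 1L else 0L
  bad <- which(is.na(raw$gene_id) | raw$gene_id == "")
  if (length(bad) > 0) {
    abort(paste0(path, ": empty gene id at line ", bad[1] + off))
  }
  bad <- which(!is.finite(raw$induction_ratio) | raw$induction_ratio <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      path, ": induction ratio must be a positive finite number, offending line ",
      bad[1] + off, " (value ", raw$induction_ratio[bad[1]], ")"
    ))
  }
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup) > 0) {
    lines <- which(raw$gene_id == dup[1])
    abort(paste0(
      path, ": duplicate gene id '", dup[1], "' at lines ",
      paste(lines + off, collapse = ", ")
    ))
  }
  raw
}

#' Read a long-format Ct table and its sample metadata
#'
#' The Ct table is long: one row per (sample, assay) with the assay role
#' (`target` or `reference`) and the raw Ct value in PCR cycles. Missing Ct
#' values (empty cells or `NA`) are kept as `NA` — undetectable wells are a
#' normal feature of plasma qPCR — and are handled downstream by [delta_ct()].
#'
#' @param ct_path Path to a delimited file with columns
#'   `sample_id`, `assay_id`, `role`, `ct`.
#' @param meta_path Path to a sample-metadata file keyed by `sample_id` with a
#'   `group` column plus any further covariates (cycle phase, symptom scores,
#'   transfection arm, estradiol dose, ...).
#' @param delim Field delimiter for both files.
#' @param group_levels Allowed group labels; anything else is rejected.
#' @return A list with elements `ct` (tibble `sample_id`, `assay_id`, `role`,
#'   `ct`) and `meta` (tibble of per-sample covariates), aligned on the same
#'   sample ids.
#' @export
read_ct_table <- function(ct_path, meta_path, delim = "\t",
                          group_levels = c("case", "control")) {
  ct <- readr::read_delim(ct_path,
    delim = delim, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c("sample_id", "assay_id", "role", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) {
    abort(paste0(ct_path, ": missing required column(s): ", paste(miss, collapse = ", ")))
  }
  bad_role <- which(!ct$role %in% c("target", "reference"))
  if (length(bad_role) > 0) {
    abort(paste0(
      ct_path, ": unknown assay role '", ct$role[bad_role[1]],
      "' at line ", bad_role[1] + 1L
    ))
  }
  ct$ct <- suppressWarnings(as.numeric(ct$ct))
  inf <- which(is.infinite(ct$ct))
  if (length(inf) > 0) {
    abort(paste0(ct_path, ": non-finite Ct at line ", inf[1] + 1L))
  }
  ct <- tibble::as_tibble(ct[need])

  meta <- read_sample_meta(meta_path, delim = delim, group_levels = group_levels)

  only_ct <- setdiff(unique(ct$sample_id), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, unique(ct$sample_id))
  if (length(only_ct) + length(only_meta) > 0) {
    abort(paste0(
    "sample ids do not match between Ct and metadata tables; ",
      "only in Ct: [", paste(only_ct, collapse = ", "), "]; ",
      "only in metadata: [", paste(only_meta, collapse = ", "), "]"
    ))
  }
  list(ct = ct, meta = meta)
}

#' Read a sample-metadata table
#'
#' @inheritParams read_ct_table
#' @param path Path to the metadata file; must contain `sample_id` and `group`.
#' @return A tibble, one row per sample.
#' @export
read_sample_meta <- function(path, delim = "\t",
                             group_levels = c("case", "control")) {
  meta <- readr::read_delim(path,
    delim = delim, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      group = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  for (col in c("sample_id", "group")) {
    if (!col %in% names(meta)) {
      abort(paste0(path, ": missing required column '", col, "'"))
    }
  }
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0) {
    abort(paste0(path, ": duplicate sample id '", dup[1], "'"))
  }
  bad <- which(!meta$group %in% group_levels)
  if (length(bad) > 0) {
    abort(paste0(
      path, ": unknown group label '", meta$group[bad[1]], "' at line ",
      bad[1] + 1L, " (allowed: ", paste(group_levels, collapse = ", "), ")"
    ))
  }
  if ("cycle_phase" %in% names(meta)) {
    ok <- c("follicular", "luteal", "unknown")
    bad <- which(!meta$cycle_phase %in% ok)
    if (length(bad) > 0) {
      abort(paste0(
        path, ": unknown cycle phase '", meta$cycle_phase[bad[1]],
        "' at line ", bad[1] + 1L
      ))
    }
  }
  if (all(c("arm", "estradiol_dose") %in% names(meta))) {
    # the transfection design uses a fixed estradiol gradient
    bad <- which(!is.na(meta$estradiol_dose) &
                   !meta$estradiol_dose %in% c(0, 1e-8, 1e-6))
    if (length(bad) > 0) {
      abort(paste0(path, ": estradiol dose must be 0, 1e-8 or 1e-6 M, got '",
                   meta$estradiol_dose[bad[1]], "' at line ", bad[1] + 1L))
    }
  }
  tibble::as_tibble(meta)
}

#' Write pipeline tables
#'
#' Delimited writers matching the readers, so that write-then-read round-trips
#' reproduce the in-memory object. An optional `comment` line (e.g. a config
#' hash and seed) is prepended with a `#` prefix and skipped on re-read.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param comment Optional single-line provenance comment.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = "\t", comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_delim(x, path, delim = delim, na = "", append = TRUE,
                       col_names = TRUE)
  } else {
    readr::write_delim(x, path, delim = delim, na = "")
  }
  invisible(path)
}

#' @rdname write_table
#' @export
write_atlas <- function(x, path, delim = "\t", comment = NULL) {
  write_table(x[c("mirna_id", "gene_id")], path, delim, comment)
}

#' @rdname write_table
#' @export
write_expression <- function(x, path, delim = "\t", comment = NULL) {
  write_table(x[c("gene_id", "induction_ratio")], path, delim, comment)
}

#' @rdname write_table
#' @export
write_ct_table <- function(x, path, delim = "\t", comment = NULL) {
  write_table(x[c("sample_id", "assay_id", "role", "ct")], path, delim, comment)
}

#' List the miRNAs of an atlas / the targets of one miRNA
#'
#' @param atlas Atlas tibble as returned by [read_atlas()].
#' @return `atlas_mirnas()`: ordered unique miRNA ids. `atlas_targets()`: the
#'   set of gene ids regulated by `mirna_id`.
#' @export
atlas_mirnas <- function(atlas) {
  sort(unique(atlas$mirna_id))
}

#' @rdname atlas_mirnas
#' @param mirna_id A single miRNA identifier.
#' @export
atlas_targets <- function(atlas, mirna_id) {
  stopifnot(length(mirna_id) == 1L)
  unique(atlas$gene_id[atlas$mirna_id == mirna_id])
}

# Shared two-column reader with line-numbered failure modes. `header` files
# get +1 on reported line numbers.
read_checked <- function(path, delim, header, col_names, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  body <- if (header) lines[-1] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) abort(paste0(path, ": file is empty"))

  raw <- suppressWarnings(readr::read_delim(path,
    delim = delim, comment = "#", show_col_types = FALSE,
    col_names = if (header) TRUE else col_names,
    col_types = col_types
  ))  # parse problems are re-raised below with line numbers
  if (header) {
    if (ncol(raw) != length(col_names)) {
      abort(paste0(
        path, ": expected ", length(col_names), " columns (",
        paste(col_names, collapse = ", "), "), found ", ncol(raw)
      ))
    }
    names(raw) <- col_names
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    off <- 0L  # readr rows already count the header line
    abort(paste0(
      path, ": malformed row at line ", probs$row[1] + off,
      " (", probs$expected[1], ", got ", probs$actual[1], ")"
    ))
  }
  tibble::as_tibble(raw)
}

validate_nonempty_strings <- function(raw, path, header) {
  off <- if (header) 1L else 0L
  for (col in names(raw)) {
    bad <- which(is.na(raw[[col]]) | raw[[col]] == "")
    if (length(bad) > 0) {
      abort(paste0(path, ": empty ", col, " at line ", bad[1] + off))
    }
  }
  invisible(raw)
}
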
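#' Protein-level peak-volume totals
#'
#' Sums assigned peptide peak volumes per protein and run. A peptide counts
#' as specific only if it maps to a single protein in the table; proteins
#' quantified by fewer than two specific peptides in a run are excluded
#' (one-hit wonders are not considered) and reported via the
#' `excluded` attribute.
#'
#' @param assigned Assigned feature tibble (from [assign_pvs()] /
#'   [assign_study()]); may span several runs.
#' @param min_peptides Minimum specific peptides per protein (default 2).
#' @return Tibble with run metadata, `protein_id`, `n_specific_peptides`,
#'   `total_pv`; attribute `excluded` holds the dropped rows.
#' @export
protein_totals <- function(assigned, min_peptides = 2) {
  if (nrow(assigned) == 0) {
    out <- tibble::tibble(run_id = character(), protein_id = character(),
                          n_specific_peptides = integer(), total_pv = numeric())
    attr(out, "excluded") <- out
    return(out)
  }
  shared <- assigned |>
    dplyr::distinct(.data$peptide_seq, .data$protein_id) |>
    dplyr::count(.data$peptide_seq) |>
    dplyr::filter(.data$n > 1)
  meta_cols <- intersect(META_FIELDS, names(assigned))
  totals <- assigned |>
    dplyr::filter(!.data$peptide_seq %in% shared$peptide_seq) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(meta_cols, "protein_id")))) |>
    dplyr::summarise(
      n_specific_peptides = dplyr::n_distinct(.data$peptide_seq),
      total_pv = sum(.data$pv),
      .groups = "drop"
    )
  keep <- totals$n_specific_peptides >= min_peptides
  out <- totals[keep, ]
  attr(out, "excluded") <- totals[!keep, ]
  out
}

#' Abundance-norm values
#'
#' Divides each protein's summed peak volume by its number of MS-accessible
#' peptides (distinct in-silico tryptic peptides inside the observable mass
#' window), yielding an estimate of molar abundance that is comparable
#' between proteins of different size. Proteins whose digest yields no
#' accessible peptide get `NA` with `norm_defined = FALSE` rather than a
#' division error.
#'
#' @param quant Output of [protein_totals()].
#' @param accessible Tibble `protein_id`, `n_accessible`, e.g. from
#'   [accessible_peptide_counts()].
#' @return `quant` with columns `n_accessible`, `abundance_norm`,
#'   `norm_defined` added.
#' @export
abundance_norm <- function(quant, accessible) {
  stopifnot(all(c("protein_id", "n_accessible") %in% names(accessible)))
  out <- quant |>
    dplyr::left_join(dplyr::distinct(accessible), by = "protein_id") |>
    dplyr::mutate(
      norm_defined = !is.na(.data$n_accessible) & .data$n_accessible > 0,
      abundance_norm = dplyr::if_else(.data$norm_defined,
                                      .data$total_pv / .data$n_accessible,
                                      NA_real_)
    )
  attr(out, "excluded") <- attr(quant, "excluded")
  out
}

#' Purification-versus-control abundance ratios
#'
#' For every protein quantified in at least one target purification,
#' compares a target abundance statistic (median abundance-norm over the
#' target runs in which it was quantified) against the worst-case control
#' (maximum abundance-norm over all negative-control runs). A protein
#' absent from every control is flagged `control_detected = FALSE` and its
#' ratio computed against a pseudo-floor of half the smallest positive
#' abundance-norm observed anywhere in the control run set, so that
#' "not detected in any control" stays distinguishable while the ratio
#' remains finite.
#'
#' @param quant Tibble from [abundance_norm()] covering target and control
#'   runs (requires `sample_class`).
#' @return Tibble `protein_id`, `target_value`, `control_value`,
#'   `control_detected`, `ratio`, `n_target_runs`.
#' @export
ap_vs_control_ratio <- function(quant) {
  stopifnot("sample_class" %in% names(quant))
  quant <- dplyr::filter(quant, .data$norm_defined)
  targets <- dplyr::filter(quant, .data$sample_class == "target_ap")
  controls <- dplyr::filter(quant, .data$sample_class != "target_ap")
  if (nrow(targets) == 0) {
    stop("no target_ap quantifications supplied", call. = FALSE)
  }
  floor_value <- control_pseudo_floor(controls)
  ctrl <- controls |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(control_value = max(.data$abundance_norm), .groups = "drop")
  targets |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(target_value = stats::median(.data$abundance_norm),
                     n_target_runs = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(ctrl, by = "protein_id") |>
    dplyr::mutate(
      control_detected = !is.na(.data$control_value),
      control_value = dplyr::coalesce(.data$control_value, floor_value),
      ratio = .data$target_value / .data$control_value
    )
}

# Half the smallest positive abundance-norm in the control run set; the
# stand-in denominator for proteins never detected in any control.
control_pseudo_floor <- function(controls) {
  pos <- controls$abundance_norm[controls$abundance_norm > 0]
  if (length(pos) == 0) return(1)  # no controls at all: neutral floor
  min(pos) / 2
}
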
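#' End-to-end AP-MS interactor pipeline
#'
#' Runs the full label-free workflow on a multi-run study: per-run m/z
#' recalibration by the median ppm offset, retention-time alignment against
#' the dynamically recomputed median reference, windowed peak-volume
#' assignment, protein totals with the two-peptide rule, abundance-norm
#' values from the in-silico digest of the supplied sequences, and
#' specificity/consistency interactor calling against the negative controls.
#'
#' @param study Multi-run feature tibble (see [read_feature_table()] for
#'   the schema; [simulate_apms_study()] generates one).
#' @param sequences Tibble `protein_id`, `sequence` used for accessible-
#'   peptide counting.
#' @param bait_id Bait accession.
#' @param tolerances A [match_tolerances()].
#' @param digest A [digest_params()].
#' @param config A [call_config()].
#' @param span,rounds,iterations Alignment settings (see [align_study()]).
#' @return A list: `calls` (an `interactor_calls`), `quant` (per-protein,
#'   per-run abundance table), `alignment` (diagnostics), `offsets`
#'   (per-run ppm offsets), `unassigned` (per-run unassigned feature
#'   counts).
#' @export
apms_pipeline <- function(study, sequences, bait_id,
                          tolerances = match_tolerances(),
                          digest = digest_params(),
                          config = call_config(),
                          span = 0.3, rounds = 2, iterations = 2) {
  recal <- recalibrate_study(study,
                             wide_ppm_window = tolerances$wide_ppm_window)
  aligned <- align_study(recal$study, span = span, iterations = iterations,
                         rounds = rounds)
  library <- build_peptide_library(aligned$study)
  assigned <- assign_study(aligned$study, library, tolerances)
  totals <- protein_totals(assigned$assigned)
  quant <- abundance_norm(totals, accessible_peptide_counts(sequences, digest))
  calls <- call_interactors(quant, bait_id, config)
  list(calls = calls, quant = quant,
       alignment = aligned$diagnostics, offsets = recal$offsets,
       unassigned = assigned$unassigned)
}
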
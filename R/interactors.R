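#' Interactor-calling configuration
#'
#' Thresholds of the specificity/consistency decision procedure: the
#' enrichment fold a protein must reach over the worst-case negative
#' control, and how many distinct antibodies must specifically co-purify it
#' under the same solubilisation condition.
#'
#' @param specificity_fold Target/control abundance ratio required for a
#'   purification to count as specific (> 1; default 10).
#' @param min_antibodies Distinct antibodies required for consistency
#'   (>= 2).
#' @param require_same_detergent Antibodies must agree within one detergent
#'   (default `TRUE`).
#' @return A list of class `call_config`.
#' @export
call_config <- function(specificity_fold = 10, min_antibodies = 2,
                        require_same_detergent = TRUE) {
  if (!(specificity_fold > 1)) stop("specificity_fold must be > 1", call. = FALSE)
  if (min_antibodies < 2) stop("min_antibodies must be >= 2", call. = FALSE)
  structure(list(specificity_fold = specificity_fold,
                 min_antibodies = as.integer(min_antibodies),
                 require_same_detergent = isTRUE(require_same_detergent)),
            class = "call_config")
}

#' Specificity test
#'
#' A purification of a protein is specific when its abundance ratio over
#' the worst-case negative control reaches the configured fold, or when the
#' protein was never detected in any control at all (in which case mere
#' quantification in the purification suffices).
#'
#' @param ratio Numeric vector of target/control abundance ratios.
#' @param control_detected Logical vector: detected in any control?
#' @param quantified Logical vector: quantified in the purification?
#' @param config A [call_config()].
#' @return Logical vector of pass/fail.
#' @export
specificity_test <- function(ratio, control_detected, quantified = TRUE,
                             config = call_config()) {
  quantified & (!control_detected | ratio >= config$specificity_fold)
}

#' Consistency test
#'
#' A protein is consistently co-purified if specifically detected with at
#' least `min_antibodies` distinct antibodies under the same solubilisation
#' condition (or across conditions if `require_same_detergent = FALSE`).
#'
#' @param specific_in Tibble with columns `antibody`, `detergent`: the
#'   purifications that passed the specificity test.
#' @param config A [call_config()].
#' @return Single logical.
#' @export
consistency_test <- function(specific_in, config = call_config()) {
  if (is.null(specific_in) || nrow(specific_in) == 0) return(FALSE)
  if (config$require_same_detergent) {
    specific_in |>
      dplyr::group_by(.data$detergent) |>
      dplyr::summarise(n_ab = dplyr::n_distinct(.data$antibody),
                       .groups = "drop") |>
      dplyr::pull(.data$n_ab) |>
      max() >= config$min_antibodies
  } else {
    dplyr::n_distinct(specific_in$antibody) >= config$min_antibodies
  }
}

#' Relative-abundance class of a prey/bait ratio
#'
#' Bins a protein's molar ratio to the bait into the conventional symbols:
#' `=` for 0.33-3.3-fold of the reference, `<` for 0.033-0.33, `<<` for
#' 0.0033-0.033, and `<<<` below 0.0033-fold. Lower bounds are inclusive.
#' Ratios above 3.3 (prey exceeding bait) also map to `=`, with a warning,
#' since no class above parity is defined.
#'
#' @param ratio_to_bait Positive numeric vector.
#' @return Character vector of class symbols.
#' @export
classify_relative_abundance <- function(ratio_to_bait) {
  if (any(is.na(ratio_to_bait)) || any(ratio_to_bait <= 0)) {
    stop("ratio_to_bait must be positive", call. = FALSE)
  }
  if (any(ratio_to_bait > 3.3)) {
    warning("ratio(s) above 3.3-fold of the bait mapped to '='", call. = FALSE)
  }
  dplyr::case_when(
    ratio_to_bait >= 0.33 ~ "=",
    ratio_to_bait >= 0.033 ~ "<",
    ratio_to_bait >= 0.0033 ~ "<<",
    TRUE ~ "<<<"
  )
}

#' Call high-confidence interaction partners
#'
#' The full decision procedure over a quantified study: per-protein
#' worst-case control values and detection flags, a specificity verdict for
#' every target purification, the cross-antibody consistency test, and
#' per-detergent abundance relative to the bait with its class symbol.
#'
#' @param quant Tibble from [abundance_norm()] over all runs (needs
#'   `run_id`, `antibody`, `sample_class`, `detergent`, `protein_id`,
#'   `abundance_norm`, `norm_defined`).
#' @param bait_id Accession of the bait protein; it must be quantified in
#'   every target purification.
#' @param config A [call_config()].
#' @return An object of class `interactor_calls`: a list with
#'   \describe{
#'     \item{calls}{per-protein tibble (`protein_id`, `is_bait`,
#'       `n_specific_aps`, `consistent`, `high_confidence`);}
#'     \item{by_detergent}{per-protein, per-detergent `ratio_to_bait` and
#'       `abundance_class` over specific purifications;}
#'     \item{ap_matrix}{long protein-by-purification verdict table with
#'       `status` in `pass`/`fail`/`not_detected`.}
#'   }
#' @export
call_interactors <- function(quant, bait_id, config = call_config()) {
  stopifnot(inherits(config, "call_config"))
  needed <- c("run_id", "antibody", "sample_class", "detergent",
              "protein_id", "abundance_norm", "norm_defined")
  stopifnot(all(needed %in% names(quant)))
  target_runs <- quant |>
    dplyr::filter(.data$sample_class == "target_ap") |>
    dplyr::distinct(.data$run_id, .data$antibody, .data$detergent)
  if (dplyr::n_distinct(target_runs$antibody) < 2) {
    stop("interactor calling needs target purifications with >= 2 antibodies",
         call. = FALSE)
  }
  bait_runs <- quant |>
    dplyr::filter(.data$protein_id == bait_id,
                  .data$sample_class == "target_ap", .data$norm_defined)
  missing_bait <- setdiff(target_runs$run_id, bait_runs$run_id)
  if (length(missing_bait) > 0) {
    stop(sprintf("bait %s not quantified in target run(s): %s",
                 bait_id, paste(missing_bait, collapse = ", ")), call. = FALSE)
  }

  ratios <- ap_vs_control_ratio(quant)
  ctrl <- ratios[, c("protein_id", "control_value", "control_detected")]

  # per-(protein, target AP) specificity verdicts
  per_ap <- quant |>
    dplyr::filter(.data$sample_class == "target_ap", .data$norm_defined) |>
    dplyr::left_join(ctrl, by = "protein_id") |>
    dplyr::mutate(
      ap_ratio = .data$abundance_norm / .data$control_value,
      pass = specificity_test(.data$ap_ratio, .data$control_detected,
                              quantified = TRUE, config = config)
    )

  ap_matrix <- target_runs |>
    tidyr::expand_grid(protein_id = unique(per_ap$protein_id)) |>
    dplyr::left_join(
      per_ap[, c("run_id", "protein_id", "pass")],
      by = c("run_id", "protein_id")
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      is.na(.data$pass) ~ "not_detected",
      .data$pass ~ "pass",
      TRUE ~ "fail"
    )) |>
    dplyr::select("protein_id", "run_id", "antibody", "detergent", "status")

  bait_by_run <- bait_runs |>
    dplyr::select("run_id", bait_norm = "abundance_norm")

  specific <- dplyr::filter(per_ap, .data$pass)
  calls <- per_ap |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_specific_aps = sum(.data$pass),
      consistent = consistency_test(
        data.frame(antibody = antibody[pass], detergent = detergent[pass]),
        config),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      is_bait = .data$protein_id == bait_id,
      high_confidence = .data$consistent
    ) |>
    dplyr::left_join(ratios, by = "protein_id") |>
    dplyr::arrange(dplyr::desc(.data$high_confidence), dplyr::desc(.data$ratio))

  by_detergent <- specific |>
    dplyr::left_join(bait_by_run, by = "run_id") |>
    dplyr::group_by(.data$protein_id, .data$detergent) |>
    dplyr::summarise(
      ratio_to_bait = stats::median(.data$abundance_norm / .data$bait_norm),
      n_specific_antibodies = dplyr::n_distinct(.data$antibody),
      .groups = "drop"
    )
  by_detergent$abundance_class <- suppressWarnings(
    classify_relative_abundance(by_detergent$ratio_to_bait))

  structure(list(calls = calls, by_detergent = by_detergent,
                 ap_matrix = ap_matrix, config = config, bait_id = bait_id),
            class = "interactor_calls")
}

#' @export
print.interactor_calls <- function(x, ...) {
  hc <- dplyr::filter(x$calls, .data$high_confidence, !.data$is_bait)
  cat(sprintf(
    "<interactor_calls> bait %s; %d proteins evaluated; %d high-confidence partner(s)\n",
    x$bait_id, nrow(x$calls), nrow(hc)))
  if (nrow(hc) > 0) print(utils::head(hc, 10))
  invisible(x)
}

#' High-confidence partners of an interactor-calling result
#'
#' @param x An `interactor_calls` object.
#' @param include_bait Keep the bait itself (default `FALSE`).
#' @return Character vector of protein accessions.
#' @export
high_confidence_partners <- function(x, include_bait = FALSE) {
  stopifnot(inherits(x, "interactor_calls"))
  hc <- dplyr::filter(x$calls, .data$high_confidence)
  if (!include_bait) hc <- dplyr::filter(hc, !.data$is_bait)
  sort(hc$protein_id)
}

#' @export
tidy.interactor_calls <- function(x, ...) {
  x$calls |>
    dplyr::left_join(x$by_detergent, by = "protein_id") |>
    tibble::as_tibble()
}

#' @export
glance.interactor_calls <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$calls),
    n_high_confidence = sum(x$calls$high_confidence & !x$calls$is_bait),
    specificity_fold = x$config$specificity_fold,
    min_antibodies = x$config$min_antibodies
  )
}

#' Purification-matrix heat map of interactor calls
#'
#' Tile plot of the protein-by-purification verdict matrix (pass / fail /
#' not detected), restricted by default to high-confidence partners plus
#' the bait.
#'
#' @param object An `interactor_calls` object.
#' @param proteins Optional accessions to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interactor_calls <- function(object, proteins = NULL, ...) {
  if (is.null(proteins)) {
    proteins <- union(object$bait_id, high_confidence_partners(object))
  }
  dat <- dplyr::filter(object$ap_matrix, .data$protein_id %in% proteins) |>
    dplyr::mutate(ap = paste(.data$antibody, .data$detergent, sep = "\n"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ap, y = .data$protein_id,
                                    fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(
      pass = "#1b7837", fail = "#d73027", not_detected = "grey85")) +
    ggplot2::labs(x = "purification (antibody / detergent)", y = NULL,
                  fill = "specificity",
                  title = "Specific co-purification across purifications") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}
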
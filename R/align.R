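#' Matching tolerances for peak-volume assignment
#'
#' The MS1 matching windows: features are assigned to identified peptides
#' when they agree within `rt_window` minutes of elution time and
#' `ppm_window` ppm of m/z. The wide window is used only for the preliminary
#' m/z-offset estimate, before recalibration.
#'
#' @param rt_window Retention-time window in minutes (default 1.0).
#' @param ppm_window Post-recalibration m/z window in ppm (default 3.0).
#' @param wide_ppm_window Preliminary window for offset estimation (default 50).
#' @return A list of class `match_tolerances`.
#' @export
match_tolerances <- function(rt_window = 1.0, ppm_window = 3.0,
                             wide_ppm_window = 50.0) {
  stopifnot(rt_window > 0, ppm_window > 0, wide_ppm_window > 0)
  if (ppm_window > wide_ppm_window) {
    stop("ppm_window must not exceed wide_ppm_window", call. = FALSE)
  }
  structure(list(rt_window = rt_window, ppm_window = ppm_window,
                 wide_ppm_window = wide_ppm_window),
            class = "match_tolerances")
}

#' Estimate a run's constant m/z offset
#'
#' The median signed ppm error of all features matched (within the wide ppm
#' window) to reference peptides with known theoretical m/z. With no library
#' given, the features' own identification-derived theoretical m/z values
#' are used.
#'
#' @param run A single-run feature tibble.
#' @param library Optional tibble `peptide_seq`, `charge`, `mz_theoretical`.
#' @param wide_ppm_window Matching window in ppm.
#' @param min_matches Minimum number of matched peptides required.
#' @return Median offset in ppm (scalar).
#' @export
estimate_mz_offset <- function(run, library = NULL, wide_ppm_window = 50,
                               min_matches = 20) {
  if (is.null(library)) {
    matched <- dplyr::transmute(
      run, ppm = ppm_error(.data$mz_observed, .data$mz_theoretical))
  } else {
    matched <- run |>
      dplyr::inner_join(
        dplyr::distinct(library[, c("peptide_seq", "charge", "mz_theoretical")]),
        by = c("peptide_seq", "charge"), suffix = c("", "_lib")
      ) |>
      dplyr::transmute(ppm = ppm_error(.data$mz_observed, .data$mz_theoretical_lib))
  }
  matched <- dplyr::filter(matched, abs(.data$ppm) <= wide_ppm_window)
  if (nrow(matched) < min_matches) {
    stop(sprintf(
      "insufficient anchors for m/z offset estimation: %d matches (< %d)",
      nrow(matched), min_matches), call. = FALSE)
  }
  stats::median(matched$ppm)
}

#' Remove a constant m/z offset from a run
#'
#' Divides observed m/z by `1 + offset_ppm * 1e-6`, so that re-estimating
#' the offset on the result gives ~0.
#'
#' @param run A single-run (or multi-run) feature tibble.
#' @param offset_ppm Offset in ppm as returned by [estimate_mz_offset()].
#' @return The tibble with recalibrated `mz_observed`.
#' @export
recalibrate_mz <- function(run, offset_ppm) {
  stopifnot(is.finite(offset_ppm))
  dplyr::mutate(run, mz_observed = .data$mz_observed / (1 + offset_ppm * 1e-6))
}

#' Estimate and remove per-run m/z offsets across a study
#'
#' @param study Multi-run feature tibble.
#' @inheritParams estimate_mz_offset
#' @return A list: `study` (recalibrated) and `offsets` (tibble `run_id`,
#'   `offset_ppm`).
#' @export
recalibrate_study <- function(study, library = NULL, wide_ppm_window = 50,
                              min_matches = 20) {
  parts <- split(study, study$run_id)
  offsets <- purrr::map_dbl(parts, estimate_mz_offset, library = library,
                            wide_ppm_window = wide_ppm_window,
                            min_matches = min_matches)
  out <- purrr::imap_dfr(parts, function(run, rid)
    recalibrate_mz(run, offsets[[rid]]))
  list(study = dplyr::arrange(out, .data$run_id),
       offsets = tibble::tibble(run_id = names(offsets),
                                offset_ppm = unname(offsets)))
}

#' Reference elution times across runs
#'
#' For every (peptide, charge) the median retention time over all runs in
#' which it was observed; the dynamic reference the per-run warps are fitted
#' against. A peptide seen in a single run contributes its own time.
#'
#' @param study Multi-run feature tibble (>= 2 runs).
#' @return Tibble `peptide_seq`, `charge`, `rt_ref`, `n_runs`.
#' @export
compute_reference_times <- function(study) {
  if (dplyr::n_distinct(study$run_id) < 2) {
    stop("compute_reference_times() needs >= 2 runs", call. = FALSE)
  }
  ref <- study |>
    dplyr::group_by(.data$peptide_seq, .data$charge) |>
    dplyr::summarise(rt_ref = stats::median(.data$rt),
                     n_runs = dplyr::n_distinct(.data$run_id),
                     .groups = "drop")
  if (all(ref$n_runs < 2)) {
    warning("no peptide shared between runs; returning empty reference",
            call. = FALSE)
    return(ref[0, ])
  }
  ref
}

#' Fit a retention-time warp for one run
#'
#' Robust local (LOESS) regression of reference elution time on the run's
#' observed elution time over shared peptide anchors, followed by an
#' isotonic repair so the warp never reverses elution order. Evaluated by
#' linear interpolation between fitted anchor points, extended with unit
#' slope beyond the anchored range.
#'
#' @param run Single-run feature tibble.
#' @param reference Tibble `peptide_seq`, `charge`, `rt_ref` (from
#'   [compute_reference_times()]).
#' @param span LOESS bandwidth fraction.
#' @param iterations Robustifying reweighting passes (0 = plain least
#'   squares).
#' @param min_anchors Minimum shared anchors required.
#' @return An object of class `warp_model`.
#' @export
fit_warp <- function(run, reference, span = 0.3, iterations = 2,
                     min_anchors = 30) {
  anchors <- run |>
    dplyr::inner_join(reference[, c("peptide_seq", "charge", "rt_ref")],
                      by = c("peptide_seq", "charge")) |>
    dplyr::transmute(rt_run = .data$rt, rt_ref = .data$rt_ref)
  if (nrow(anchors) < min_anchors) {
    stop(sprintf("insufficient anchors for warp fit: %d (< %d)%s",
                 nrow(anchors), min_anchors,
                 if ("run_id" %in% names(run) && nrow(run) > 0)
                   sprintf(" in run %s", run$run_id[1]) else ""),
         call. = FALSE)
  }
  if (stats::sd(anchors$rt_run) < 1e-8) {
    stop("degenerate anchors: run retention times are constant", call. = FALSE)
  }
  fit <- stats::loess(
    rt_ref ~ rt_run, data = anchors, span = span, degree = 2,
    family = if (iterations > 0) "symmetric" else "gaussian",
    control = stats::loess.control(surface = "direct",
                                   iterations = max(1, iterations + 1))
  )
  ord <- order(anchors$rt_run)
  x <- anchors$rt_run[ord]
  yhat <- stats::predict(fit, newdata = data.frame(rt_run = x))
  # collapse duplicate x for interpolation; isotonic repair of the curve
  grid <- tibble::tibble(x = x, y = yhat) |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  iso <- stats::isoreg(grid$x, grid$y)
  model <- structure(
    list(anchor_times = grid$x, warped_times = iso$yf,
         span = span, iterations = iterations,
         n_anchors = nrow(anchors), anchors = anchors),
    class = "warp_model"
  )
  model$residual_mad <- stats::mad(
    anchors$rt_ref - predict(model, anchors$rt_run))
  model
}

#' Evaluate a fitted warp at new times
#'
#' @param object A `warp_model`.
#' @param newdata Numeric vector of run retention times (minutes).
#' @param ... Unused.
#' @return Warped (reference-scale) times.
#' @export
predict.warp_model <- function(object, newdata, ...) {
  x <- object$anchor_times
  y <- object$warped_times
  out <- stats::approx(x, y, xout = newdata, rule = 2, ties = "ordered")$y
  # unit-slope extension beyond the anchored range
  lo <- newdata < x[1]
  hi <- newdata > x[length(x)]
  out[lo] <- y[1] + (newdata[lo] - x[1])
  out[hi] <- y[length(y)] + (newdata[hi] - x[length(x)])
  out
}

#' @export
print.warp_model <- function(x, ...) {
  cat(sprintf(
    "<warp_model> %d anchors over [%.2f, %.2f] min; span %.2f, %d robust passes; residual MAD %.4f min\n",
    x$n_anchors, min(x$anchor_times), max(x$anchor_times),
    x$span, x$iterations, x$residual_mad))
  invisible(x)
}

#' @export
tidy.warp_model <- function(x, ...) {
  tibble::tibble(anchor_time = x$anchor_times, warped_time = x$warped_times)
}

#' @export
glance.warp_model <- function(x, ...) {
  tibble::tibble(n_anchors = x$n_anchors, span = x$span,
                 iterations = x$iterations, residual_mad = x$residual_mad)
}

#' @export
autoplot.warp_model <- function(object, ...) {
  ggplot2::ggplot(object$anchors,
                  ggplot2::aes(x = .data$rt_run, y = .data$rt_ref - .data$rt_run)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_line(
      data = tidy.warp_model(object),
      ggplot2::aes(x = .data$anchor_time,
                   y = .data$warped_time - .data$anchor_time),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(x = "run retention time (min)",
                  y = "shift to reference (min)",
                  title = "Retention-time warp") +
    ggplot2::theme_minimal()
}

#' Align all runs of a study to a dynamic reference
#'
#' Alternates between recomputing reference times (median elution time per
#' peptide across runs) and refitting per-run warps, for `rounds` rounds.
#' Per-run residual MAD is reported per round and is expected to be
#' non-increasing.
#'
#' @param study Multi-run feature tibble.
#' @param span,iterations,min_anchors Passed to [fit_warp()].
#' @param rounds Alternation rounds (default 2).
#' @return A list: `study` (aligned), `warps` (per-run `warp_model`s of the
#'   final round), `diagnostics` (tibble `run_id`, `round`, `n_anchors`,
#'   `residual_mad`).
#' @export
align_study <- function(study, span = 0.3, iterations = 2, rounds = 2,
                        min_anchors = 30) {
  run_ids <- unique(study$run_id)
  if (length(run_ids) < 2) {
    warning("single-run study: nothing to align", call. = FALSE)
    return(list(study = study, warps = list(),
                diagnostics = tibble::tibble(run_id = character(),
                                             round = integer(),
                                             n_anchors = integer(),
                                             residual_mad = numeric())))
  }
  aligned <- study
  diagnostics <- list()
  warps <- list()
  for (r in seq_len(rounds)) {
    reference <- compute_reference_times(aligned)
    parts <- split(aligned, aligned$run_id)
    for (rid in names(parts)) {
      w <- tryCatch(
        fit_warp(parts[[rid]], reference, span = span,
                 iterations = iterations, min_anchors = min_anchors),
        error = function(e) stop(sprintf("alignment failed for run %s: %s",
                                         rid, conditionMessage(e)),
                                 call. = FALSE)
      )
      parts[[rid]]$rt <- predict(w, parts[[rid]]$rt)
      warps[[rid]] <- w
      diagnostics[[length(diagnostics) + 1]] <- tibble::tibble(
        run_id = rid, round = r, n_anchors = w$n_anchors,
        residual_mad = w$residual_mad)
    }
    aligned <- dplyr::bind_rows(parts)
  }
  list(study = dplyr::arrange(aligned, .data$run_id),
       warps = warps,
       diagnostics = dplyr::bind_rows(diagnostics))
}

# Windowed nearest-match assignment for one charge stratum, via sorted
# binary search on library m/z.
assign_charge_stratum <- function(feat, lib, tolerances) {
  lib <- dplyr::arrange(lib, .data$mz_theoretical)
  w <- tolerances$ppm_window * 1e-6
  lo <- findInterval(feat$mz_observed * (1 - w), lib$mz_theoretical) + 1L
  hi <- findInterval(feat$mz_observed * (1 + w), lib$mz_theoretical)
  n_cand <- pmax(0L, hi - lo + 1L)
  if (sum(n_cand) == 0) return(NULL)
  fi <- rep.int(seq_len(nrow(feat)), n_cand)
  li <- unlist(lapply(which(n_cand > 0), function(i) lo[i]:hi[i]),
               use.names = FALSE)
  cand <- tibble::tibble(
    feature_idx = fi,
    lib_idx = li,
    dppm = abs(ppm_error(feat$mz_observed[fi], lib$mz_theoretical[li])),
    drt = abs(feat$rt[fi] - lib$rt_ref[li])
  ) |>
    dplyr::filter(.data$dppm <= tolerances$ppm_window,
                  .data$drt <= tolerances$rt_window)
  if (nrow(cand) == 0) return(NULL)
  # deterministic tie-break: smallest |ppm|, then smallest |rt|, then
  # lexicographic peptide
  cand |>
    dplyr::mutate(peptide_seq = lib$peptide_seq[.data$lib_idx]) |>
    dplyr::arrange(.data$feature_idx, .data$dppm, .data$drt, .data$peptide_seq) |>
    dplyr::distinct(.data$feature_idx, .keep_all = TRUE) |>
    dplyr::mutate(
      protein_id = lib$protein_id[.data$lib_idx],
      charge = lib$charge[.data$lib_idx],
      mz_theoretical = lib$mz_theoretical[.data$lib_idx],
      rt_ref = lib$rt_ref[.data$lib_idx],
      pv = feat$pv[.data$feature_idx],
      mz_observed = feat$mz_observed[.data$feature_idx],
      rt_observed = feat$rt[.data$feature_idx]
    )
}

#' Assign peak volumes to identified peptides
#'
#' Matches every MS1 feature of an aligned run against a library of
#' identified peptides (theoretical m/z plus reference elution time). A
#' feature is assigned when it lies within the ppm and retention-time
#' windows of a library peptide; ambiguous features go to the candidate with
#' the smaller |ppm| error, ties broken by smaller |RT| difference and then
#' lexicographic peptide order, so assignment is deterministic. Each feature
#' is assigned at most once; peak volumes of features assigned to the same
#' (peptide, charge) are summed.
#'
#' @param run Aligned single-run feature tibble.
#' @param library Tibble `protein_id`, `peptide_seq`, `charge`,
#'   `mz_theoretical`, `rt_ref`.
#' @param tolerances A [match_tolerances()] object.
#' @return A list: `assigned` (one row per matched (peptide, charge) with
#'   summed `pv`) and `n_unassigned` (features matching no library peptide).
#' @export
assign_pvs <- function(run, library, tolerances = match_tolerances()) {
  stopifnot(inherits(tolerances, "match_tolerances"))
  meta <- if (nrow(run) > 0) run[1, intersect(META_FIELDS, names(run))] else NULL
  hits <- purrr::map_dfr(sort(unique(run$charge)), function(z) {
    feat <- dplyr::filter(run, .data$charge == z)
    lib <- dplyr::filter(library, .data$charge == z)
    if (nrow(feat) == 0 || nrow(lib) == 0) return(NULL)
    assign_charge_stratum(feat, lib, tolerances)
  })
  n_unassigned <- nrow(run) - nrow(hits)
  if (nrow(hits) == 0) {
    return(list(assigned = empty_feature_tibble(), n_unassigned = nrow(run)))
  }
  assigned <- hits |>
    dplyr::group_by(.data$protein_id, .data$peptide_seq, .data$charge) |>
    dplyr::summarise(
      mz_theoretical = .data$mz_theoretical[1],
      mz_observed = stats::median(.data$mz_observed),
      rt = .data$rt_ref[1],
      pv = sum(.data$pv),
      n_features = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(meta) && ncol(meta) > 0) {
    assigned <- dplyr::bind_cols(meta[rep(1, nrow(assigned)), ], assigned)
  }
  list(assigned = assigned, n_unassigned = n_unassigned)
}

#' Assign peak volumes across all runs of an aligned study
#'
#' @param study Aligned multi-run feature tibble.
#' @inheritParams assign_pvs
#' @return A list: `assigned` (stacked tibble) and `unassigned` (tibble
#'   `run_id`, `n_unassigned`).
#' @export
assign_study <- function(study, library, tolerances = match_tolerances()) {
  parts <- split(study, study$run_id)
  res <- purrr::imap(parts, function(run, rid)
    assign_pvs(run, library, tolerances))
  list(
    assigned = purrr::map_dfr(res, "assigned"),
    unassigned = tibble::tibble(
      run_id = names(res),
      n_unassigned = purrr::map_int(res, "n_unassigned"))
  )
}

#' Build a peptide library from an aligned study
#'
#' The identified peptides of the study itself, with theoretical m/z from
#' identification and reference elution times recomputed on the aligned
#' time base.
#'
#' @param study Aligned multi-run feature tibble.
#' @return Tibble `protein_id`, `peptide_seq`, `charge`, `mz_theoretical`,
#'   `rt_ref`.
#' @export
build_peptide_library <- function(study) {
  study |>
    dplyr::group_by(.data$protein_id, .data$peptide_seq, .data$charge) |>
    dplyr::summarise(mz_theoretical = .data$mz_theoretical[1],
                     rt_ref = stats::median(.data$rt), .groups = "drop")
}
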
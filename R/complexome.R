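#' Smooth a migration profile by sliding average
#'
#' Centred moving average over gel slices (default window 5). At the
#' profile edges the window truncates to the available slices, so the
#' output has the same length as the input and stays within its range.
#'
#' @param values Numeric vector of per-slice peak volumes (or a long
#'   profile tibble; see [smooth_profiles()]).
#' @param window Odd window width, `1 <= window <= length(values)`.
#' @return Smoothed numeric vector.
#' @export
smooth_profile <- function(values, window = 5) {
  stopifnot(is.numeric(values))
  if (window %% 2 == 0 || window < 1 || window > length(values)) {
    stop("window must be odd, >= 1 and no longer than the profile",
         call. = FALSE)
  }
  if (window == 1) return(values)
  as.numeric(zoo::rollapply(values, width = window, FUN = mean,
                            partial = TRUE, align = "center"))
}

#' Smooth all profiles of a slice bundle
#'
#' @param profiles Long tibble `protein_id`, `slice`, `pv`.
#' @param window Odd window width.
#' @return Tibble of the same shape with smoothed `pv`.
#' @export
smooth_profiles <- function(profiles, window = 5) {
  stopifnot(all(c("protein_id", "slice", "pv") %in% names(profiles)))
  profiles |>
    dplyr::arrange(.data$protein_id, .data$slice) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(pv = smooth_profile(.data$pv, window)) |>
    dplyr::ungroup()
}

#' Fit the slice-to-mass calibration from marker complexes
#'
#' Least-squares fit of a four-parameter logistic
#' `log10(mass) = d + (a - d) / (1 + exp((slice - s0)/b))`
#' to the observed peak slices of marker complexes of known mass. The fit
#' must be strictly monotone (mass decreasing with slice) over the marker
#' range; markers must themselves migrate in mass order.
#'
#' @param markers Tibble with columns `peak_slice` and `mass_kda`
#'   (optionally `protein_id`); >= 4 markers spanning >= 1 decade.
#' @return An object of class `calibration_model` with elements `a`, `d`,
#'   `s0`, `b`, `fit_residual_mad` (log10 units), `valid_slice_range` and
#'   the marker table with fitted values.
#' @export
fit_calibration <- function(markers) {
  stopifnot(all(c("peak_slice", "mass_kda") %in% names(markers)))
  if (nrow(markers) < 4) {
    stop("calibration needs >= 4 markers", call. = FALSE)
  }
  if (diff(range(log10(markers$mass_kda))) < 1) {
    stop("markers must span at least one decade of mass", call. = FALSE)
  }
  ord <- order(markers$peak_slice)
  m_sorted <- markers[ord, ]
  viol <- which(diff(m_sorted$mass_kda) >= 0)
  if (length(viol) > 0) {
    ids <- if ("protein_id" %in% names(m_sorted)) {
      unique(c(m_sorted$protein_id[viol], m_sorted$protein_id[viol + 1]))
    } else {
      paste("marker", unique(c(viol, viol + 1)))
    }
    stop(sprintf("marker masses do not decrease with slice: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }

  dat <- data.frame(s = markers$peak_slice, y = log10(markers$mass_kda))
  start <- list(
    a = max(dat$y) + 0.2, d = min(dat$y) - 0.2,
    s0 = stats::median(dat$s), b = diff(range(dat$s)) / 4
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + exp((s - s0) / b)),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop(sprintf(
      "calibration fit failed to converge: %s", conditionMessage(e)),
      call. = FALSE)
  )
  p <- as.list(stats::coef(fit))
  if (!(p$b > 0 && p$a > p$d)) {
    stop(sprintf(
      "calibration fit is not monotone decreasing (a=%.3f, d=%.3f, b=%.3f)",
      p$a, p$d, p$b), call. = FALSE)
  }
  resid <- dat$y - stats::predict(fit)
  model <- structure(
    list(a = p$a, d = p$d, s0 = p$s0, b = p$b,
         fit_residual_mad = stats::mad(resid, center = 0),
         valid_slice_range = range(markers$peak_slice),
         markers = dplyr::mutate(tibble::as_tibble(markers),
                                 log10_mass = dat$y,
                                 .fitted = stats::predict(fit),
                                 .resid = resid)),
    class = "calibration_model"
  )
  model
}

#' Convert gel slices to apparent complex masses
#'
#' Evaluates the fitted logistic calibration; strictly decreasing in slice.
#' Slices outside the marker-anchored range are extrapolations and trigger
#' a warning.
#'
#' @param slice Numeric (possibly fractional) slice indices.
#' @param model A `calibration_model`.
#' @return Apparent masses in kDa.
#' @export
slice_to_mass <- function(slice, model) {
  stopifnot(inherits(model, "calibration_model"))
  out_of_range <- slice < model$valid_slice_range[1] |
    slice > model$valid_slice_range[2]
  if (any(out_of_range)) {
    warning(sprintf(
      "%d slice value(s) outside the marker-calibrated range [%g, %g]; extrapolating",
      sum(out_of_range), model$valid_slice_range[1], model$valid_slice_range[2]),
      call. = FALSE)
  }
  10^(model$d + (model$a - model$d) / (1 + exp((slice - model$s0) / model$b)))
}

#' Convert apparent masses to gel slices
#'
#' Analytic inverse of [slice_to_mass()]; defined for masses strictly
#' between the calibration asymptotes.
#'
#' @param mass_kda Apparent masses in kDa.
#' @param model A `calibration_model`.
#' @return Fractional slice indices.
#' @export
mass_to_slice <- function(mass_kda, model) {
  stopifnot(inherits(model, "calibration_model"))
  L <- log10(mass_kda)
  if (any(L >= model$a | L <= model$d)) {
    stop("mass outside the invertible calibration range", call. = FALSE)
  }
  model$s0 + model$b * log((model$a - L) / (L - model$d))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> log10(kDa) = %.3f + (%.3f - %.3f)/(1 + exp((s - %.1f)/%.1f))\n",
    x$d, x$a, x$d, x$s0, x$b))
  cat(sprintf("  %d markers over slices [%g, %g]; residual MAD %.4f log10 units\n",
              nrow(x$markers), x$valid_slice_range[1], x$valid_slice_range[2],
              x$fit_residual_mad))
  invisible(x)
}

#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("a", "d", "s0", "b"),
                 estimate = c(x$a, x$d, x$s0, x$b))
}

#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(n_markers = nrow(x$markers),
                 fit_residual_mad = x$fit_residual_mad,
                 slice_min = x$valid_slice_range[1],
                 slice_max = x$valid_slice_range[2])
}

#' @export
autoplot.calibration_model <- function(object, ...) {
  grid <- tibble::tibble(
    slice = seq(object$valid_slice_range[1], object$valid_slice_range[2],
                length.out = 200))
  grid$mass <- suppressWarnings(slice_to_mass(grid$slice, object))
  ggplot2::ggplot(object$markers,
                  ggplot2::aes(x = .data$peak_slice, y = .data$mass_kda)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$slice, y = .data$mass),
                       colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gel slice", y = "complex mass (kDa)",
                  title = "Marker-based slice-to-mass calibration") +
    ggplot2::theme_minimal()
}

#' Detect the migration peak of a smoothed profile
#'
#' The apparent complex mass is read at the profile maximum (ties resolved
#' to the smaller slice, i.e. the larger mass, with a multi-peak warning);
#' the reported mass range spans the outermost slices where the profile
#' reaches at least half its maximum, converted through the calibration.
#' An all-zero profile yields a flagged no-peak row rather than an error.
#'
#' @param values Numeric per-slice peak volumes (smoothed).
#' @param model A `calibration_model`.
#' @param protein_id Optional label carried into the report.
#' @return One-row tibble `protein_id`, `peak_found`, `peak_slice`,
#'   `apparent_mass_kda`, `mass_low_kda`, `mass_high_kda`, `peak_pv`.
#' @export
detect_peak <- function(values, model, protein_id = NA_character_) {
  stopifnot(is.numeric(values), inherits(model, "calibration_model"))
  if (all(values == 0)) {
    return(tibble::tibble(
      protein_id = protein_id, peak_found = FALSE, peak_slice = NA_integer_,
      apparent_mass_kda = NA_real_, mass_low_kda = NA_real_,
      mass_high_kda = NA_real_, peak_pv = NA_real_))
  }
  peak_pv <- max(values)
  maxima <- which(values == peak_pv)
  if (length(maxima) > 1) {
    warning(sprintf("profile%s has %d equal maxima; reporting the smaller slice",
                    if (is.na(protein_id)) "" else paste0(" ", protein_id),
                    length(maxima)), call. = FALSE)
  }
  peak_slice <- maxima[1]
  above <- which(values >= peak_pv / 2)
  lo_slice <- min(above)   # gel top: largest mass
  hi_slice <- max(above)
  masses <- suppressWarnings(
    slice_to_mass(c(peak_slice, lo_slice, hi_slice), model))
  tibble::tibble(
    protein_id = protein_id, peak_found = TRUE,
    peak_slice = as.integer(peak_slice),
    apparent_mass_kda = masses[1],
    mass_low_kda = masses[3],   # deepest slice -> smallest mass
    mass_high_kda = masses[2],
    peak_pv = peak_pv
  )
}

#' Detect peaks for every protein of a profile bundle
#'
#' @param profiles Long tibble `protein_id`, `slice`, `pv` (smoothed).
#' @param model A `calibration_model`.
#' @return Tibble with one [detect_peak()] row per protein.
#' @export
detect_peaks <- function(profiles, model) {
  profiles |>
    dplyr::arrange(.data$protein_id, .data$slice) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_map(~ detect_peak(.x$pv, model, protein_id = .y$protein_id)) |>
    dplyr::bind_rows()
}

#' Complexome-profiling pipeline
#'
#' Smooths all profiles (window 5 by default), locates marker peaks, fits
#' the sigmoidal slice-to-mass calibration, and reports apparent masses
#' and half-maximum mass ranges for every protein.
#'
#' @param profiles Long tibble `protein_id`, `slice`, `pv`.
#' @param markers Tibble `protein_id`, `mass_kda` of calibration markers
#'   present in `profiles`.
#' @param window Smoothing window (odd; default 5).
#' @return A list: `peaks` (per-protein report), `calibration`
#'   (`calibration_model`), `profiles` (smoothed).
#' @export
profile_complexome <- function(profiles, markers, window = 5) {
  stopifnot(all(markers$protein_id %in% profiles$protein_id))
  sm <- smooth_profiles(profiles, window)
  marker_peaks <- sm |>
    dplyr::filter(.data$protein_id %in% markers$protein_id) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(peak_slice = .data$slice[which.max(.data$pv)],
                     .groups = "drop") |>
    dplyr::inner_join(markers, by = "protein_id")
  cal <- fit_calibration(marker_peaks)
  peaks <- detect_peaks(sm, cal)
  list(peaks = peaks, calibration = cal, profiles = sm)
}

#' Abundance-versus-mass profile plot
#'
#' @param profiles Long tibble `protein_id`, `slice`, `pv` (typically
#'   smoothed).
#' @param model Optional `calibration_model`; with it the x axis is the
#'   apparent mass (log scale, decreasing slice), without it the slice
#'   index.
#' @param proteins Optional subset of accessions to draw.
#' @return A ggplot.
#' @export
plot_slice_profiles <- function(profiles, model = NULL, proteins = NULL) {
  dat <- profiles
  if (!is.null(proteins)) {
    dat <- dplyr::filter(dat, .data$protein_id %in% proteins)
  }
  if (!is.null(model)) {
    dat$x <- suppressWarnings(slice_to_mass(dat$slice, model))
    xlab <- "apparent complex mass (kDa)"
  } else {
    dat$x <- dat$slice
    xlab <- "gel slice"
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$pv,
                                         colour = .data$protein_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "peak volume", colour = NULL,
                  title = "Migration profiles") +
    ggplot2::theme_minimal()
  if (!is.null(model)) p <- p + ggplot2::scale_x_log10()
  p
}
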
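#' Configuration for a simulated multi-epitope AP-MS study
#'
#' Defaults emulate the design of a stringent multi-epitope
#' affinity-purification study of a low-abundance membrane bait: several
#' target antibodies and two solubilisation detergents, five
#' target-unrelated-control (TUC) antibody purifications and knockout-line
#' purifications as negative controls, log-normally perturbed peak volumes
#' whose background spans four orders of magnitude, smooth monotone
#' retention-time drift between runs, and a constant ppm-scale m/z offset
#' per run.
#'
#' @param n_background_proteins Number of non-specific background proteins
#'   present in every run.
#' @param n_true_partners Number of planted true interaction partners.
#' @param n_antibodies_target Distinct antibodies targeting the bait.
#' @param n_tuc_controls Distinct target-unrelated control antibodies.
#' @param include_ko_controls Add knockout-line purifications (bait and
#'   partners absent) for each target antibody/detergent.
#' @param detergents Subset of `c("CL-47", "CL-91")`.
#' @param bait_abundance Expected total peak volume of the bait in a target
#'   purification.
#' @param partner_ratio_to_bait Positive per-partner molar ratios to the
#'   bait; default log-spaced from 1 down to 0.03.
#' @param enrichment_fold Fold by which partners are enriched in target
#'   purifications over controls; `Inf` removes partners from controls
#'   entirely (the "not detected in any negative control" regime).
#' @param pv_lognormal_sigma Log-scale (natural log) standard deviation of
#'   multiplicative peak-volume noise.
#' @param dynamic_range_decades Span, in orders of magnitude, of background
#'   protein abundances below the bait.
#' @param rt_drift_amplitude Maximum retention-time drift per run (minutes).
#' @param mz_offset_ppm_range Range the per-run constant m/z offset is drawn
#'   from (ppm).
#' @param mz_noise_ppm Per-feature m/z measurement noise (ppm, sd).
#' @param rt_noise_sd Per-feature retention-time noise (minutes, sd).
#' @param dropout_prob Probability that a peptide feature is missing from a
#'   run.
#' @param peptides_per_protein Integer range `c(min, max)` of observable
#'   peptides per protein.
#' @param rt_range Gradient window (minutes) reference elution times are
#'   drawn from.
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `ap_sim_config`.
#' @export
ap_sim_config <- function(n_background_proteins = 500,
                          n_true_partners = 5,
                          n_antibodies_target = 4,
                          n_tuc_controls = 5,
                          include_ko_controls = TRUE,
                          detergents = c("CL-47", "CL-91"),
                          bait_abundance = 1e7,
                          partner_ratio_to_bait = NULL,
                          enrichment_fold = 100,
                          pv_lognormal_sigma = 0.25,
                          dynamic_range_decades = 4,
                          rt_drift_amplitude = 2,
                          mz_offset_ppm_range = c(-8, 8),
                          mz_noise_ppm = 0.5,
                          rt_noise_sd = 0.05,
                          dropout_prob = 0.1,
                          peptides_per_protein = c(3, 8),
                          rt_range = c(10, 110),
                          seed = 1L) {
  if (is.null(partner_ratio_to_bait) && n_true_partners > 0) {
    partner_ratio_to_bait <- 10^seq(0, -1.5, length.out = n_true_partners)
  }
  cfg <- list(
    n_background_proteins = n_background_proteins,
    n_true_partners = n_true_partners,
    n_antibodies_target = n_antibodies_target,
    n_tuc_controls = n_tuc_controls,
    include_ko_controls = include_ko_controls,
    detergents = detergents,
    bait_abundance = bait_abundance,
    partner_ratio_to_bait = partner_ratio_to_bait,
    enrichment_fold = enrichment_fold,
    pv_lognormal_sigma = pv_lognormal_sigma,
    dynamic_range_decades = dynamic_range_decades,
    rt_drift_amplitude = rt_drift_amplitude,
    mz_offset_ppm_range = mz_offset_ppm_range,
    mz_noise_ppm = mz_noise_ppm,
    rt_noise_sd = rt_noise_sd,
    dropout_prob = dropout_prob,
    peptides_per_protein = peptides_per_protein,
    rt_range = rt_range,
    seed = as.integer(seed)
  )
  validate_ap_sim_config(cfg)
  structure(cfg, class = "ap_sim_config")
}

validate_ap_sim_config <- function(cfg) {
  with(cfg, {
    if (n_background_proteins < 0 || n_true_partners < 0 ||
        n_antibodies_target < 1 || n_tuc_controls < 0) {
      stop("counts in ap_sim_config must be non-negative (>= 1 target antibody)",
           call. = FALSE)
    }
    if (length(detergents) == 0 || !all(detergents %in% DETERGENTS)) {
      stop("detergents must be a non-empty subset of CL-47/CL-91", call. = FALSE)
    }
    if (dropout_prob < 0 || dropout_prob > 1) {
      stop("dropout_prob must be in [0, 1]", call. = FALSE)
    }
    if (n_true_partners > 0 &&
        (length(partner_ratio_to_bait) != n_true_partners ||
         any(partner_ratio_to_bait <= 0))) {
      stop("partner_ratio_to_bait must give one positive ratio per partner",
           call. = FALSE)
    }
    if (enrichment_fold <= 1) stop("enrichment_fold must exceed 1", call. = FALSE)
    if (rt_drift_amplitude < 0) stop("rt_drift_amplitude must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

# Random protein built as a concatenation of tryptic blocks: each block has
# no internal K/R, no leading P, and ends in K or R, so a 0-missed-cleavage
# digest returns exactly these blocks with masses in the observable window.
random_tryptic_protein <- function(n_peptides) {
  interior <- setdiff(AA_ALPHABET, c("K", "R", "P"))
  blocks <- vapply(seq_len(n_peptides), function(i) {
    len <- sample(7:18, 1)
    body <- sample(interior, len, replace = TRUE)
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1))
  }, character(1))
  paste(blocks, collapse = "")
}

# Strictly increasing warp with cubic drift bounded by `amplitude` minutes.
make_rt_warp <- function(amplitude, rt_range) {
  coef <- stats::runif(3, -1, 1)
  poly <- function(u) coef[1] * u + coef[2] * u^2 + coef[3] * u^3
  grid_u <- seq(0, 1, length.out = 201)
  scale0 <- max(abs(poly(grid_u)), 1e-9)
  span <- diff(rt_range)
  drift <- function(t) {
    u <- (t - rt_range[1]) / span
    amplitude * poly(u) / scale0
  }
  # shrink until strictly increasing on a fine grid
  shrink <- 1
  tgrid <- seq(rt_range[1], rt_range[2], length.out = 401)
  repeat {
    w <- tgrid + shrink * drift(tgrid)
    if (all(diff(w) > 1e-4) || shrink < 1e-3) break
    shrink <- shrink * 0.7
  }
  force(shrink)
  function(t) t + shrink * drift(t)
}

#' Simulate a multi-epitope AP-MS study with planted ground truth
#'
#' Generates one feature table per run: target purifications for every
#' (target antibody, detergent) pair, TUC-antibody controls, and optional
#' knockout controls. Bait and partner proteins are present in target runs
#' at configured ratios and reduced by `enrichment_fold` (or absent, if
#' `Inf`) in controls; background proteins appear everywhere with abundances
#' log-uniform over the configured dynamic range. Each run carries a smooth
#' strictly increasing retention-time warp, a constant m/z offset (ppm),
#' per-feature log-normal peak-volume noise, and random feature dropout.
#' Peptides, masses and m/z values come from real in-silico tryptic digests
#' of the generated sequences, so ppm arithmetic is physically meaningful.
#'
#' @param config An [ap_sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{study}{long feature tibble over all runs (the observed data);}
#'     \item{sequences}{tibble of generated protein sequences;}
#'     \item{truth}{ground-truth list: `bait_id`, `partner_ids`,
#'       `partner_true_ratio`, `run_mz_offset_ppm`, `run_warps` (tibble of
#'       time grid/warped time per run), `true_abundance` (expected total PV
#'       per protein and run), and the peptide `library` with reference
#'       retention times.}
#'   }
#' @export
simulate_apms_study <- function(config = ap_sim_config()) {
  stopifnot(inherits(config, "ap_sim_config"))
  withr::with_seed(config$seed, simulate_apms_study_impl(config))
}

simulate_apms_study_impl <- function(cfg) {
  bait_id <- "BAIT0001"
  partner_ids <- if (cfg$n_true_partners > 0) {
    sprintf("PART%04d", seq_len(cfg$n_true_partners))
  } else character(0)
  background_ids <- if (cfg$n_background_proteins > 0) {
    sprintf("BG%06d", seq_len(cfg$n_background_proteins))
  } else character(0)
  ids <- c(bait_id, partner_ids, background_ids)

  npp <- cfg$peptides_per_protein
  n_pep <- c(
    max(npp) * 2L,  # the bait is a large multidomain protein
    sample(npp[1]:npp[2], length(ids) - 1L, replace = TRUE)
  )
  sequences <- tibble::tibble(
    protein_id = ids,
    description = dplyr::case_when(
      ids == bait_id ~ "simulated bait channel",
      ids %in% partner_ids ~ "simulated true partner",
      TRUE ~ "simulated background protein"
    ),
    sequence = vapply(n_pep, random_tryptic_protein, character(1))
  )

  # Peptide library: digest each sequence (0 missed cleavages recovers the
  # generating blocks), fixed charge and ionization weight per peptide.
  library <- purrr::map2_dfr(sequences$protein_id, sequences$sequence,
    function(pid, seq) {
      dig <- tryptic_digest(seq, digest_params(missed_cleavages = 0,
                                               min_mass = 500, max_mass = 4000))
      dplyr::transmute(dig, protein_id = pid, peptide_seq = .data$peptide_seq,
                       mass = .data$mass)
    })
  library$charge <- sample(2:3, nrow(library), replace = TRUE,
                           prob = c(0.7, 0.3))
  library$mz_theoretical <- mz_from_mass(library$mass, library$charge)
  library$rt_ref <- stats::runif(nrow(library), cfg$rt_range[1], cfg$rt_range[2])
  # fixed relative ionization efficiency, normalised within protein
  w <- stats::rlnorm(nrow(library), 0, 0.5)
  library <- library |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(ion_weight = w[dplyr::cur_group_rows()] /
                    sum(w[dplyr::cur_group_rows()])) |>
    dplyr::ungroup()

  # Run design
  runs <- dplyr::bind_rows(
    tidyr::expand_grid(antibody = sprintf("anti-T%d", seq_len(cfg$n_antibodies_target)),
                       detergent = cfg$detergents) |>
      dplyr::mutate(sample_class = "target_ap"),
    if (cfg$n_tuc_controls > 0) {
      tidyr::expand_grid(antibody = sprintf("TUC%d", seq_len(cfg$n_tuc_controls)),
                         detergent = cfg$detergents) |>
        dplyr::mutate(sample_class = "tuc_control")
    },
    if (cfg$include_ko_controls) {
      tidyr::expand_grid(antibody = sprintf("anti-T%d", seq_len(cfg$n_antibodies_target)),
                         detergent = cfg$detergents) |>
        dplyr::mutate(sample_class = "ko_control")
    }
  ) |>
    dplyr::mutate(
      run_id = sprintf("run%02d_%s_%s_%s", dplyr::row_number(),
                       .data$sample_class, .data$antibody, .data$detergent),
      species_source = "simulated"
    )

  # Per-protein base abundance (expected total PV in a target purification)
  base_abundance <- tibble::tibble(
    protein_id = ids,
    base = c(
      cfg$bait_abundance,
      cfg$bait_abundance * cfg$partner_ratio_to_bait,
      10^stats::runif(length(background_ids),
                      log10(cfg$bait_abundance) - cfg$dynamic_range_decades,
                      log10(cfg$bait_abundance))
    )
  )

  # Per-run nuisance parameters
  offsets <- stats::runif(nrow(runs), cfg$mz_offset_ppm_range[1],
                          cfg$mz_offset_ppm_range[2])
  warps <- lapply(seq_len(nrow(runs)),
                  function(i) make_rt_warp(cfg$rt_drift_amplitude, cfg$rt_range))
  names(warps) <- runs$run_id
  run_mz_offset_ppm <- tibble::tibble(run_id = runs$run_id, offset_ppm = offsets)

  # Expected abundance of each protein in each run
  specific <- c(bait_id, partner_ids)
  expected <- tidyr::expand_grid(run_id = runs$run_id, protein_id = ids) |>
    dplyr::left_join(runs[, c("run_id", "sample_class")], by = "run_id") |>
    dplyr::left_join(base_abundance, by = "protein_id") |>
    dplyr::mutate(expected_pv = dplyr::case_when(
      !.data$protein_id %in% specific ~ .data$base,
      .data$sample_class == "target_ap" ~ .data$base,
      .data$protein_id == bait_id ~ 0,          # bait not captured in controls
      is.infinite(cfg$enrichment_fold) ~ 0,      # partners absent from controls
      TRUE ~ .data$base / cfg$enrichment_fold
    )) |>
    dplyr::filter(.data$expected_pv > 0) |>
    dplyr::select("protein_id", "run_id", "expected_pv")

  # Assemble features
  study <- expected |>
    dplyr::inner_join(library, by = "protein_id",
                      relationship = "many-to-many") |>
    dplyr::left_join(runs, by = "run_id")
  n <- nrow(study)
  keep <- stats::runif(n) >= cfg$dropout_prob
  study <- study[keep, ]
  n <- nrow(study)
  warped_rt <- numeric(n)
  for (rid in unique(study$run_id)) {
    idx <- which(study$run_id == rid)
    warped_rt[idx] <- warps[[rid]](study$rt_ref[idx])
  }
  offset_of <- unname(stats::setNames(offsets, runs$run_id)[study$run_id])
  study <- study |>
    dplyr::mutate(
      pv = .data$expected_pv * .data$ion_weight *
        stats::rlnorm(n, 0, cfg$pv_lognormal_sigma),
      rt = pmax(0, warped_rt + stats::rnorm(n, 0, cfg$rt_noise_sd)),
      mz_observed = .data$mz_theoretical *
        (1 + (offset_of + stats::rnorm(n, 0, cfg$mz_noise_ppm)) / 1e6)
    ) |>
    dplyr::select(dplyr::all_of(c(META_FIELDS, FEATURE_COLUMNS))) |>
    dplyr::arrange(.data$run_id, .data$protein_id, .data$peptide_seq)

  run_warps <- purrr::map_dfr(runs$run_id, function(rid) {
    tg <- seq(cfg$rt_range[1], cfg$rt_range[2], length.out = 101)
    tibble::tibble(run_id = rid, t = tg, warped = warps[[rid]](tg))
  })

  list(
    study = study,
    sequences = sequences,
    truth = list(
      bait_id = bait_id,
      partner_ids = partner_ids,
      partner_true_ratio = stats::setNames(
        cfg$partner_ratio_to_bait %||% numeric(0), partner_ids),
      run_design = runs,
      run_mz_offset_ppm = run_mz_offset_ppm,
      run_warps = run_warps,
      true_abundance = expected,
      library = library |>
        dplyr::select("protein_id", "peptide_seq", "charge",
                      "mz_theoretical", "rt_ref", "ion_weight"),
      config = cfg
    )
  )
}

#' Configuration for a simulated blue-native gel slice series
#'
#' Emulates a cryo-sliced blue-native gel lane: each protein complex migrates
#' to the slice implied by its mass through a true logistic slice-to-log10
#' (mass) calibration and leaves a Gaussian peak-volume peak over slices,
#' with multiplicative noise. Slice 1 is the gel top (largest mass). Marker
#' complexes of known mass (defaults follow mitochondrial respiratory-chain
#' complexes and supercomplexes, 130-2800 kDa) are included for calibration.
#'
#' @param n_slices Number of gel slices (default 192).
#' @param complexes Tibble `protein_id`, `mass_kda`, `amplitude`,
#'   `width_slices` of planted non-marker complexes; default plants one bait
#'   complex at 1400 kDa.
#' @param markers Tibble `protein_id`, `mass_kda` of marker complexes.
#' @param calibration Named numeric `c(a, d, s0, b)`: true
#'   `log10(mass) = d + (a - d) / (1 + exp((slice - s0)/b))`.
#' @param noise_sigma Relative (log-normal sdlog) peak-volume noise.
#' @param marker_amplitude,marker_width Peak parameters for markers.
#' @param seed Integer seed.
#' @return A list of class `bn_sim_config`.
#' @export
bn_sim_config <- function(n_slices = 192,
                          complexes = tibble::tibble(
                            protein_id = "BAIT_COMPLEX", mass_kda = 1400,
                            amplitude = 5e6, width_slices = 4
                          ),
                          markers = tibble::tibble(
                            protein_id = sprintf("MARKER%d", 1:7),
                            mass_kda = c(130, 200, 490, 720, 1000, 1700, 2800)
                          ),
                          calibration = c(a = 3.9, d = 1.3, s0 = 90, b = 45),
                          noise_sigma = 0.1,
                          marker_amplitude = 1e7,
                          marker_width = 3,
                          seed = 1L) {
  cfg <- structure(
    list(n_slices = as.integer(n_slices), complexes = complexes,
         markers = markers, calibration = calibration,
         noise_sigma = noise_sigma, marker_amplitude = marker_amplitude,
         marker_width = marker_width, seed = as.integer(seed)),
    class = "bn_sim_config"
  )
  if (cfg$n_slices < 10) stop("n_slices must be >= 10", call. = FALSE)
  if (nrow(cfg$markers) < 4) stop("need >= 4 marker complexes", call. = FALSE)
  if (any(c(cfg$complexes$mass_kda, cfg$markers$mass_kda) <= 0)) {
    stop("complex masses must be positive", call. = FALSE)
  }
  if (!all(c("a", "d", "s0", "b") %in% names(cfg$calibration))) {
    stop("calibration must name a, d, s0, b", call. = FALSE)
  }
  cfg
}

true_mass_to_slice <- function(mass_kda, cal) {
  L <- log10(mass_kda)
  if (any(L >= cal["a"] | L <= cal["d"])) {
    bad <- which(L >= cal["a"] | L <= cal["d"])
    stop(sprintf("complex mass outside calibration range: %s",
                 paste(sprintf("%.0f kDa", mass_kda[bad]), collapse = ", ")),
         call. = FALSE)
  }
  unname(cal["s0"] + cal["b"] * log((cal["a"] - L) / (L - cal["d"])))
}

#' Simulate a complexome-profiling slice series
#'
#' @param config A [bn_sim_config()] object.
#' @return A list with `profiles` (long tibble `protein_id`, `slice`, `pv`),
#'   `markers` (marker table with true peak slices) and `truth` (calibration
#'   parameters and all planted complexes with their true slices).
#' @export
simulate_complexome <- function(config = bn_sim_config()) {
  stopifnot(inherits(config, "bn_sim_config"))
  withr::with_seed(config$seed, {
    cal <- config$calibration
    all_cx <- dplyr::bind_rows(
      dplyr::mutate(config$complexes, is_marker = FALSE),
      dplyr::mutate(config$markers, amplitude = config$marker_amplitude,
                    width_slices = config$marker_width, is_marker = TRUE)
    )
    all_cx$true_slice <- true_mass_to_slice(all_cx$mass_kda, cal)
    slices <- seq_len(config$n_slices)
    profiles <- purrr::map_dfr(seq_len(nrow(all_cx)), function(i) {
      mu <- all_cx$true_slice[i]
      shape <- all_cx$amplitude[i] *
        exp(-(slices - mu)^2 / (2 * all_cx$width_slices[i]^2))
      noise <- stats::rlnorm(length(slices), 0, config$noise_sigma)
      tibble::tibble(protein_id = all_cx$protein_id[i], slice = slices,
                     pv = shape * noise)
    })
    list(
      profiles = profiles,
      markers = dplyr::filter(all_cx, .data$is_marker)[
        , c("protein_id", "mass_kda", "true_slice")],
      truth = list(calibration = cal, complexes = all_cx, config = config)
    )
  })
}

#' Write a named fixture set to disk
#'
#' Materialises a preset simulation as plain-text fixtures: per-run feature
#' tables and a FASTA for AP-MS presets, or a slice matrix plus marker table
#' for the complexome preset, along with YAML ground-truth and manifest
#' files echoing the configuration and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset One of `"paper_like_apms"`, `"null_apms"`,
#'   `"paper_like_complexome"`.
#' @param seed Integer seed used for the preset's generator.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.yaml`).
#' @export
write_fixture_set <- function(out_dir, preset, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (preset %in% c("paper_like_apms", "null_apms")) {
    cfg <- switch(preset,
      paper_like_apms = ap_sim_config(seed = seed),
      null_apms = ap_sim_config(n_true_partners = 0, seed = seed)
    )
    sim <- simulate_apms_study(cfg)
    for (rid in unique(sim$study$run_id)) {
      f <- file.path(out_dir, paste0(rid, ".tsv"))
      write_feature_table(dplyr::filter(sim$study, .data$run_id == rid), f)
      files <- c(files, basename(f))
    }
    write_fasta(sim$sequences, file.path(out_dir, "proteins.fasta"))
    files <- c(files, "proteins.fasta")
    truth <- list(
      bait_id = sim$truth$bait_id,
      partner_ids = as.list(sim$truth$partner_ids),
      partner_true_ratio = as.list(sim$truth$partner_true_ratio),
      run_mz_offset_ppm = stats::setNames(
        as.list(sim$truth$run_mz_offset_ppm$offset_ppm),
        sim$truth$run_mz_offset_ppm$run_id
      )
    )
    yaml::write_yaml(truth, file.path(out_dir, "truth.yaml"))
    files <- c(files, "truth.yaml")
    config_echo <- unclass(cfg)
  } else if (preset == "paper_like_complexome") {
    cfg <- bn_sim_config(seed = seed)
    sim <- simulate_complexome(cfg)
    write_slice_matrix(sim$profiles, file.path(out_dir, "slice_matrix.tsv"))
    utils::write.table(sim$markers[, c("protein_id", "mass_kda")],
                       file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      list(calibration = as.list(sim$truth$calibration),
           complexes = lapply(seq_len(nrow(sim$truth$complexes)), function(i)
             as.list(sim$truth$complexes[i, c("protein_id", "mass_kda",
                                              "true_slice")]))),
      file.path(out_dir, "truth.yaml")
    )
    files <- c("slice_matrix.tsv", "markers.tsv", "truth.yaml")
    config_echo <- unclass(cfg)
    config_echo$complexes <- as.list(as.data.frame(cfg$complexes))
    config_echo$markers <- as.list(as.data.frame(cfg$markers))
    config_echo$calibration <- as.list(cfg$calibration)
  } else {
    stop(sprintf("unknown preset %s", sQuote(preset)), call. = FALSE)
  }
  manifest <- list(preset = preset, seed = as.integer(seed),
                   files = as.list(sort(files)),
                   config = rapply(config_echo, function(x)
                     if (is.numeric(x) || is.character(x) || is.logical(x))
                       as.vector(x) else x, how = "replace"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
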
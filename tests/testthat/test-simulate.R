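test_that("the AP-MS generator is deterministic under a fixed seed", {
  cfg <- ap_sim_config(n_background_proteins = 20, seed = 5)
  a <- simulate_apms_study(cfg)
  b <- simulate_apms_study(cfg)
  expect_identical(a$study, b$study)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth$run_mz_offset_ppm, b$truth$run_mz_offset_ppm)
})

test_that("a null design plants no partners", {
  sim <- simulate_apms_study(ap_sim_config(
    n_background_proteins = 20, n_true_partners = 0, seed = 6))
  expect_length(sim$truth$partner_ids, 0)
  expect_false(any(grepl("^PART", sim$study$protein_id)))
})

test_that("planted partner enrichment is recoverable from peak volumes", {
  sim <- small_sim()
  cfg <- sim$truth$config
  # exact at the expected-abundance level ...
  truth_ratio <- sim$truth$true_abundance |>
    dplyr::filter(protein_id %in% sim$truth$partner_ids) |>
    dplyr::left_join(dplyr::distinct(sim$study[, c("run_id", "sample_class")]),
                     by = "run_id") |>
    dplyr::group_by(protein_id, target = sample_class == "target_ap") |>
    dplyr::summarise(pv = mean(expected_pv), .groups = "drop") |>
    tidyr::pivot_wider(names_from = target, values_from = pv)
  expect_true(all(abs(truth_ratio$`TRUE` / truth_ratio$`FALSE` -
                        cfg$enrichment_fold) < 1e-6))
  # ... and within log-normal sampling error at the realized level
  sums <- sim$study |>
    dplyr::filter(protein_id %in% sim$truth$partner_ids) |>
    dplyr::group_by(protein_id, run_id, sample_class) |>
    dplyr::summarise(pv = sum(pv), .groups = "drop") |>
    dplyr::group_by(protein_id, target = sample_class == "target_ap") |>
    dplyr::summarise(pv = mean(pv), .groups = "drop") |>
    tidyr::pivot_wider(names_from = target, values_from = pv)
  realized <- sums$`TRUE` / sums$`FALSE`
  expect_true(all(realized > cfg$enrichment_fold / 2 &
                    realized < cfg$enrichment_fold * 2))
})

test_that("partners vanish from controls when enrichment is infinite", {
  sim <- simulate_apms_study(ap_sim_config(
    n_background_proteins = 10, enrichment_fold = Inf, seed = 8))
  ctl <- dplyr::filter(sim$study, sample_class != "target_ap")
  expect_false(any(ctl$protein_id %in% c(sim$truth$bait_id,
                                         sim$truth$partner_ids)))
})

test_that("retention-time warps are strictly increasing and m/z offsets constant", {
  sim <- small_sim()
  inc <- sim$truth$run_warps |>
    dplyr::group_by(run_id) |>
    dplyr::summarise(ok = all(diff(warped) > 0))
  expect_true(all(inc$ok))
  ppm <- sim$study |>
    dplyr::mutate(ppm = (mz_observed - mz_theoretical) / mz_theoretical * 1e6) |>
    dplyr::group_by(run_id) |>
    dplyr::summarise(med = median(ppm), spread = mad(ppm)) |>
    dplyr::left_join(sim$truth$run_mz_offset_ppm, by = "run_id")
  expect_true(all(abs(ppm$med - ppm$offset_ppm) < 0.3))
  expect_true(all(ppm$spread < 3 * sim$truth$config$mz_noise_ppm))
})

test_that("feature m/z values derive from real digest masses", {
  sim <- small_sim()
  idx <- sample(nrow(sim$study), 20)
  m <- vapply(sim$study$peptide_seq[idx], oracle_peptide_mass, numeric(1))
  z <- sim$study$charge[idx]
  expect_equal(sim$study$mz_theoretical[idx], (m + z * 1.00727646688) / z,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("config invariants are enforced", {
  expect_error(ap_sim_config(detergents = character(0)), "detergents")
  expect_error(ap_sim_config(dropout_prob = 1.5), "dropout_prob")
  expect_error(ap_sim_config(n_true_partners = 2,
                             partner_ratio_to_bait = 1), "partner_ratio")
  expect_error(bn_sim_config(n_slices = 5), "n_slices")
  expect_error(
    bn_sim_config(markers = tibble::tibble(protein_id = c("a", "b", "c"),
                                           mass_kda = c(100, 500, 1000))),
    ">= 4 marker")
})

test_that("noiseless complexes peak exactly at the calibrated slice", {
  cfg <- bn_sim_config(
    complexes = tibble::tibble(protein_id = c("X", "Y"),
                               mass_kda = c(800, 800),
                               amplitude = 1e6, width_slices = 3),
    noise_sigma = 0, seed = 9)
  sim <- simulate_complexome(cfg)
  cal <- cfg$calibration
  expected <- cal[["s0"]] + cal[["b"]] *
    log((cal[["a"]] - log10(800)) / (log10(800) - cal[["d"]]))
  peaks <- sim$profiles |>
    dplyr::filter(protein_id %in% c("X", "Y")) |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(peak = slice[which.max(pv)])
  expect_true(all(abs(peaks$peak - expected) <= 0.5 + 1e-9))
  expect_equal(peaks$peak[1], peaks$peak[2])  # same mass, same center
})

test_that("marker peak slices decrease with marker mass", {
  sim <- simulate_complexome(bn_sim_config(seed = 10))
  m <- dplyr::arrange(sim$markers, mass_kda)
  expect_true(all(diff(m$true_slice) < 0))
  peaks <- sim$profiles |>
    dplyr::filter(protein_id %in% m$protein_id) |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(peak = slice[which.max(pv)]) |>
    dplyr::left_join(m, by = "protein_id") |>
    dplyr::arrange(mass_kda)
  expect_true(all(diff(peaks$peak) < 0))
})

test_that("complex masses outside the calibration range are rejected by name", {
  cfg <- bn_sim_config(seed = 2)
  cfg$complexes <- tibble::tibble(protein_id = "HUGE", mass_kda = 1e5,
                                  amplitude = 1e6, width_slices = 3)
  expect_error(simulate_complexome(cfg), "outside calibration")
})

test_that("fixture sets are reproducible and presets are validated", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_set(d1, "paper_like_complexome", seed = 4)
  m2 <- write_fixture_set(d2, "paper_like_complexome", seed = 4)
  expect_identical(m1, m2)
  expect_identical(readLines(file.path(d1, "slice_matrix.tsv")),
                   readLines(file.path(d2, "slice_matrix.tsv")))
  expect_true(file.exists(file.path(d1, "markers.tsv")))
  expect_true(file.exists(file.path(d1, "truth.yaml")))
  expect_error(write_fixture_set(d1, "nope"), "unknown preset")
})

test_that("a written null AP-MS fixture set lists runs and no partners", {
  d <- withr::local_tempdir()
  m <- write_fixture_set(d, "null_apms", seed = 3)
  truth <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_length(truth$partner_ids, 0)
  run_files <- grep("^run", unlist(m$files), value = TRUE)
  expect_gt(length(run_files), 1)
  expect_equal(nrow(read_feature_table(file.path(d, run_files[1]))) > 0, TRUE)
})
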
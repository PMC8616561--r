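# A run with known offsets/shifts, built from real peptide masses.
shifted_run <- function(n = 40, ppm_shift = 0, rt_shift = 0, seed = 31) {
  set.seed(seed)
  peps <- replicate(n, paste0(random_aa_sequence(9), sample(c("K", "R"), 1)))
  mass <- vapply(peps, oracle_peptide_mass, numeric(1))
  z <- sample(2:3, n, replace = TRUE)
  mz <- (mass + z * 1.00727646688) / z
  make_run(tibble::tibble(
    protein_id = sprintf("P%03d", seq_len(n)), peptide_seq = peps,
    charge = as.integer(z), mz_theoretical = mz,
    mz_observed = mz * (1 + ppm_shift / 1e6),
    rt = seq(10, 100, length.out = n) + rt_shift, pv = 1e5
  ))
}

test_that("a constant m/z shift is recovered exactly as the median offset", {
  run <- shifted_run(ppm_shift = 3)
  expect_equal(estimate_mz_offset(run), 3, tolerance = 1e-9)
  sym <- shifted_run(n = 40)
  sym$mz_observed <- sym$mz_theoretical *
    (1 + rep(c(2, -2), 20) / 1e6)
  expect_equal(estimate_mz_offset(sym), 0, tolerance = 1e-9)
  expect_error(estimate_mz_offset(shifted_run(n = 10)), "insufficient anchors")
})

test_that("recalibration removes the estimated offset and is invertible", {
  run <- shifted_run(ppm_shift = 5)
  expect_identical(recalibrate_mz(run, 0), run)
  rec <- recalibrate_mz(run, estimate_mz_offset(run))
  expect_lt(abs(estimate_mz_offset(rec)), 1e-9)
  # inverse: dividing back out reproduces the original m/z
  fwd <- recalibrate_mz(run, 5)
  back <- dplyr::mutate(fwd, mz_observed = mz_observed * (1 + 5e-6))
  expect_equal(back$mz_observed, run$mz_observed, tolerance = 1e-12)
})

test_that("per-run offsets on simulated data are recovered within 0.3 ppm", {
  sim <- small_sim()
  rec <- recalibrate_study(sim$study)
  cmp <- dplyr::left_join(rec$offsets, sim$truth$run_mz_offset_ppm,
                          by = "run_id")
  expect_true(all(abs(cmp$offset_ppm.x - cmp$offset_ppm.y) < 0.3))
  resid <- purrr::map_dbl(split(rec$study, rec$study$run_id),
                          estimate_mz_offset)
  expect_true(all(abs(resid) < 0.1))
})

test_that("reference times are per-peptide medians, invariant to run order", {
  study <- dplyr::bind_rows(
    make_run(tibble::tibble(protein_id = "P1", peptide_seq = "AAK",
                            charge = 2L, mz_theoretical = 400, mz_observed = 400,
                            rt = 10.0, pv = 1), run_id = "a"),
    make_run(tibble::tibble(protein_id = "P1", peptide_seq = "AAK",
                            charge = 2L, mz_theoretical = 400, mz_observed = 400,
                            rt = 10.2, pv = 1), run_id = "b"),
    make_run(tibble::tibble(protein_id = "P1", peptide_seq = c("AAK", "GGR"),
                            charge = 2L, mz_theoretical = 400, mz_observed = 400,
                            rt = c(10.4, 55), pv = 1), run_id = "c")
  )
  ref <- compute_reference_times(study)
  expect_equal(ref$rt_ref[ref$peptide_seq == "AAK"], 10.2)
  # a peptide seen in one run contributes its own time
  expect_equal(ref$rt_ref[ref$peptide_seq == "GGR"], 55)
  shuffled <- study[sample(nrow(study)), ]
  expect_equal(compute_reference_times(shuffled), ref)
  expect_error(compute_reference_times(study[study$run_id == "a", ]),
               ">= 2 runs")
})

test_that("a study with no shared peptides yields an empty reference", {
  study <- dplyr::bind_rows(
    make_run(tibble::tibble(protein_id = "P1", peptide_seq = "AAK", charge = 2L,
                            mz_theoretical = 400, mz_observed = 400,
                            rt = 10, pv = 1), run_id = "a"),
    make_run(tibble::tibble(protein_id = "P1", peptide_seq = "GGR", charge = 2L,
                            mz_theoretical = 500, mz_observed = 500,
                            rt = 20, pv = 1), run_id = "b")
  )
  expect_warning(ref <- compute_reference_times(study), "no peptide shared")
  expect_equal(nrow(ref), 0)
})

test_that("warp fitting reproduces identity and constant-shift maps", {
  run <- shifted_run(n = 120)
  ref <- tibble::tibble(peptide_seq = run$peptide_seq, charge = run$charge,
                        rt_ref = run$rt)
  w <- fit_warp(run, ref)
  ts <- seq(12, 98, by = 1)
  expect_true(all(abs(predict(w, ts) - ts) < 0.01))
  expect_lt(w$residual_mad, 1e-6)
  # exact +0.5 min shift
  ref2 <- dplyr::mutate(ref, rt_ref = rt_ref + 0.5)
  w2 <- fit_warp(run, ref2)
  mid <- seq(25, 85, by = 1)
  expect_true(all(abs(predict(w2, mid) - (mid + 0.5)) < 0.02))
})

test_that("warp fitting is robust to outliers under smooth monotone drift", {
  set.seed(33)
  n <- 500
  x <- sort(runif(n, 5, 115))
  u <- (x - 5) / 110
  truth <- x + 2 * (u - 1.8 * u^2 + 0.9 * u^3)  # bounded cubic drift
  y <- truth + rnorm(n, 0, 0.02)
  out_idx <- sample(n, 25)  # 5% gross outliers
  y[out_idx] <- y[out_idx] + runif(25, -8, 8)
  peps <- replicate(n, paste0(random_aa_sequence(8), "K"))
  run <- make_run(tibble::tibble(
    protein_id = "P1", peptide_seq = peps, charge = 2L,
    mz_theoretical = 500, mz_observed = 500, rt = x, pv = 1))
  ref <- tibble::tibble(peptide_seq = peps, charge = 2L, rt_ref = y)
  w <- fit_warp(run, ref)
  err <- predict(w, x) - truth
  expect_lt(median(abs(err)), 0.1)
  expect_true(all(diff(w$warped_times) >= 0))  # isotonic repair holds
})

test_that("warp fitting enforces anchor floor and non-degenerate times", {
  run <- shifted_run(n = 10)
  ref <- tibble::tibble(peptide_seq = run$peptide_seq, charge = run$charge,
                        rt_ref = run$rt)
  expect_error(fit_warp(run, ref), "insufficient anchors")
  run2 <- shifted_run(n = 50)
  run2$rt <- 42
  ref2 <- tibble::tibble(peptide_seq = run2$peptide_seq, charge = run2$charge,
                         rt_ref = seq_len(50))
  expect_error(fit_warp(run2, ref2), "degenerate")
})

test_that("aligning a study shrinks drift and recovers true warps", {
  sim <- small_sim()
  aligned <- align_study(sim$study)
  by_round <- aligned$diagnostics |>
    dplyr::group_by(run_id) |>
    dplyr::summarise(non_increasing = all(diff(residual_mad) <= 1e-6))
  expect_true(mean(by_round$non_increasing) > 0.9)
  # aligned retention times sit near the planted reference times
  cmp <- aligned$study |>
    dplyr::inner_join(sim$truth$library,
                      by = c("protein_id", "peptide_seq", "charge"))
  per_run <- cmp |>
    dplyr::group_by(run_id) |>
    dplyr::summarise(offset = median(rt - rt_ref),
                     mae = median(abs(rt - rt_ref - median(rt - rt_ref))))
  expect_true(all(per_run$mae < 0.15))
})

test_that("single-run and identical-run studies align trivially", {
  sim <- small_sim()
  one <- dplyr::filter(sim$study, run_id == sim$study$run_id[1])
  expect_warning(res <- align_study(one), "single-run")
  expect_identical(res$study, one)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, run_id = "copy"))
  res2 <- align_study(two)
  ts <- seq(15, 105, by = 5)
  for (w in res2$warps) expect_true(all(abs(predict(w, ts) - ts) < 0.02))
})

test_that("assignment respects the ppm and retention-time windows", {
  lib <- tibble::tibble(protein_id = "P1", peptide_seq = "AAAAAAAK",
                        charge = 2L, mz_theoretical = 400,
                        rt_ref = 50)
  mk_feat <- function(ppm, drt) make_run(tibble::tibble(
    protein_id = "P1", peptide_seq = "AAAAAAAK", charge = 2L,
    mz_theoretical = 400, mz_observed = 400 * (1 + ppm / 1e6),
    rt = 50 + drt, pv = 7))
  inside <- assign_pvs(mk_feat(2.9, 0.5), lib)
  expect_equal(nrow(inside$assigned), 1)
  expect_equal(inside$n_unassigned, 0)
  outside_ppm <- assign_pvs(mk_feat(4.0, 0.0), lib)
  expect_equal(nrow(outside_ppm$assigned), 0)
  expect_equal(outside_ppm$n_unassigned, 1)
  outside_rt <- assign_pvs(mk_feat(0, 1.2), lib)
  expect_equal(outside_rt$n_unassigned, 1)
})

test_that("ambiguous assignments break ties on ppm, then RT, then peptide", {
  two_pep <- function(mz2, rt2) tibble::tibble(
    protein_id = c("P1", "P2"), peptide_seq = c("AAAAAAK", "CCCCCCK"),
    charge = 2L, mz_theoretical = c(400, mz2), rt_ref = c(49.5, rt2))
  feat <- make_run(tibble::tibble(
    protein_id = "P1", peptide_seq = "AAAAAAK", charge = 2L,
    mz_theoretical = 400, mz_observed = 400 * (1 + 1e-6), rt = 50, pv = 3))
  # equidistant in RT, ppm decides
  r1 <- assign_pvs(feat, two_pep(400 * (1 + 2.4e-6), 50.5))
  expect_equal(r1$assigned$peptide_seq, "AAAAAAK")
  # ppm tie (symmetric), RT decides
  r2 <- assign_pvs(feat, two_pep(400 * (1 + 2e-6), 50.1))
  expect_equal(r2$assigned$peptide_seq, "CCCCCCK")
  # full tie: lexicographic
  r3 <- assign_pvs(feat, two_pep(400, 49.5))
  expect_equal(r3$assigned$peptide_seq, "AAAAAAK")
})

test_that("assignment conserves peak volume and never double-counts", {
  sim <- small_sim()
  aligned <- align_study(recalibrate_study(sim$study)$study)
  lib <- build_peptide_library(aligned$study)
  run1 <- dplyr::filter(aligned$study, run_id == aligned$study$run_id[1])
  res <- assign_pvs(run1, lib)
  expect_lte(sum(res$assigned$pv), sum(run1$pv) + 1e-6)
  expect_equal(sum(res$assigned$n_features) + res$n_unassigned, nrow(run1))
})

test_that("almost all simulated features are assigned to their true peptide", {
  sim <- small_sim()
  rec <- recalibrate_study(sim$study)
  aligned <- align_study(rec$study)
  lib <- build_peptide_library(aligned$study)
  res <- assign_study(aligned$study, lib)
  correct <- aligned$study |>
    dplyr::select(run_id, protein_id, peptide_seq, charge, pv) |>
    dplyr::inner_join(
      res$assigned[, c("run_id", "protein_id", "peptide_seq", "charge",
                       "pv")],
      by = c("run_id", "protein_id", "peptide_seq", "charge"),
      suffix = c("_true", "_assigned"))
  frac <- sum(pmin(correct$pv_true, correct$pv_assigned)) / sum(aligned$study$pv)
  expect_gte(frac, 0.95)
})
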
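# MS trace processing, peak picking, cross-run alignment and FAME
# integration.

test_that("noise gating zeroes almost all of a pure-noise trace", {
  set.seed(3)
  noise <- rnorm(5000)
  out <- smooth_and_denoise(noise, window = 7, k_noise = 3)
  expect_gte(mean(out == 0), 0.99)
})

test_that("smoothing preserves a noiseless peak apex within 2%", {
  x <- seq(-5, 5, length.out = 201)
  peak <- 100 * exp(-x^2 / 0.5)
  out <- smooth_and_denoise(peak, window = 7, k_noise = 0)
  expect_equal(max(out), max(peak), tolerance = 0.02)
  expect_identical(smooth_and_denoise(peak, window = 1, k_noise = 0), peak)
  expect_error(smooth_and_denoise(peak, window = 4), "odd")
})

test_that("peak picking finds apexes with parabolic refinement", {
  tri <- c(rep(0, 10), seq(0, 10, by = 2), seq(8, 0, by = -2), rep(0, 10))
  p <- pick_peaks(tri, k_noise = 0, window = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rt, which.max(tri), tolerance = 1)
  two <- c(rep(0, 8), 0, 5, 10, 5, 0, rep(0, 6), 0, 4, 8, 4, 0, rep(0, 8))
  p2 <- pick_peaks(two, k_noise = 0, window = 1)
  expect_equal(nrow(p2), 2L)
})

test_that("planted peaks in a synthetic run are recovered", {
  design <- tiny_design()
  truth <- truth_manifest(design, attenuation_range = c(1, 1))
  flasks <- simulate_flasks(design, truth)
  run <- synth_ms_run(flasks[1, ], "lcms", truth)
  ref <- compound_table()
  ref <- ref[!is.na(ref$theoretical_mz), ]
  # every reference compound above the floor appears within mass tolerance
  hits <- vapply(ref$theoretical_mz, function(mz) {
    any(abs(run$mz - mz) < 0.01)
  }, logical(1))
  expect_true(all(hits))
  expect_error(synth_ms_run(flasks[1, ], "maldi", truth), "unknown platform")
  # a floor above every amplitude empties the list
  hi <- truth_manifest(design, attenuation_range = c(1, 1),
                       ms_noise_sd = 1e12, n_decoys = 0L)
  expect_equal(nrow(synth_ms_run(flasks[1, ], "lcms", hi)), 0L)
})

test_that("runs differing by a linear RT shift align to one feature each", {
  design <- make_study_design("pA", 4, seed = 5)
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          n_decoys = 0L, mz_error_ppm = 0.5)
  flasks <- simulate_flasks(design, truth)
  runs <- lapply(seq_len(nrow(flasks)), function(i)
    synth_ms_run(flasks[i, ], "lcms", truth))
  fm <- align_runs(runs, mz_tol = 0.005, rt_tol = 0.2)
  ref <- compound_table()
  ref <- ref[!is.na(ref$theoretical_mz), ]
  n_hit <- vapply(ref$theoretical_mz, function(mz) {
    sum(abs(fm_descriptors(fm)$mz - mz) < 0.01)
  }, numeric(1))
  expect_true(all(n_hit == 1))          # exactly one feature per compound
  # cells fully populated for planted compounds
  full <- rowSums(!is.na(fm_values(fm)))
  expect_true(all(full == nrow(flasks)))
})

test_that("alignment degenerate cases behave as specified", {
  design <- tiny_design()
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          n_decoys = 0L)
  flasks <- simulate_flasks(design, truth)
  r1 <- synth_ms_run(flasks[1, ], "lcms", truth)
  # single run: features are its peaks
  fm1 <- align_runs(list(r1))
  expect_equal(nrow(fm_values(fm1)), nrow(r1))
  # zero tolerances: no cross-run matching
  r2 <- synth_ms_run(flasks[2, ], "lcms", truth)
  fm0 <- align_runs(list(r1, r2), mz_tol = 0, rt_tol = 0)
  expect_equal(nrow(fm_values(fm0)), nrow(r1) + nrow(r2))
  expect_error(align_runs(list(r1, r2), mz_tol = -1), "non-negative")
  # mixed platforms refused
  g1 <- synth_ms_run(flasks[1, ], "gcms", truth)
  expect_error(align_runs(list(r1, g1)), "mixed platforms")
})

test_that("feature count is monotone non-increasing in the tolerances", {
  design <- tiny_design()
  truth <- truth_manifest(design, attenuation_range = c(1, 1))
  flasks <- simulate_flasks(design, truth)
  runs <- lapply(seq_len(nrow(flasks)), function(i)
    synth_ms_run(flasks[i, ], "lcms", truth))
  counts <- vapply(c(0.0005, 0.005, 0.05), function(tol) {
    nrow(fm_values(align_runs(runs, mz_tol = tol, rt_tol = 0.2)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("aligning an already-aligned bundle is idempotent", {
  design <- tiny_design()
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          n_decoys = 0L, rt_drift_sd = 0)
  flasks <- simulate_flasks(design, truth)
  runs <- lapply(seq_len(nrow(flasks)), function(i)
    synth_ms_run(flasks[i, ], "lcms", truth))
  fm <- align_runs(runs, mz_tol = 0.005, rt_tol = 0.2)
  # re-express the matrix as per-run peak lists and align again
  again <- lapply(seq_along(runs), function(i) {
    v <- fm_values(fm)[, i]
    keep <- !is.na(v)
    structure(data.frame(mz = fm_descriptors(fm)$mz[keep],
                         rt = fm_descriptors(fm)$rt[keep],
                         intensity = v[keep]),
              run_id = fm_samples(fm)[i], platform = "lcms",
              class = c("peak_list", "data.frame"))
  })
  fm2 <- align_runs(again, mz_tol = 0.005, rt_tol = 0.2)
  expect_equal(nrow(fm_values(fm2)), nrow(fm_values(fm)))
  expect_equal(sort(fm_descriptors(fm2)$mz), sort(fm_descriptors(fm)$mz),
               tolerance = 1e-9)
})

test_that("FAME targets integrate inside their retention windows", {
  design <- tiny_design()
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          n_decoys = 4L, rt_drift_sd = 0)
  flasks <- simulate_flasks(design, truth)
  run <- synth_ms_run(flasks[1, ], "gcms", truth)
  tw <- fame_target_windows()
  ints <- integrate_fame_targets(run, tw)
  c18 <- run$intensity[abs(run$mz - 1800) < 1]
  expect_equal(unname(ints[["C18:0"]]), c18)
  # empty window integrates to zero with a flag
  empty <- integrate_fame_targets(run, data.frame(name = "none",
                                                  lo = 5000, hi = 5010))
  expect_equal(unname(empty[["none"]]), 0)
  expect_equal(attr(empty, "absent"), "none")
  expect_error(integrate_fame_targets(run,
                                      data.frame(name = c("a", "b"),
                                                 lo = c(1, 5),
                                                 hi = c(10, 20))),
               "overlapping")
})
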
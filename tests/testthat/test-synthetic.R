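# The study generator: design enumeration, the cell-number confounder,
# planted effects, reference-line independence, and on-disk bundles.

test_that("the design enumerates passages x treatments x replicates", {
  d <- make_study_design()
  expect_equal(nrow(d), 40L)                       # 5 x 2 x 4
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_setequal(unique(d$treatment), c("TCDD", "DMSO"))
  expect_equal(nrow(make_study_design("p1", 1)), 2L)
  expect_error(make_study_design(character(0)), "non-empty")
  expect_error(make_study_design("p1", 0), "n_replicates")
})

test_that("cell scales center on the configured TCDD ratio", {
  d0 <- make_study_design("pA", 2, seed = 3)
  t0 <- truth_manifest(d0, cell_ratio_tcdd = 1.0, cell_cv = 0)
  expect_true(all(simulate_flasks(d0, t0)$cell_scale == 1))
  # sample-mean oracle at n = 10^4
  big <- make_study_design("pA", 5000L, seed = 3)
  tr <- truth_manifest(big, cell_ratio_tcdd = 0.7, cell_cv = 0.15)
  fl <- simulate_flasks(big, tr)
  expect_equal(mean(fl$cell_scale[fl$treatment == "TCDD"]), 0.7,
               tolerance = 0.01)
  expect_equal(mean(fl$cell_scale[fl$treatment == "DMSO"]), 1,
               tolerance = 0.01)
  # determinism
  expect_identical(simulate_flasks(big, tr), simulate_flasks(big, tr))
  expect_error(truth_manifest(d0, cell_ratio_tcdd = -1), "positive")
})

test_that("noiseless spectra carry the planted ratios exactly", {
  design <- tiny_design(passages = "pA", n_replicates = 1)
  truth <- quiet_truth(design, cell_ratio_tcdd = 1)
  flasks <- simulate_flasks(design, truth)
  tcdd <- flasks[flasks$treatment == "TCDD", ][1, ]
  dmso <- flasks[flasks$treatment == "DMSO", ][1, ]
  sp_t <- process_fid(synth_nmr_fid(tcdd, "apolar", truth), "chcl3")
  sp_d <- process_fid(synth_nmr_fid(dmso, "apolar", truth), "chcl3")
  r <- integrate_region(sp_t, 4.10, 4.32) / integrate_region(sp_d, 4.10, 4.32)
  expect_equal(r, 0.51, tolerance = 0.01)          # triglyceride RTD
  # zero noise, DMSO, cell_scale 1: deterministic template
  dmso$cell_scale <- 1
  f1 <- synth_nmr_fid(dmso, "apolar", truth)
  f2 <- synth_nmr_fid(dmso, "apolar", truth)
  expect_identical(f1$data, f2$data)
  expect_equal(f1$npoints, 16384L)
  expect_error(synth_nmr_fid(dmso, "middle", truth), "unknown fraction")
})

test_that("attenuation exponents damp planted effects per passage", {
  design <- make_study_design(c("pA", "pB"), 1, seed = 6)
  truth <- quiet_truth(design, attenuation_range = c(0.5, 0.5),
                       cell_ratio_tcdd = 1)
  flasks <- simulate_flasks(design, truth)
  tcdd <- flasks[flasks$treatment == "TCDD", ][1, ]
  dmso <- flasks[flasks$treatment == "DMSO", ][1, ]
  sp_t <- process_fid(synth_nmr_fid(tcdd, "apolar", truth), "chcl3")
  sp_d <- process_fid(synth_nmr_fid(dmso, "apolar", truth), "chcl3")
  r <- integrate_region(sp_t, 4.10, 4.32) / integrate_region(sp_d, 4.10, 4.32)
  expect_equal(r, 0.51^0.5, tolerance = 0.01)
})

test_that("the CHCl3 reference is independent of cell number", {
  design <- make_study_design("pA", 20L, seed = 13)
  truth <- truth_manifest(design, cell_cv = 0.3, replicate_cv = 0,
                          ppm_jitter_sd = 0, fid_noise_sd = 0,
                          baseline_amplitude = 0,
                          attenuation_range = c(1, 1))
  flasks <- simulate_flasks(design, truth)
  areas <- vapply(seq_len(nrow(flasks)), function(i) {
    sp <- process_fid(synth_nmr_fid(flasks[i, ], "apolar", truth,
                                    n_points = 4096L),
                      reference = NULL, target_points = 16384L)
    integrate_region(sp, 7.20, 7.32)
  }, numeric(1))
  expect_lt(abs(stats::cor(areas, flasks$cell_scale)), 0.3)
  expect_lt(stats::sd(areas) / mean(areas), 0.05)  # constant within noise
})

test_that("LC-MS runs place compounds at their adduct masses", {
  design <- tiny_design()
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          mz_error_ppm = 1)
  flasks <- simulate_flasks(design, truth)
  run <- synth_ms_run(flasks[1, ], "lcms", truth)
  proline <- adduct_mz(monoisotopic_mass("C5H9NO2"), "M+H")   # 116.0706
  hit <- run$mz[abs(run$mz - proline) < 0.01]
  expect_length(hit, 1L)
  expect_equal(hit, proline, tolerance = 5 * proline * 1e-6)
  # same seed, same run
  expect_identical(synth_ms_run(flasks[1, ], "lcms", truth),
                   synth_ms_run(flasks[1, ], "lcms", truth))
})

test_that("AA and DHA carry no treatment effect per cell", {
  design <- make_study_design("pA", 30L, seed = 17)
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          n_decoys = 0L)
  flasks <- simulate_flasks(design, truth)
  percell <- vapply(seq_len(nrow(flasks)), function(i) {
    run <- synth_ms_run(flasks[i, ], "gcms", truth)
    aa <- run$intensity[abs(run$mz - fame_retention_index(20, 4)) < 2]
    dha <- run$intensity[abs(run$mz - fame_retention_index(22, 6)) < 2]
    (aa + dha) / flasks$cell_scale[i]
  }, numeric(1))
  g <- flasks$treatment
  expect_equal(mean(percell[g == "TCDD"]) / mean(percell[g == "DMSO"]), 1,
               tolerance = 0.1)
})

test_that("study bundles are complete, deterministic and reloadable", {
  cfg <- list(study = list(passages = "pA", n_replicates = 2L, seed = 5L),
              truth = list(n_decoys = 5L))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  generate_study(cfg, out1)
  generate_study(cfg, out2)
  # 4 flasks x 4 data streams + metadata + manifest
  expect_length(list.files(out1, recursive = TRUE), 4L * 4L + 2L)
  m1 <- readLines(file.path(out1, "truth.yaml"))
  m2 <- readLines(file.path(out2, "truth.yaml"))
  expect_identical(m1, m2)
  d1 <- readLines(file.path(out1, "nmr_apolar", "pA_TCDD_r1.dx"))
  d2 <- readLines(file.path(out2, "nmr_apolar", "pA_TCDD_r1.dx"))
  expect_identical(d1, d2)
  # the manifest round-trips losslessly
  truth <- read_truth_manifest(file.path(out1, "truth.yaml"))
  expect_s3_class(truth, "truth_manifest")
  expect_equal(truth$rtd$nmr_apolar[["triglyceride"]], 0.51)
  expect_length(attr(truth, "cell_scale"), 4L)
  # metadata table agrees with the design
  meta <- read.delim(file.path(out1, "metadata.tsv"))
  expect_equal(nrow(meta), 4L)
  expect_setequal(names(meta),
                  c("sample_id", "passage", "treatment", "replicate"))
})
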
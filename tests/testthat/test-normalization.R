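# Internal-standard normalization: region integrals, TS/CHCl3 and PL/CHCl3
# factors, matrix normalization and GC-MS AA+DHA scaling.

rect_spectrum <- function() {
  ppm <- seq(10, -2, length.out = 12001)           # 0.001 ppm grid
  y <- ifelse(ppm >= 3.0 & ppm < 3.1, 1, 0)        # unit-height rectangle
  spectrum1d(ppm, y)
}

test_that("region integration is trapezoidal and additive", {
  sp <- rect_spectrum()
  expect_equal(integrate_region(sp, 3.0, 3.1), 0.1, tolerance = 0.01)
  expect_error(integrate_region(sp, 5, 4), "lo_ppm")
  expect_error(integrate_region(sp, -10, 0), "outside")
  # additivity over disjoint windows covering disjoint signals
  a <- integrate_region(sp, 2.5, 3.05)
  b <- integrate_region(sp, 3.05, 3.5)
  u <- integrate_region(sp, 2.5, 3.5)
  expect_equal(a + b, u, tolerance = 2e-2)  # one grid cell at the junction
})

test_that("TS/CHCl3 scales with lipid amount at fixed CHCl3", {
  design <- tiny_design(passages = "pA", n_replicates = 1)
  flasks1 <- simulate_flasks(design, quiet_truth(design))
  fl <- flasks1[flasks1$treatment == "DMSO", ][1, ]
  truth1 <- quiet_truth(design)
  sp1 <- process_fid(synth_nmr_fid(fl, "apolar", truth1),
                     reference = "chcl3")
  # doubled cells = doubled lipid amplitudes, fixed CHCl3
  fl2 <- fl; fl2$cell_scale <- 2 * fl$cell_scale
  sp2 <- process_fid(synth_nmr_fid(fl2, "apolar", truth1),
                     reference = "chcl3")
  expect_equal(ts_over_chcl3(sp2) / ts_over_chcl3(sp1), 2,
               tolerance = 0.02)
  # all-lipid-zero spectrum: TS -> 0 (CHCl3 alone remains)
  ppm <- seq(10, -2, length.out = 8001)
  chonly <- spectrum1d(ppm, ifelse(abs(ppm - 7.26) < 0.01, 100, 0))
  expect_lt(ts_over_chcl3(chonly), 0.05)
  nochcl3 <- spectrum1d(ppm, ifelse(abs(ppm - 1.3) < 0.01, 100, 0))
  expect_error(ts_over_chcl3(nochcl3), "CHCl3")
})

test_that("PL/CHCl3 tracks cell number and ignores planted effects", {
  design <- tiny_design(passages = "pA", n_replicates = 1)
  truth <- quiet_truth(design)
  flasks <- simulate_flasks(design, truth)
  fl <- flasks[flasks$treatment == "DMSO", ][1, ]
  f1 <- pl_over_chcl3(process_fid(synth_nmr_fid(fl, "apolar", truth),
                                  reference = "chcl3"))
  half <- fl; half$cell_scale <- fl$cell_scale / 2
  f2 <- pl_over_chcl3(process_fid(synth_nmr_fid(half, "apolar", truth),
                                  reference = "chcl3"))
  expect_equal(f2 / f1, 0.5, tolerance = 0.02)
  # invariant to the planted triglyceride effect (PL is untreated)
  truth_tg <- quiet_truth(design, overrides = list(
    nmr_apolar = c(triglyceride = 0.2)))
  tcdd <- flasks[flasks$treatment == "TCDD", ][1, ]
  tcdd$cell_scale <- fl$cell_scale
  f3 <- pl_over_chcl3(process_fid(synth_nmr_fid(tcdd, "apolar", truth_tg),
                                  reference = "chcl3"))
  expect_equal(f3 / f1, 1, tolerance = 0.02)
  # no PL signal: error
  ppm <- seq(10, -2, length.out = 8001)
  nopl <- spectrum1d(ppm, ifelse(abs(ppm - 7.26) < 0.01, 100, 0))
  expect_error(pl_over_chcl3(nopl), "PL")
})

test_that("matrix normalization cancels the cell-number confounder", {
  design <- make_study_design("pA", 4, seed = 12)
  # null metabolite study: every planted effect neutralized
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          cell_ratio_tcdd = 0.7,
                          overrides = list(nmr_apolar = c(
                            triglyceride = 1, cholesterol_ester = 1,
                            acyl_allylic = 1, acyl_olefinic = 1)))
  flasks <- simulate_flasks(design, truth)
  res <- process_nmr_fraction(simulate_nmr_study(flasks, "apolar", truth),
                              "apolar")
  g <- flasks$treatment
  raw <- window_fold_change(res$matrix, 2.72, 2.88, g)
  norm <- normalize_matrix(res$matrix, res$factors)
  cor <- window_fold_change(norm, 2.72, 2.88, g)
  expect_equal(raw, 0.7, tolerance = 0.2)      # confounder visible
  expect_lt(abs(cor - 1), abs(raw - 1))        # and removed
  expect_equal(cor, 1, tolerance = 0.15)
})

test_that("normalization validates factors and pairing", {
  vals <- matrix(c(2, 4, 6, 8), 2, dimnames = list(NULL, c("f1", "f2")))
  fm <- feature_matrix(vals, data.frame(ppm_center = c(1, 2)))
  ident <- normalize_matrix(fm, c(f1 = 1, f2 = 1))
  expect_equal(fm_values(ident), vals)
  expect_error(normalize_matrix(fm, c(f1 = 1)), "factor")
  expect_error(normalize_matrix(fm, c(f1 = 1, f2 = -2)), "positive")
  # explicit pairing maps samples to flasks
  paired <- normalize_matrix(fm, c(A = 2, B = 4),
                             pairing = c(f1 = "A", f2 = "B"))
  expect_equal(fm_values(paired)[, "f2"], vals[, "f2"] / 4)
  expect_error(normalize_matrix(fm, c(A = 2), pairing = c(f1 = "A")),
               "pairing")
  # missing cells stay missing
  vals[1, 2] <- NA
  fmna <- feature_matrix(vals, data.frame(ppm_center = c(1, 2)))
  expect_true(is.na(fm_values(normalize_matrix(fmna,
                                               c(f1 = 2, f2 = 2)))[1, 2]))
})

test_that("GC-MS normalization by AA+DHA recovers planted ratios", {
  design <- make_study_design("pA", 6, seed = 9)
  truth <- truth_manifest(design, attenuation_range = c(1, 1),
                          intensity_cv = 0, rt_drift_sd = 0, n_decoys = 0L)
  flasks <- simulate_flasks(design, truth)
  tw <- fame_target_windows()
  ints <- vapply(seq_len(nrow(flasks)), function(i) {
    integrate_fame_targets(synth_ms_run(flasks[i, ], "gcms", truth), tw)
  }, numeric(nrow(tw)))
  colnames(ints) <- flasks$sample_id
  norm <- gc_normalize(ints)
  g <- flasks$treatment
  fc <- group_fold_change(norm, g)
  names(fc) <- fm_descriptors(norm)$name
  expect_equal(unname(fc["C16:1 (n-6)"]), 0.63, tolerance = 0.02)
  expect_equal(unname(fc["C18:0"]), 1.27, tolerance = 0.02)
  # doubled injection volume leaves the normalized profile unchanged
  ints2 <- ints
  ints2[, 1] <- ints2[, 1] * 2
  norm2 <- gc_normalize(ints2)
  expect_equal(fm_values(norm2)[, 1], fm_values(norm)[, 1])
  # AA+DHA missing: error
  bad <- ints[!rownames(ints) %in% "C20:4 (AA)", ]
  expect_error(gc_normalize(bad), "AA and DHA")
})
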
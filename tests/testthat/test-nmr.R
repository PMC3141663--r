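# NMR processing chain: apodization, zero filling, Fourier transform,
# phasing, baseline, calibration and multi-spectrum alignment.

test_that("squared sine-bell window is anchored at 1 and 0", {
  fid <- fid_record(complex(real = rep(1, 64)), sw = 1000)
  ap <- apodize(fid)
  w <- Re(ap$data)
  expect_equal(w[1], 1)
  expect_equal(w[64], 0)
  i <- 0:63
  expect_equal(w, cos(pi * i / (2 * 63))^2)
  expect_error(apodize(fid_record(complex(real = c(1, 1)), sw = 1)), NA)
})

test_that("zero filling appends zeros and validates the target", {
  fid <- fid_record(complex(real = rnorm(100), imaginary = rnorm(100)),
                    sw = 1000)
  zf <- zero_fill(fid, 256)
  expect_equal(zf$npoints, 256L)
  expect_equal(zf$data[1:100], fid$data)
  expect_true(all(zf$data[101:256] == 0))
  expect_equal(zero_fill(fid, 100)$npoints, 100L)     # identity
  expect_error(zero_fill(fid, 50), "smaller")
  # acquisition-size default: 16 K points fill to 128 K
  big <- fid_record(complex(real = rep(0, 16384), imaginary = rep(0, 16384)),
                    sw = 5000)
  expect_equal(zero_fill(big)$npoints, 131072L)
})

test_that("transform places a pure tone at its ppm and preserves energy", {
  n <- 4096; sw <- 5000; obs <- 400.13
  f <- (7.0 - 5.5) * obs                    # tone at 7.0 ppm
  t <- (seq_len(n) - 1) / sw
  s <- exp(2i * pi * f * t)
  s[1] <- 0                                  # sidestep first-point scaling
  fid <- fid_record(s, sw = sw, obs_freq = obs, ppm_center = 5.5)
  sp <- transform_fid(fid)
  apex <- sp$ppm[which.max(abs(sp$complex_values))]
  expect_lt(abs(apex - 7.0), (sw / obs) / n * 1.5)   # within one grid point
  # Parseval (unnormalized DFT convention)
  expect_equal(sum(Mod(sp$complex_values)^2), n * sum(Mod(s)^2),
               tolerance = 1e-8)
  # all-zero FID stays zero
  z <- transform_fid(fid_record(complex(real = rep(0, 64)), sw = 1000))
  expect_true(all(z$intensity == 0))
})

test_that("auto phasing recovers known dephasing within a degree", {
  design <- tiny_design()
  truth <- quiet_truth(design)
  flasks <- simulate_flasks(design, truth)
  sp <- transform_fid(zero_fill(apodize(
    synth_nmr_fid(flasks[1, ], "apolar", truth, n_points = 4096L)), 16384L))
  phi0 <- 15 * pi / 180
  phi1 <- 10 * pi / 180
  x <- (seq_along(sp$complex_values) - 1) / (length(sp$complex_values) - 1)
  dephased <- sp
  dephased$complex_values <- sp$complex_values * exp(-1i * (phi0 + phi1 * x))
  dephased$intensity <- Re(dephased$complex_values)
  rec <- auto_phase(dephased)
  expect_lt(abs(rec$meta$phi0_deg - 15), 1)
  expect_lt(abs(rec$meta$phi1_deg - 10), 1)
  # an already-phased spectrum is left essentially unchanged
  again <- auto_phase(sp)
  expect_lt(max(abs(again$intensity - sp$intensity)) /
              max(abs(sp$intensity)), 0.01)
  # pure noise: finite result, no error
  noise <- spectrum1d(seq(10, -2, length.out = 256), rnorm(256),
                      complex_values = complex(real = rnorm(256),
                                               imaginary = rnorm(256)))
  expect_true(all(is.finite(auto_phase(noise)$intensity)))
})

test_that("baseline correction removes drift but preserves peaks", {
  n <- 8192
  ppm <- seq(11, -1, length.out = n)
  lorentz <- function(c, g, a) a * g^2 / ((ppm - c)^2 + g^2)
  peaks <- lorentz(7.2, 0.004, 50) + lorentz(3.1, 0.004, 80) +
    lorentz(1.4, 0.004, 30)
  x <- seq(0, 1, length.out = n)
  drift <- 5 + 4 * x - 6 * x^2
  sp <- spectrum1d(ppm, peaks + drift)
  corr <- baseline_correct(sp)
  resid <- corr$intensity - peaks
  expect_lt(sqrt(mean(resid^2)) / sqrt(mean(drift^2)), 0.02)
  # apex heights preserved within 5%
  for (c in c(7.2, 3.1, 1.4)) {
    i <- which(abs(ppm - c) < 0.02)
    expect_equal(max(corr$intensity[i]) / max(peaks[i]), 1,
                 tolerance = 0.05)
  }
  # flat zero baseline: identity within tolerance
  flat <- baseline_correct(spectrum1d(ppm, peaks))
  expect_lt(max(abs(flat$intensity - peaks)) / max(peaks), 0.05)
  # a negative-going artifact is not amplified
  dip <- peaks; dip[4000:4010] <- -20
  dipc <- baseline_correct(spectrum1d(ppm, dip))
  expect_gt(min(dipc$intensity), -21)
})

test_that("ppm calibration restores a known shift on the reference", {
  design <- tiny_design()
  truth <- quiet_truth(design)
  flasks <- simulate_flasks(design, truth)
  sp <- process_fid(synth_nmr_fid(flasks[1, ], "apolar", truth,
                                  n_points = 4096L),
                    reference = NULL, target_points = 16384L)
  shifted <- sp
  shifted$ppm <- sp$ppm + 0.03
  cal <- calibrate_ppm(shifted, "chcl3")
  expect_equal(cal$meta$ppm_shift, -0.03, tolerance = 2e-3)
  cal2 <- calibrate_ppm(cal, "chcl3")
  expect_lt(abs(cal2$meta$ppm_shift), 2e-3)
  # no reference present: polar spectra carry no CHCl3... fake spectrum
  empty <- spectrum1d(seq(10, -2, length.out = 2048), rep(0, 2048))
  expect_error(calibrate_ppm(empty, "chcl3"), "not found")
})

test_that("alignment corrects small shifts and respects max_shift", {
  design <- tiny_design()
  truth <- quiet_truth(design)
  flasks <- simulate_flasks(design, truth)
  sp <- process_fid(synth_nmr_fid(flasks[1, ], "apolar", truth,
                                  n_points = 4096L),
                    reference = "chcl3", target_points = 16384L)
  dppm <- abs(diff(sp$ppm[1:2]))
  k <- round(0.004 / dppm)
  shifted <- sp
  shifted$intensity <- c(sp$intensity[-seq_len(k)],
                         rep(sp$intensity[length(sp$intensity)], k))
  mats <- align_spectra(list(sp, sp, shifted), bin_width_ppm = 0.005,
                        max_shift_ppm = 0.02,
                        sample_ids = c("a", "b", "c"))
  v <- fm_values(mats)
  expect_gt(stats::cor(v[, "a"], v[, "c"]), 0.999)
  expect_equal(v[, "a"], v[, "b"])                 # identical spectra
  # total intensity conserved within 1% by shifting
  expect_equal(sum(v[, "c"]), sum(v[, "a"]), tolerance = 0.01)
  # max_shift 0 is pure binning: the shifted spectrum stays shifted
  m0 <- align_spectra(list(sp, shifted), max_shift_ppm = 0,
                      sample_ids = c("a", "c"))
  v0 <- fm_values(m0)
  expect_lt(stats::cor(v0[, "a"], v0[, "c"]),
            stats::cor(v[, "a"], v[, "c"]))
  expect_error(align_spectra(list(sp), bin_width_ppm = -1), "bin_width")
})

test_that("noiseless processing recovers planted amplitudes (r2 > 0.999)", {
  design <- tiny_design(passages = "pA", n_replicates = 1)
  truth <- quiet_truth(design)
  flasks <- simulate_flasks(design, truth)
  fl <- flasks[flasks$treatment == "DMSO", ][1, ]
  sp <- process_fid(synth_nmr_fid(fl, "apolar", truth), reference = "chcl3")
  asg <- apolar_assignments()
  iso <- asg[asg$signal %in% c(1, 9, 12, 13, 14, 15, 16, 17, 18, 19, 22), ]
  areas <- vapply(iso$center_ppm, function(c) {
    integrate_region(sp, c - 0.02, c + 0.02)
  }, numeric(1))
  amps <- metabopipe:::.APOLAR_BASE[iso$signal]
  fit <- stats::lm(areas ~ amps)
  expect_gt(summary(fit)$r.squared, 0.999)
})
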
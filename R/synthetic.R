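# Synthetic exposure-study generator. Produces complete study bundles (NMR
# FIDs for both fractions, LC-MS and GC-MS peak lists, metadata, ground
# truth) with the statistical structure the analysis pipeline assumes: a
# global per-flask cell-number confounder (fewer cells under TCDD), passage-
# dependent effect magnitudes, and planted per-metabolite TCDD:DMSO fold
# changes (RTD).

# Deterministic per-stream seeds below 2^31 so any flask/fraction can be
# regenerated in isolation and bundles are byte-identical under one seed.
.derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# mean-one lognormal multiplier; cv may vary per draw
.lnoise <- function(n, cv) {
  cv <- rep_len(cv, n)
  out <- rep(1, n)
  nz <- cv > 0
  if (any(nz)) {
    sdlog <- sqrt(log(1 + cv[nz]^2))
    out[nz] <- stats::rlnorm(sum(nz), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out
}

#' Enumerate the study design
#'
#' Full crossing of passages, the two treatments (TCDD and its vehicle
#' control DMSO) and biological replicates (tissue-culture flasks), with
#' deterministic sample ids.
#'
#' @param passages Character vector of passage labels.
#' @param n_replicates Biological replicates per passage and treatment.
#' @param seed Integer seed stored with the design.
#' @return A `study_design`: data.frame with sample_id, passage, treatment,
#'   replicate.
#' @examples
#' nrow(make_study_design())  # 5 passages x 2 treatments x 4 replicates = 40
#' @export
make_study_design <- function(passages = c("p7", "p11a", "p11b", "p17", "p30"),
                              n_replicates = 4L, seed = 1L) {
  if (length(passages) == 0L) stop("passages must be non-empty")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  design <- expand.grid(replicate = seq_len(n_replicates),
                        treatment = c("TCDD", "DMSO"),
                        passage = passages,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("passage", "treatment", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%d", design$passage, design$treatment,
                              design$replicate)
  stopifnot(!anyDuplicated(design$sample_id))
  structure(design, seed = seed, class = c("study_design", "data.frame"))
}

#' Default planted ground truth and noise model
#'
#' Builds the truth manifest: planted TCDD:DMSO ratios (RTD) for every
#' simulated species on every platform, the TCDD cell-number ratio, the
#' per-passage effect-attenuation exponents, and all noise parameters.
#' Fold changes default to the values recovered from real HepG2 extracts
#' (apolar NMR/GC-MS and polar NMR/LC-MS results tables); species not listed
#' there are null (RTD = 1).
#'
#' @param design A [make_study_design()] result (attenuations are drawn per
#'   passage from `attenuation_range` using the design seed).
#' @param cell_ratio_tcdd Mean cell_scale of TCDD flasks relative to DMSO.
#' @param cell_cv Lognormal flask-to-flask coefficient of variation of
#'   cell_scale.
#' @param replicate_cv Per-signal lognormal replicate CV.
#' @param attenuation_range Range the per-passage effect-attenuation
#'   exponents are drawn from (uniform); `c(1, 1)` fixes full effects.
#' @param linewidth_hz NMR Lorentzian line width.
#' @param ppm_jitter_sd Per-sample chemical-shift jitter (ppm), applied to
#'   cell-derived lines only.
#' @param fid_noise_sd Additive Gaussian noise on each FID channel.
#' @param baseline_amplitude Amplitude of a broad baseline hump (0 disables).
#' @param mz_error_ppm LC-MS Gaussian mass error (ppm).
#' @param rt_drift_sd Scale of the per-run monotone retention-time drift.
#' @param intensity_cv MS intensity CV.
#' @param ms_noise_sd MS intensity noise floor scale; the detection floor is
#'   `3 * ms_noise_sd`.
#' @param n_decoys Decoy peaks per LC-MS run (GC-MS uses a quarter of this).
#' @param overrides Named list of RTD overrides, e.g.
#'   `list(nmr_apolar = c(triglyceride = 1))`.
#' @return A `truth_manifest` list.
#' @export
truth_manifest <- function(design = make_study_design(),
                           cell_ratio_tcdd = 0.7, cell_cv = 0.1,
                           replicate_cv = 0.1,
                           attenuation_range = c(0.6, 1.0),
                           linewidth_hz = 1.5, ppm_jitter_sd = 0.003,
                           fid_noise_sd = 0.002, baseline_amplitude = 0.05,
                           mz_error_ppm = 2, rt_drift_sd = 0.01,
                           intensity_cv = 0.1, ms_noise_sd = 300,
                           n_decoys = 100L, overrides = list()) {
  if (cell_ratio_tcdd <= 0) stop("cell ratio must be positive")
  seed <- attr(design, "seed") %||% 1L
  passages <- unique(design$passage)
  att <- .with_seed(.derive_seed(seed, "attenuation"),
                    stats::runif(length(passages), attenuation_range[1],
                                 attenuation_range[2]))
  names(att) <- passages

  # apolar NMR: planted effects by species group of the assignment table
  nmr_apolar <- c(triglyceride = 0.51, cholesterol_ester = 0.69,
                  acyl_allylic = 0.75, acyl_olefinic = 0.75,
                  pufa_bisallylic = 1.0, cholesterol_free = 1.0,
                  phospholipid = 1.0, choline = 1.0, cholesterol_total = 1.0,
                  acyl_ch3 = 1.0, acyl_n3_ch3 = 1.0, acyl_ch2 = 1.0,
                  acyl_oco_ch2 = 1.0, acyl_oco = 1.0)
  # polar NMR: by assignment name
  nmr_polar <- c("Leucine" = 0.69, "Isoleucine" = 0.69, "Valine" = 0.72,
                 "Threonine" = 1.0, "Lactate" = 0.49, "Alanine" = 0.68,
                 "N-acetyl-aspartate" = 0.68, "Glutamate" = 0.79,
                 "Glutamine" = 0.69, "Oxidized glutathione" = 1.26,
                 "Reduced glutathione" = 1.58, "Aspartate" = 0.66,
                 "Citrate" = 1.46, "Creatine/Phosphocreatine" = 0.66,
                 "Choline derivatives" = 1.0, "Taurine" = 1.37,
                 "Glycine" = 0.72, "Serine" = 0.65,
                 "AXP nucleotides" = 0.45, "UXP nucleotides" = 0.45,
                 "NAD(P)(H)" = 1.0, "Tyrosine" = 0.58, "Formate" = 1.0)
  # LC-MS: by compound-table name
  lcms <- c("Proline" = 0.54, "Leucine/Isoleucine" = 0.64,
            "Spermidine" = 0.24, "N-acetyl-aspartate" = 0.72,
            "Tyrosine" = 0.44, "Acetyl spermidine" = 0.59,
            "L-tryptophan" = 0.79, "Citric acid" = 1.68,
            "Propionylcarnitine" = 0.66, "Pantothenic acid" = 0.62,
            "Butyrylcarnitine" = 0.58, "Glutathione reduced" = 1.23,
            "UMP" = 0.71, "AMP" = 0.67, "Glutathione oxidized" = 1.31,
            "UDP-N-acetyl-hexosamine" = 1.48)
  # GC-MS: by FAME species name; AA and DHA are per-cell constant
  gcms <- c("C12:0" = 0.78, "C14:0" = 0.72, "C14:1_a" = 0.70,
            "C14:1_b" = 0.29, "C16:0" = 1.0, "C16:1 (n-6)" = 0.63,
            "C16:1 (n-9)" = 0.62, "C17:0" = 1.20, "C18:0" = 1.27,
            "C18:1 (n-9)" = 0.78, "C18:1_c" = 0.72, "C18:2_a" = 0.71,
            "C18:2_b" = 0.63, "C18:2_c" = 1.29, "C18:2_d" = 0.64,
            "C18:2_e" = 0.63, "C20:1_b" = 0.79, "C20:2_a" = 0.74,
            "C20:2_b" = 0.70, "C20:3_a" = 0.80, "C20:3_b" = 0.64,
            "C20:4 (AA)" = 1.0, "C22:2" = 0.61, "C22:3_a" = 0.73,
            "C22:6 (DHA)" = 1.0)
  for (k in names(overrides)) {
    tab <- get(k)
    tab[names(overrides[[k]])] <- overrides[[k]]
    assign(k, tab)
  }
  if (any(c(nmr_apolar, nmr_polar, lcms, gcms) <= 0)) {
    stop("planted RTD values must be positive")
  }
  structure(list(
    seed = seed,
    rtd = list(nmr_apolar = nmr_apolar, nmr_polar = nmr_polar,
               lcms = lcms, gcms = gcms),
    effect_attenuation = att,
    cell_ratio_tcdd = cell_ratio_tcdd, cell_cv = cell_cv,
    replicate_cv = replicate_cv,
    noise = list(linewidth_hz = linewidth_hz, ppm_jitter_sd = ppm_jitter_sd,
                 fid_noise_sd = fid_noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 mz_error_ppm = mz_error_ppm, rt_drift_sd = rt_drift_sd,
                 intensity_cv = intensity_cv, ms_noise_sd = ms_noise_sd,
                 n_decoys = as.integer(n_decoys)),
    # reference-line amplitudes: independent of cell number
    chcl3_amplitude = 30, chcl3_cv = 0.02,
    tmsp_amplitude = 5, tmsp_cv = 0.02,
    lcms_base_intensity = 1e5, gcms_base_intensity = 1e4
  ), class = "truth_manifest")
}

# per-signal base amplitudes (a.u.) of the apolar assignment lines
.APOLAR_BASE <- c(0.5, 1.5, 3.0, 0.8, 0.6, 0.7, 0.5, 1.2, 8.0, 2.5, 0.9,
                  2.0, 2.2, 1.2, 1.5, 0.8, 1.0, 0.7, 0.3, 0.9, 0.35, 2.8)

#' Realize per-flask cell scales
#'
#' TCDD flasks draw their cell_scale (the global multiplier on all
#' cell-derived signal) around the configured TCDD cell ratio; DMSO flasks
#' around 1. Flask-to-flask variation is mean-one lognormal.
#'
#' @param design A study design.
#' @param truth A [truth_manifest()].
#' @return The design with a `cell_scale` column appended.
#' @export
simulate_flasks <- function(design, truth) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_manifest"))
  base <- ifelse(design$treatment == "TCDD", truth$cell_ratio_tcdd, 1)
  noise <- .with_seed(.derive_seed(truth$seed, "cells"),
                      .lnoise(nrow(design), truth$cell_cv))
  design$cell_scale <- base * noise
  design
}

# line table (ppm, amplitude, rtd, cell_derived) for one fraction
.nmr_lines <- function(fraction, truth) {
  if (fraction == "apolar") {
    asg <- apolar_assignments()
    rtd <- truth$rtd$nmr_apolar[asg$species]
    rtd[is.na(rtd)] <- 1
    lines <- data.frame(ppm = asg$center_ppm, amplitude = .APOLAR_BASE,
                        rtd = as.numeric(rtd), cell = TRUE)
    rbind(lines, data.frame(ppm = 7.26, amplitude = truth$chcl3_amplitude,
                            rtd = 1, cell = FALSE))
  } else if (fraction == "polar") {
    asg <- polar_assignments()
    shifts <- strsplit(asg$shifts_ppm, ";")
    rtd <- truth$rtd$nmr_polar[asg$assignment]
    rtd[is.na(rtd)] <- 1
    lines <- data.frame(
      ppm = as.numeric(unlist(shifts)),
      amplitude = 1,
      rtd = rep(as.numeric(rtd), lengths(shifts)),
      cell = TRUE)
    rbind(lines, data.frame(ppm = 0.0, amplitude = truth$tmsp_amplitude,
                            rtd = 1, cell = FALSE))
  } else {
    stop("unknown fraction: ", fraction)
  }
}

#' Simulate one flask's FID
#'
#' Sum of exponentially damped sinusoids (Lorentzian lines): one per
#' assignment-table entry, with amplitude `base * cell_scale *
#' RTD^attenuation` (TCDD flasks) times mean-one lognormal replicate noise;
#' plus a reference line whose amplitude is independent of cell_scale (the
#' residual CHCl3 proton for the apolar fraction, TMSP for the polar one);
#' plus additive Gaussian noise and an optional broad baseline hump. One
#' per-sample ppm jitter shifts all cell-derived lines.
#'
#' @param flask One row of a [simulate_flasks()] result (needs sample_id,
#'   passage, treatment, cell_scale).
#' @param fraction `"apolar"` or `"polar"`.
#' @param truth A [truth_manifest()].
#' @param n_points,sw,obs_freq,ppm_center Acquisition settings: 16 K points,
#'   5000 Hz spectral width at 400.13 MHz by default.
#' @return A [fid_record].
#' @export
synth_nmr_fid <- function(flask, fraction, truth, n_points = 16384L,
                          sw = 5000, obs_freq = 400.13, ppm_center = 5.5) {
  stopifnot(inherits(truth, "truth_manifest"))
  lines <- .nmr_lines(fraction, truth)
  att <- truth$effect_attenuation[[flask$passage]] %||% 1
  .with_seed(.derive_seed(truth$seed, flask$sample_id, fraction), {
    eff <- if (flask$treatment == "TCDD") lines$rtd^att else
      rep(1, nrow(lines))
    amp <- lines$amplitude * eff *
      ifelse(lines$cell, flask$cell_scale, 1) *
      .lnoise(nrow(lines), ifelse(lines$cell, truth$replicate_cv,
                                  truth$chcl3_cv))
    jitter <- stats::rnorm(1, 0, truth$noise$ppm_jitter_sd)
    ppm <- lines$ppm + ifelse(lines$cell, jitter, 0)
    t <- (seq_len(n_points) - 1L) / sw
    f <- (ppm - ppm_center) * obs_freq          # offset Hz
    lambda <- pi * truth$noise$linewidth_hz     # Lorentzian decay rate
    phase <- outer(t, 2 * pi * f)               # n_points x n_lines
    s <- (cos(phase) %*% amp) + 1i * (sin(phase) %*% amp)
    s <- as.vector(s) * exp(-lambda * t)
    if (truth$noise$baseline_amplitude > 0) {
      hump_f <- stats::runif(1, -sw / 4, sw / 4)
      s <- s + truth$noise$baseline_amplitude * sum(abs(amp)) *
        exp((2i * pi * hump_f - 400) * t)
    }
    if (truth$noise$fid_noise_sd > 0) {
      s <- s + complex(real = stats::rnorm(n_points, 0, truth$noise$fid_noise_sd),
                       imaginary = stats::rnorm(n_points, 0,
                                                truth$noise$fid_noise_sd))
    }
    fid_record(s, sw = sw, obs_freq = obs_freq, ppm_center = ppm_center,
               meta = list(sample_id = flask$sample_id, fraction = fraction,
                           treatment = flask$treatment,
                           passage = flask$passage,
                           relaxation_delay = 2,
                           scans = if (fraction == "polar") 1024 else 128))
  })
}

#' Simulate one flask's MS peak list
#'
#' LC-MS runs contain one peak per reference compound at its theoretical
#' adduct m/z perturbed by Gaussian ppm-scale mass error, with a per-run
#' monotone retention-time drift; GC-MS runs contain one peak per FAME
#' species at its retention index, including the AA (C20:4) and DHA (C22:6)
#' anchors whose per-cell amounts carry no treatment effect. Intensities
#' scale like the NMR amplitudes. Decoy peaks are added and everything below
#' the detection floor (3 x the MS noise scale) is dropped.
#'
#' @param flask One row of a [simulate_flasks()] result.
#' @param platform `"lcms"` or `"gcms"`.
#' @param truth A [truth_manifest()].
#' @return A `peak_list` data.frame with columns mz (m/z or retention
#'   index), rt, intensity and attributes `run_id`, `platform`.
#' @export
synth_ms_run <- function(flask, platform, truth) {
  stopifnot(inherits(truth, "truth_manifest"))
  if (!platform %in% c("lcms", "gcms")) stop("unknown platform: ", platform)
  att <- truth$effect_attenuation[[flask$passage]] %||% 1
  floor_int <- 3 * truth$noise$ms_noise_sd
  .with_seed(.derive_seed(truth$seed, flask$sample_id, platform), {
    if (platform == "lcms") {
      ref <- compound_table()
      ref <- ref[!is.na(ref$theoretical_mz), ]
      rtd <- truth$rtd$lcms[ref$name]
      rtd[is.na(rtd)] <- 1
      base <- truth$lcms_base_intensity
      eff <- if (flask$treatment == "TCDD") rtd^att else rep(1, nrow(ref))
      intensity <- base * flask$cell_scale * eff *
        .lnoise(nrow(ref), truth$noise$intensity_cv)
      mz <- ref$theoretical_mz *
        (1 + stats::rnorm(nrow(ref), 0, truth$noise$mz_error_ppm) * 1e-6)
      rt_nominal <- 1 + 17 * (seq_len(nrow(ref)) - 1) / max(1, nrow(ref) - 1)
      slope <- stats::rnorm(1, 0, truth$noise$rt_drift_sd)
      offset <- stats::rnorm(1, 0, truth$noise$rt_drift_sd)
      rt <- rt_nominal * (1 + slope) + abs(offset)
      nd <- truth$noise$n_decoys
      peaks <- data.frame(mz = c(mz, stats::runif(nd, 80, 650)),
                          rt = c(rt, stats::runif(nd, 0.5, 19.5)),
                          intensity = c(intensity,
                                        floor_int * 2 * .lnoise(nd, 1)))
    } else {
      ref <- fame_table()
      rtd <- truth$rtd$gcms[ref$name]
      rtd[is.na(rtd)] <- 1
      base <- truth$gcms_base_intensity
      eff <- if (flask$treatment == "TCDD") rtd^att else rep(1, nrow(ref))
      intensity <- base * flask$cell_scale * eff *
        .lnoise(nrow(ref), truth$noise$intensity_cv)
      # retention indices are ladder-calibrated, so between-run drift is a
      # small additive shift rather than a multiplicative stretch
      shift <- stats::rnorm(1, 0, truth$noise$rt_drift_sd * 50)
      ri <- ref$retention_index + shift
      nd <- max(1L, truth$noise$n_decoys %/% 4L)
      peaks <- data.frame(mz = c(ri, stats::runif(nd, 1100, 2400)),
                          rt = c(ri / 100, stats::runif(nd, 11, 24)),
                          intensity = c(intensity,
                                        floor_int * 2 * .lnoise(nd, 1)))
    }
    peaks <- peaks[peaks$intensity >= floor_int, , drop = FALSE]
    peaks <- peaks[order(peaks$rt), , drop = FALSE]
    rownames(peaks) <- NULL
    structure(peaks, run_id = flask$sample_id, platform = platform,
              class = c("peak_list", "data.frame"))
  })
}

#' Simulate all FIDs of one fraction in memory
#'
#' @param flasks A [simulate_flasks()] result.
#' @param fraction `"apolar"` or `"polar"`.
#' @param truth A [truth_manifest()].
#' @return Named list of [fid_record]s, one per flask.
#' @export
simulate_nmr_study <- function(flasks, fraction, truth) {
  fids <- lapply(seq_len(nrow(flasks)), function(i) {
    synth_nmr_fid(flasks[i, ], fraction, truth)
  })
  names(fids) <- flasks$sample_id
  fids
}

#' Write a complete synthetic study bundle to disk
#'
#' Per flask: JCAMP-DX FIDs for both fractions, LC-MS and GC-MS peak-list
#' TSVs; plus the sample metadata table and the truth manifest (YAML). A
#' fixed seed yields a byte-identical bundle.
#'
#' @param config Study configuration as from [default_config()] (or a
#'   partial list merged over it).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the design, truth and file index.
#' @export
generate_study <- function(config = default_config(), outdir) {
  config <- .merge_config(default_config(), config)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir)
  }
  design <- make_study_design(config$study$passages,
                              config$study$n_replicates,
                              config$study$seed)
  truth <- do.call(truth_manifest, c(list(design = design),
                                     config$truth))
  flasks <- simulate_flasks(design, truth)
  for (sub in c("nmr_apolar", "nmr_polar", "lcms", "gcms")) {
    dir.create(file.path(outdir, sub), showWarnings = FALSE)
  }
  for (i in seq_len(nrow(flasks))) {
    fl <- flasks[i, ]
    write_jcampdx(synth_nmr_fid(fl, "apolar", truth),
                  file.path(outdir, "nmr_apolar",
                            paste0(fl$sample_id, ".dx")),
                  title = paste0(fl$sample_id, " apolar"))
    write_jcampdx(synth_nmr_fid(fl, "polar", truth),
                  file.path(outdir, "nmr_polar",
                            paste0(fl$sample_id, ".dx")),
                  title = paste0(fl$sample_id, " polar"))
    write_peak_list(synth_ms_run(fl, "lcms", truth),
                    file.path(outdir, "lcms", paste0(fl$sample_id, ".tsv")))
    write_peak_list(synth_ms_run(fl, "gcms", truth),
                    file.path(outdir, "gcms", paste0(fl$sample_id, ".tsv")))
  }
  utils::write.table(flasks[, c("sample_id", "passage", "treatment",
                                "replicate")],
                     file.path(outdir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth_manifest(truth, flasks, file.path(outdir, "truth.yaml"))
  invisible(list(design = design, truth = truth, flasks = flasks,
                 outdir = outdir))
}

#' Serialize / restore a truth manifest
#'
#' The manifest (including realized per-flask cell scales) round-trips
#' losslessly through its YAML form.
#'
#' @param truth A [truth_manifest()].
#' @param flasks Optional [simulate_flasks()] result whose cell scales are
#'   stored alongside.
#' @param path Output path.
#' @export
write_truth_manifest <- function(truth, flasks = NULL, path) {
  obj <- unclass(truth)
  obj$effect_attenuation <- as.list(obj$effect_attenuation)
  obj$rtd <- lapply(obj$rtd, as.list)
  if (!is.null(flasks)) {
    obj$cell_scale <- as.list(stats::setNames(flasks$cell_scale,
                                              flasks$sample_id))
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$effect_attenuation <- unlist(obj$effect_attenuation)
  obj$rtd <- lapply(obj$rtd, unlist)
  cell <- obj$cell_scale
  obj$cell_scale <- NULL
  out <- structure(obj, class = "truth_manifest")
  attr(out, "cell_scale") <- if (!is.null(cell)) unlist(cell)
  out
}

#' Write / read a peak-list TSV
#'
#' @param peaks A `peak_list` (columns mz, rt, intensity).
#' @param path File path.
#' @export
write_peak_list <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# run_id: %s", attr(peaks, "run_id") %||% ""),
               sprintf("# platform: %s", attr(peaks, "platform") %||% "")),
             con)
  utils::write.table(peaks, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(paste0("^# ", key, ":"), "", m[1])) else ""
  }
  tab <- utils::read.delim(text = paste(lines[!grepl("^#", lines)],
                                        collapse = "\n"),
                           stringsAsFactors = FALSE)
  structure(tab, run_id = get("run_id"), platform = get("platform"),
            class = c("peak_list", "data.frame"))
}
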
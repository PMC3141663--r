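# Configuration handling and end-to-end orchestration:
# simulate -> process -> normalize -> select -> annotate.

#' Default pipeline configuration
#'
#' All tunable parameters of the simulator and the pipeline with their
#' defaults: the 5-passage x 2-treatment x 4-replicate study design, the
#' noise model, NMR processing and alignment settings, MS alignment
#' tolerances, selection thresholds and the annotation tolerance.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    study = list(passages = c("p7", "p11a", "p11b", "p17", "p30"),
                 n_replicates = 4L, seed = 1L),
    truth = list(cell_ratio_tcdd = 0.7, cell_cv = 0.1, replicate_cv = 0.1,
                 attenuation_range = c(0.6, 1.0), linewidth_hz = 1.5,
                 ppm_jitter_sd = 0.003, fid_noise_sd = 0.002,
                 baseline_amplitude = 0.05, mz_error_ppm = 2,
                 rt_drift_sd = 0.01, intensity_cv = 0.1, ms_noise_sd = 300,
                 n_decoys = 100L),
    nmr = list(target_points = 131072L, bin_width_ppm = 0.005,
               segment_width_ppm = 0.1, max_shift_ppm = 0.02,
               smoothness = 1e4, asymmetry = 0.05,
               water_window = c(4.7, 5.0), tmsp_window = c(-0.3, 0.3),
               chcl3_window = c(7.20, 7.32), pl_window = c(5.17, 5.24)),
    ms = list(lcms_mz_tol = 0.005, lcms_rt_tol = 0.1, gcms_ri_tol = 3,
              gcms_rt_tol = 0.5, smooth_window = 7L, poly_order = 2L,
              k_noise = 3, fame_window_halfwidth = 2.5),
    selection = list(alpha_pre = 0.01, alpha_bonf = 0.05, min_fc = 1.2,
                     grouping = "treatment", bonferroni_universe = "pre"),
    annotation = list(tol_mda = 5)
  )
}

# recursive merge with unknown-key and type validation
.merge_config <- function(defaults, override, path = character()) {
  if (is.null(override)) return(defaults)
  stopifnot(is.list(override))
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults)) stop("unknown configuration key: ", full)
    d <- defaults[[key]]
    o <- override[[key]]
    if (is.list(d) && !is.null(names(d))) {
      defaults[[key]] <- .merge_config(d, o, c(path, key))
    } else {
      if (is.numeric(d) && !is.numeric(o)) {
        stop("configuration key ", full, " must be numeric")
      }
      if (is.character(d) && !is.character(o)) {
        stop("configuration key ", full, " must be character")
      }
      defaults[[key]] <- o
    }
  }
  defaults
}

#' Load, validate and save pipeline configurations
#'
#' Configurations are YAML; missing keys take their defaults, unknown keys
#' are rejected by name. `write_config()` followed by `load_config()` is the
#' identity on a validated configuration.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  given <- yaml::read_yaml(path)
  cfg <- .merge_config(default_config(), given)
  # yaml scalars come back untyped in places; coerce the integer-ish ones
  cfg$study$n_replicates <- as.integer(cfg$study$n_replicates)
  cfg$study$seed <- as.integer(cfg$study$seed)
  cfg
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Summed bin intensity of a ppm window, per sample
#'
#' @param matrix An NMR [feature_matrix] with `ppm_center` descriptors.
#' @param lo_ppm,hi_ppm Window bounds.
#' @return Named numeric vector (one value per sample).
#' @export
window_intensity <- function(matrix, lo_ppm, hi_ppm) {
  stopifnot(inherits(matrix, "feature_matrix"))
  ctr <- fm_descriptors(matrix)$ppm_center
  if (is.null(ctr)) stop("matrix has no ppm_center descriptor")
  rows <- which(ctr >= lo_ppm & ctr < hi_ppm)
  if (length(rows) == 0L) stop("no bins inside [", lo_ppm, ", ", hi_ppm, "]")
  colSums(matrix$values[rows, , drop = FALSE], na.rm = TRUE)
}

#' Fold change of a ppm window between treatments
#'
#' Integrates the window per sample (sum of bins) and forms the ratio of
#' group means — the window-level RTD estimate.
#'
#' @inheritParams window_intensity
#' @param groups Treatment labels per sample column.
#' @param numerator,denominator Labels forming the ratio.
#' @return The ratio of arithmetic group means.
#' @export
window_fold_change <- function(matrix, lo_ppm, hi_ppm, groups,
                               numerator = "TCDD", denominator = "DMSO") {
  v <- window_intensity(matrix, lo_ppm, hi_ppm)
  stopifnot(length(groups) == length(v))
  mean(v[groups == numerator]) / mean(v[groups == denominator])
}

#' Process one fraction's FIDs into spectra, a matrix and factors
#'
#' Runs the full NMR chain on every FID, aligns the calibrated spectra into
#' a binned feature matrix (masking the reference/solvent windows), and, for
#' the apolar fraction, computes the per-flask TS/CHCl3 and PL/CHCl3
#' normalization factors.
#'
#' @param fids Named list of [fid_record]s (names = flask ids).
#' @param fraction `"apolar"` or `"polar"`.
#' @param config Pipeline configuration (see [default_config()]).
#' @return A list with `spectra`, `matrix` and (apolar only) `factors`.
#' @export
process_nmr_fraction <- function(fids, fraction, config = default_config()) {
  stopifnot(fraction %in% c("apolar", "polar"))
  nmr <- config$nmr
  reference <- if (fraction == "apolar") "chcl3" else "tmsp"
  spectra <- lapply(fids, process_fid, reference = reference,
                    target_points = nmr$target_points,
                    smoothness = nmr$smoothness, asymmetry = nmr$asymmetry)
  exclude <- if (fraction == "apolar") list(nmr$chcl3_window) else
    list(nmr$water_window, nmr$tmsp_window)
  mat <- align_spectra(spectra, bin_width_ppm = nmr$bin_width_ppm,
                       segment_width_ppm = nmr$segment_width_ppm,
                       max_shift_ppm = nmr$max_shift_ppm,
                       exclude_windows = exclude,
                       sample_ids = names(fids), fraction = fraction)
  out <- list(spectra = spectra, matrix = mat)
  if (fraction == "apolar") {
    out$factors <- normalization_factors(spectra,
                                         chcl3_window = nmr$chcl3_window)
  }
  out
}

#' Run the whole pipeline on a synthetic study
#'
#' Generates (or reuses) a study bundle on disk, processes every platform,
#' computes and applies the normalization factors, runs the selection
#' cascade per platform, annotates the selected LC-MS features by exact
#' mass, and writes factors, matrices, selection reports and a summary
#' table under `outdir`. Every stage logs its parameters and the seed to
#' `run.log`.
#'
#' @param config Configuration (list or YAML path); see [default_config()].
#' @param outdir Output directory.
#' @param seed Optional override of `config$study$seed`.
#' @param verbose Log progress to standard error.
#' @return A `metab_pipeline` object: design, truth, factors, per-platform
#'   matrices, selections, annotations and the summary table.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  config <- .merge_config(default_config(), config)
  if (!is.null(seed)) config$study$seed <- as.integer(seed)
  if (length(config$study$passages) == 0L) stop("empty study design")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  log <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logfile, append = TRUE)
    if (verbose) message(msg)
  }
  log("pipeline start, seed ", config$study$seed)

  raw <- generate_study(config, file.path(outdir, "raw"))
  flasks <- raw$flasks
  groups <- flasks$treatment
  grouping <- if (identical(config$selection$grouping,
                            "passage-x-treatment")) {
    paste(flasks$passage, flasks$treatment, sep = ":")
  } else groups
  log("simulated ", nrow(flasks), " flasks")

  # --- NMR, both fractions (read back from disk: stage isolation) -------
  nmr_res <- list()
  for (fraction in c("apolar", "polar")) {
    files <- file.path(outdir, "raw", paste0("nmr_", fraction),
                       paste0(flasks$sample_id, ".dx"))
    fids <- lapply(files, read_jcampdx)
    names(fids) <- flasks$sample_id
    nmr_res[[fraction]] <- process_nmr_fraction(fids, fraction, config)
    write_feature_table(nmr_res[[fraction]]$matrix,
                        file.path(outdir,
                                  paste0("matrix_nmr_", fraction, ".tsv")))
    log("processed ", length(fids), " ", fraction, " spectra")
  }

  # --- MS platforms ------------------------------------------------------
  lc_lists <- lapply(file.path(outdir, "raw", "lcms",
                               paste0(flasks$sample_id, ".tsv")),
                     read_peak_list)
  lcms_mat <- align_runs(lc_lists, mz_tol = config$ms$lcms_mz_tol,
                         rt_tol = config$ms$lcms_rt_tol)
  write_feature_table(lcms_mat, file.path(outdir, "matrix_lcms.tsv"))
  log("aligned ", nrow(fm_values(lcms_mat)), " LC-MS features")

  gc_lists <- lapply(file.path(outdir, "raw", "gcms",
                               paste0(flasks$sample_id, ".tsv")),
                     read_peak_list)
  windows <- fame_target_windows(config$ms$fame_window_halfwidth)
  gc_int <- vapply(gc_lists, integrate_fame_targets, numeric(nrow(windows)),
                   target_windows = windows)
  colnames(gc_int) <- flasks$sample_id

  # --- normalization -----------------------------------------------------
  factors <- nmr_res$apolar$factors
  factors$gc_aa_dha <- gc_int["C20:4 (AA)", factors$flask] +
    gc_int["C22:6 (DHA)", factors$flask]
  utils::write.table(factors, file.path(outdir, "factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  norm <- list(
    nmr_apolar = normalize_matrix(nmr_res$apolar$matrix, factors),
    nmr_polar = normalize_matrix(nmr_res$polar$matrix, factors),
    lcms = normalize_matrix(lcms_mat, factors),
    gcms = gc_normalize(gc_int))
  log("normalized all platforms by PL/CHCl3 (GC-MS by AA+DHA)")

  # --- selection + annotation -------------------------------------------
  selections <- list()
  for (platform in names(norm)) {
    selections[[platform]] <- select_affected(
      norm[[platform]], grouping,
      alpha_pre = config$selection$alpha_pre,
      alpha_bonf = config$selection$alpha_bonf,
      min_fc = config$selection$min_fc,
      bonferroni_universe = config$selection$bonferroni_universe,
      treatment = groups)
    export_selected_features(selections[[platform]], norm[[platform]],
                             file.path(outdir,
                                       paste0("selection_", platform,
                                              ".tsv")))
    log(platform, ": ", sum(selections[[platform]]$selected), "/",
        nrow(selections[[platform]]), " features selected")
  }
  sel_lc <- selections$lcms
  annotations <- if (any(sel_lc$selected)) {
    ann <- annotate_features(sel_lc$mz[sel_lc$selected],
                             tol_mda = config$annotation$tol_mda)
    ann$fold_change <- sel_lc$fold_change[sel_lc$selected][ann$feature]
    ann
  } else {
    data.frame(feature = integer(0), mz = numeric(0), name = character(0))
  }
  utils::write.table(annotations, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary_tab <- do.call(rbind, lapply(names(selections), function(pl) {
    s <- selections[[pl]]
    sel <- s[s$selected, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    desc <- if (!is.null(sel$ppm_center)) sprintf("%.3f ppm", sel$ppm_center)
      else if (!is.null(sel$name)) as.character(sel$name)
      else sprintf("m/z %.4f", sel$mz)
    data.frame(platform = pl, feature = desc,
               fold_change = round(sel$fold_change, 3),
               bonferroni_p = signif(sel$bonferroni_p, 3))
  }))
  if (is.null(summary_tab)) {
    summary_tab <- data.frame(platform = character(0), feature = character(0),
                              fold_change = numeric(0),
                              bonferroni_p = numeric(0))
  }
  utils::write.table(summary_tab, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("pipeline done")

  structure(list(config = config, design = raw$design, truth = raw$truth,
                 flasks = flasks, factors = factors, matrices = norm,
                 selections = selections, annotations = annotations,
                 summary = summary_tab, outdir = outdir),
            class = "metab_pipeline")
}

#' @export
print.metab_pipeline <- function(x, ...) {
  cat(sprintf("<metab_pipeline: %d flasks, seed %d>\n", nrow(x$flasks),
              x$config$study$seed))
  for (pl in names(x$selections)) {
    cat(sprintf("  %-10s %d/%d features selected\n", pl,
                sum(x$selections[[pl]]$selected),
                nrow(x$selections[[pl]])))
  }
  invisible(x)
}
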
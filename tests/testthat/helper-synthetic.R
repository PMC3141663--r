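# Small study fixtures used across tests. Unit tests run on short FIDs
# (4 K points, 32 K zero-fill) so the full chain stays fast; the acceptance
# tests use the full-size acquisition.

tiny_design <- function(seed = 7, passages = c("pA", "pB"),
                        n_replicates = 2L) {
  make_study_design(passages, n_replicates, seed)
}

# noiseless truth: planted effects only, no confounder unless asked
quiet_truth <- function(design, ...) {
  args <- list(design = design, attenuation_range = c(1, 1), cell_cv = 0,
               replicate_cv = 0, ppm_jitter_sd = 0, fid_noise_sd = 0,
               baseline_amplitude = 0)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(truth_manifest, args)
}

fast_config <- function() {
  cfg <- default_config()
  cfg$nmr$target_points <- 32768L
  cfg
}

fast_fids <- function(flasks, fraction, truth) {
  fids <- lapply(seq_len(nrow(flasks)), function(i) {
    synth_nmr_fid(flasks[i, ], fraction, truth, n_points = 4096L)
  })
  names(fids) <- flasks$sample_id
  fids
}
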
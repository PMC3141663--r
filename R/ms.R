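# MS pre-processing and cross-run alignment: smoothing/denoising and peak
# picking for single traces, correspondence clustering of peak lists across
# runs, and declarative retention-window integration of GC-MS FAME targets.

#' Smooth a trace and zero sub-noise values
#'
#' Savitzky-Golay local-polynomial smoothing followed by noise gating: the
#' noise level sigma is the scaled median absolute deviation (1.4826 x MAD)
#' of the detrended trace, and smoothed values below `k_noise * sigma` are
#' zeroed.
#'
#' @param trace Numeric vector (e.g. an extracted-ion chromatogram).
#' @param window Odd smoothing window length; `1` means identity smoothing.
#' @param poly_order Local polynomial order.
#' @param k_noise Gating threshold in noise-sigma units; `0` disables
#'   gating.
#' @return The smoothed, gated trace.
#' @export
smooth_and_denoise <- function(trace, window = 7L, poly_order = 2L,
                               k_noise = 3) {
  stopifnot(is.numeric(trace), window >= 1L, k_noise >= 0)
  if (window %% 2L == 0L) stop("window must be odd")
  sm <- if (window == 1L) trace else
    as.numeric(signal::sgolayfilt(trace, p = min(poly_order, window - 1L),
                                  n = window))
  sigma <- stats::mad(trace - sm, center = 0)
  if (sigma == 0) sigma <- stats::mad(trace, center = stats::median(trace))
  if (k_noise > 0) sm[sm < k_noise * sigma] <- 0
  sm
}

#' Pick peaks from a trace
#'
#' Local maxima above `k_noise * sigma` (sigma as in
#' [smooth_and_denoise()]); apex positions are refined by 3-point parabolic
#' interpolation.
#'
#' @param trace Numeric intensity vector.
#' @param x Positions (retention time/index) of the trace samples; defaults
#'   to the sample index.
#' @param k_noise Threshold in noise-sigma units.
#' @param window,poly_order Smoothing applied before picking.
#' @return A `peak_list` data.frame (mz = NA, rt = apex position,
#'   intensity = apex height).
#' @export
pick_peaks <- function(trace, x = seq_along(trace), k_noise = 3,
                       window = 7L, poly_order = 2L) {
  stopifnot(length(x) == length(trace))
  sm <- if (window > 1L)
    as.numeric(signal::sgolayfilt(trace, p = min(poly_order, window - 1L),
                                  n = window)) else trace
  sigma <- stats::mad(trace - sm, center = 0)
  thr <- k_noise * sigma
  n <- length(sm)
  if (n < 3L) return(.empty_peaks())
  is_max <- c(FALSE, sm[2:(n - 1L)] > sm[1:(n - 2L)] &
                sm[2:(n - 1L)] >= sm[3:n], FALSE) & sm > thr
  idx <- which(is_max)
  if (length(idx) == 0L) return(.empty_peaks())
  apex_x <- numeric(length(idx))
  apex_y <- numeric(length(idx))
  for (j in seq_along(idx)) {
    k <- idx[j]
    y1 <- sm[k - 1L]; y2 <- sm[k]; y3 <- sm[k + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
    apex_x[j] <- x[k] + delta * (x[min(k + 1L, n)] - x[k])
    apex_y[j] <- y2 - 0.25 * (y1 - y3) * delta
  }
  structure(data.frame(mz = NA_real_, rt = apex_x, intensity = apex_y),
            class = c("peak_list", "data.frame"))
}

.empty_peaks <- function() {
  structure(data.frame(mz = numeric(0), rt = numeric(0),
                       intensity = numeric(0)),
            class = c("peak_list", "data.frame"))
}

#' Align peak lists across runs into a feature matrix
#'
#' Three steps: (1) landmark peaks — present in at least `landmark_frac` of
#' runs at high intensity — fit a per-run linear retention-time correction
#' (a monotone map for the drift magnitudes chromatography produces);
#' (2) corrected peaks are pooled and greedily clustered in order of
#' descending intensity, absorbing at most one peak per run within `mz_tol`
#' and `rt_tol`; (3) the matrix cell is the peak intensity, or missing when
#' a run contributed no peak.
#'
#' @param peaklists List of `peak_list` objects of one platform.
#' @param mz_tol m/z tolerance in Da (or retention-index units for GC-MS).
#' @param rt_tol Retention-time tolerance. Zero tolerances disable matching
#'   so the feature count equals the total peak count.
#' @param landmark_frac Fraction of runs a landmark must appear in.
#' @return A [feature_matrix] (platform from the peak lists).
#' @export
align_runs <- function(peaklists, mz_tol = 0.005, rt_tol = 0.1,
                       landmark_frac = 0.8) {
  stopifnot(is.list(peaklists), length(peaklists) >= 1L)
  if (mz_tol < 0 || rt_tol < 0) stop("tolerances must be non-negative")
  platforms <- unique(vapply(peaklists, function(p)
    attr(p, "platform") %||% "", character(1)))
  if (length(platforms) > 1L) {
    stop("mixed platforms: ", paste(platforms, collapse = ", "))
  }
  run_ids <- vapply(seq_along(peaklists), function(i)
    attr(peaklists[[i]], "run_id") %||% paste0("run", i), character(1))
  nrun <- length(peaklists)

  # (1) retention-time correction against the first run's strong peaks
  rt_corr <- lapply(seq_len(nrun), function(i) identity)
  if (nrun >= 2L && rt_tol > 0) {
    ref <- peaklists[[1L]]
    strong <- ref[ref$intensity >= stats::quantile(ref$intensity, 0.5), ,
                  drop = FALSE]
    pairs <- lapply(seq_len(nrun), function(i) {
      run <- peaklists[[i]]
      hit_rt <- rep(NA_real_, nrow(strong))
      for (k in seq_len(nrow(strong))) {
        cand <- which(abs(run$mz - strong$mz[k]) <= mz_tol &
                        abs(run$rt - strong$rt[k]) <= 5 * rt_tol)
        if (length(cand)) {
          hit_rt[k] <- run$rt[cand[which.min(abs(run$rt[cand] -
                                                   strong$rt[k]))]]
        }
      }
      hit_rt
    })
    found <- rowSums(!is.na(do.call(cbind, pairs)))
    landmark <- found >= landmark_frac * nrun
    if (sum(landmark) >= 3L) {
      for (i in seq_len(nrun)) {
        ok <- landmark & !is.na(pairs[[i]])
        if (sum(ok) >= 3L) {
          fit <- stats::lm(strong$rt[ok] ~ pairs[[i]][ok])
          b <- stats::coef(fit)
          if (is.finite(b[2]) && b[2] > 0) {  # keep the map monotone
            rt_corr[[i]] <- local({
              a0 <- b[1]; a1 <- b[2]
              function(rt) a0 + a1 * rt
            })
          }
        }
      }
    }
  }

  pooled <- do.call(rbind, lapply(seq_len(nrun), function(i) {
    p <- as.data.frame(peaklists[[i]])
    if (nrow(p) == 0L) return(NULL)
    p$rt <- rt_corr[[i]](p$rt)
    p$run <- i
    p
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(feature_matrix(matrix(numeric(0), 0, nrun,
                                 dimnames = list(NULL, run_ids)),
                          data.frame(mz = numeric(0), rt = numeric(0)),
                          platform = platforms %||% "lcms"))
  }

  # (2) greedy descending-intensity correspondence clustering
  ord <- order(-pooled$intensity)
  assigned <- rep(FALSE, nrow(pooled))
  feat_of <- rep(NA_integer_, nrow(pooled))
  nfeat <- 0L
  for (p in ord) {
    if (assigned[p]) next
    nfeat <- nfeat + 1L
    cand <- which(!assigned &
                    abs(pooled$mz - pooled$mz[p]) <= mz_tol &
                    abs(pooled$rt - pooled$rt[p]) <= rt_tol)
    # at most one peak per run: keep the closest in rt
    keep <- vapply(split(cand, pooled$run[cand]), function(ix) {
      ix[which.min(abs(pooled$rt[ix] - pooled$rt[p]))]
    }, integer(1))
    assigned[keep] <- TRUE
    feat_of[keep] <- nfeat
  }

  # (3) build the matrix
  vals <- matrix(NA_real_, nfeat, nrun, dimnames = list(NULL, run_ids))
  for (p in seq_len(nrow(pooled))) {
    vals[feat_of[p], pooled$run[p]] <- pooled$intensity[p]
  }
  agg <- function(v) {
    w <- pooled$intensity
    vapply(seq_len(nfeat), function(f) {
      ix <- which(feat_of == f)
      sum(v[ix] * w[ix]) / sum(w[ix])
    }, numeric(1))
  }
  desc <- data.frame(mz = agg(pooled$mz), rt = agg(pooled$rt))
  ord2 <- order(desc$mz, desc$rt)
  feature_matrix(vals[ord2, , drop = FALSE], desc[ord2, , drop = FALSE],
                 platform = if (length(platforms)) platforms else "lcms")
}

#' Integrate named GC-MS fatty-acid targets
#'
#' Sums peak intensity inside each named retention window (the declarative
#' replacement for manual integration of identified FAME peaks). Windows
#' must not overlap. A window with no peaks integrates to 0 and is flagged.
#'
#' @param gc_peaklist A GC-MS `peak_list` whose `mz` column holds retention
#'   indices.
#' @param target_windows data.frame with columns name, lo, hi (retention
#'   index units).
#' @return Named numeric vector of integrals; absent targets are flagged in
#'   `attr(, "absent")`.
#' @export
integrate_fame_targets <- function(gc_peaklist, target_windows) {
  stopifnot(all(c("name", "lo", "hi") %in% names(target_windows)))
  if (any(target_windows$lo >= target_windows$hi)) {
    stop("invalid window (lo >= hi)")
  }
  tw <- target_windows[order(target_windows$lo), ]
  if (nrow(tw) > 1L && any(tw$lo[-1L] < tw$hi[-nrow(tw)])) {
    stop("overlapping target windows")
  }
  out <- vapply(seq_len(nrow(target_windows)), function(i) {
    inside <- gc_peaklist$mz >= target_windows$lo[i] &
      gc_peaklist$mz <= target_windows$hi[i]
    sum(gc_peaklist$intensity[inside])
  }, numeric(1))
  names(out) <- target_windows$name
  attr(out, "absent") <- names(out)[out == 0]
  out
}

#' Default FAME retention windows
#'
#' One window per species of the packaged FAME table, centred on its
#' retention index.
#'
#' @param half_width Window half-width in retention-index units.
#' @export
fame_target_windows <- function(half_width = 2.5) {
  tab <- fame_table()
  data.frame(name = tab$name, lo = tab$retention_index - half_width,
             hi = tab$retention_index + half_width)
}
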
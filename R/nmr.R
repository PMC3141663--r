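# 1D 1H-NMR processing: apodization, zero filling, Fourier transformation,
# automatic phasing, asymmetric-least-squares baseline correction, ppm
# calibration, and segment-wise alignment of many spectra into a binned
# feature matrix.

#' Squared sine-bell apodization (shifted pi/2)
#'
#' Multiplies FID sample i (0-based) by `cos^2(pi * i / (2 * (N - 1)))`, so
#' the first point keeps weight 1 and the last is zeroed.
#'
#' @param fid A [fid_record].
#' @return The apodized [fid_record].
#' @export
apodize <- function(fid) {
  stopifnot(inherits(fid, "fid_record"))
  n <- fid$npoints
  if (n < 2L) stop("FID too short to apodize")
  i <- seq_len(n) - 1L
  w <- cos(pi * i / (2 * (n - 1)))^2
  fid$data <- fid$data * w
  fid
}

#' Zero-fill an FID
#'
#' Appends zeros up to `target_points` (default 128 K) before Fourier
#' transformation; the acquired samples are untouched.
#'
#' @param fid A [fid_record].
#' @param target_points Total length after filling.
#' @return A [fid_record] of length `target_points`.
#' @export
zero_fill <- function(fid, target_points = 131072L) {
  stopifnot(inherits(fid, "fid_record"))
  if (target_points < fid$npoints) {
    stop("target_points (", target_points, ") smaller than FID length (",
         fid$npoints, ")")
  }
  if (target_points > fid$npoints) {
    fid$data <- c(fid$data, complex(real = rep(0, target_points - fid$npoints)))
    fid$npoints <- length(fid$data)
  }
  fid
}

#' Fourier-transform an FID into a ppm-axis spectrum
#'
#' Discrete Fourier transform with the frequency axis converted to ppm via
#' the observe frequency and the carrier position. The complex spectrum is
#' retained for phasing; the intensity slot holds the real part.
#'
#' @param fid A [fid_record].
#' @return A [spectrum1d] with a descending ppm axis.
#' @export
transform_fid <- function(fid) {
  stopifnot(inherits(fid, "fid_record"))
  n <- fid$npoints
  x <- fid$data
  x[1] <- x[1] / 2   # first-point scaling: removes the s(0)/2 DC offset
  S <- stats::fft(x)
  half <- n %/% 2
  S <- S[c((half + 1L):n, 1:half)]            # fftshift
  freq <- (seq_len(n) - 1L - half) * fid$sw / n
  ppm <- fid$ppm_center + freq / fid$obs_freq
  ord <- rev(seq_len(n))                      # descending ppm convention
  spectrum1d(ppm[ord], Re(S)[ord], complex_values = S[ord],
             obs_freq = fid$obs_freq, meta = fid$meta)
}

#' Automatic phase correction
#'
#' Chooses zero- and first-order phase to minimize the negative-area penalty
#' of the real part (sum of squared negative intensities). If the
#' optimization fails the magnitude spectrum is returned with
#' `meta$phase_mode = "magnitude"` and a warning.
#'
#' @param spectrum A [spectrum1d] carrying complex values.
#' @param decimate Evaluate the penalty on every `decimate`-th point for
#'   speed; the final correction is applied at full resolution.
#' @return The phased [spectrum1d]; applied angles (degrees) in
#'   `meta$phi0_deg` / `meta$phi1_deg`.
#' @export
auto_phase <- function(spectrum, decimate = 8L) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  S <- spectrum$complex_values
  if (is.null(S)) {
    warning("no complex values: returning magnitude spectrum")
    spectrum$intensity <- abs(spectrum$intensity)
    spectrum$meta$phase_mode <- "magnitude"
    return(spectrum)
  }
  n <- length(S)
  idx <- seq(1L, n, by = max(1L, as.integer(decimate)))
  Sd <- S[idx]
  xd <- (idx - 1) / (n - 1)
  scale <- max(Mod(Sd))
  if (scale == 0) scale <- 1
  penalty <- function(par) {
    re <- Re(Sd * exp(1i * (par[1] + par[2] * xd)))
    sum(pmin(re, 0)^2) / scale^2
  }
  fit <- tryCatch(
    stats::optim(c(0, 0), penalty, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("phase optimization failed: returning magnitude spectrum")
    spectrum$intensity <- Mod(S)
    spectrum$meta$phase_mode <- "magnitude"
    return(spectrum)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  corrected <- S * exp(1i * (fit$par[1] + fit$par[2] * x))
  spectrum$complex_values <- corrected
  spectrum$intensity <- Re(corrected)
  spectrum$meta$phase_mode <- "auto"
  spectrum$meta$phi0_deg <- fit$par[1] * 180 / pi
  spectrum$meta$phi1_deg <- fit$par[2] * 180 / pi
  spectrum
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline by iteratively reweighted penalized least
#' squares (Eilers-Boelens): points above the current baseline get weight
#' `asymmetry`, points below get `1 - asymmetry`, with a second-difference
#' roughness penalty. For long spectra the baseline is estimated on a
#' block-mean grid of at most `max_nodes` nodes and interpolated back, which
#' changes peak apexes by well under the 5% the pipeline tolerates.
#'
#' @param spectrum A [spectrum1d].
#' @param smoothness Roughness penalty lambda on the (possibly decimated)
#'   baseline grid.
#' @param asymmetry Weight for points above the baseline, in (0, 0.5).
#' @param max_nodes Maximum baseline grid size.
#' @param iterations Reweighting iterations.
#' @return The baseline-subtracted [spectrum1d]; the removed baseline is in
#'   `meta$baseline` only if `keep_baseline = TRUE`.
#' @param keep_baseline Store the subtracted baseline in the metadata.
#' @export
baseline_correct <- function(spectrum, smoothness = 1e4, asymmetry = 0.05,
                             max_nodes = 2048L, iterations = 8L,
                             keep_baseline = FALSE) {
  stopifnot(inherits(spectrum, "spectrum1d"), asymmetry > 0, asymmetry < 0.5)
  y <- spectrum$intensity
  n <- length(y)
  d <- max(1L, ceiling(n / max_nodes))
  if (d > 1L) {
    # lower-envelope decimation: block minima suppress narrow peaks at the
    # node scale while broad baseline structure survives, so the penalized
    # fit can follow humps without eating peak apexes
    m <- ceiling(n / d)
    pad <- m * d - n
    blocks <- matrix(c(y, rep(NA_real_, pad)), nrow = d)
    yd <- suppressWarnings(apply(blocks, 2L, min, na.rm = TRUE))
    # widen the envelope past the Lorentzian peak base so flank tails do
    # not masquerade as baseline
    r <- 5L
    ydr <- yd
    for (k in seq_len(r)) {
      ydr <- pmin(ydr, c(yd[-seq_len(k)], rep(yd[m], k)),
                  c(rep(yd[1], k), yd[seq_len(m - k)]))
    }
    yd <- ydr
    centers <- pmin((seq_len(m) - 0.5) * d + 0.5, n)
  } else {
    m <- n
    yd <- y
    centers <- seq_len(n)
  }
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- yd
  for (it in seq_len(iterations)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + P, w * yd))
    w_new <- ifelse(yd > z, asymmetry, 1 - asymmetry)
    if (all(w_new == w)) break
    w <- w_new
  }
  baseline <- if (d > 1L) {
    stats::approx(centers, z, xout = seq_len(n), rule = 2)$y
  } else z
  spectrum$intensity <- y - baseline
  if (!is.null(spectrum$complex_values)) {
    spectrum$complex_values <- spectrum$complex_values - baseline
  }
  if (keep_baseline) spectrum$meta$baseline <- baseline
  spectrum
}

#' Calibrate the ppm axis on a reference signal
#'
#' Shifts the axis so the detected reference apex (parabolically
#' interpolated) sits at its nominal position: TMSP at 0.00 ppm for the
#' polar fraction, residual CHCl3 at 7.26 ppm for the apolar fraction.
#'
#' @param spectrum A [spectrum1d].
#' @param reference `"tmsp"`, `"chcl3"`, or a numeric nominal ppm.
#' @param search_width Half-width of the search window in ppm.
#' @param min_snr Reference apex must exceed `min_snr` times the robust
#'   noise level (MAD) of the spectrum, else an error is raised.
#' @return The calibrated [spectrum1d]; applied shift in `meta$ppm_shift`.
#' @export
calibrate_ppm <- function(spectrum, reference = "tmsp", search_width = 0.1,
                          min_snr = 10) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  nominal <- if (is.numeric(reference)) reference else
    switch(reference, tmsp = 0.0, chcl3 = 7.26,
           stop("unknown reference: ", reference))
  win <- which(abs(spectrum$ppm - nominal) <= search_width)
  if (length(win) < 3L) stop("reference search window outside the axis")
  noise <- stats::mad(spectrum$intensity, center = 0)
  k <- win[which.max(spectrum$intensity[win])]
  if (spectrum$intensity[k] <= 0 ||
      spectrum$intensity[k] < min_snr * noise) {
    stop("reference peak not found within the search window around ",
         nominal, " ppm")
  }
  apex <- spectrum$ppm[k]
  if (k > 1L && k < length(spectrum$ppm)) {   # 3-point parabolic apex
    y1 <- spectrum$intensity[k - 1L]
    y2 <- spectrum$intensity[k]
    y3 <- spectrum$intensity[k + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      apex <- apex + delta * (spectrum$ppm[k + 1L] - spectrum$ppm[k])
    }
  }
  shift <- nominal - apex
  spectrum$ppm <- spectrum$ppm + shift
  spectrum$meta$ppm_shift <- shift
  spectrum
}

#' Segment-wise alignment and binning of calibrated spectra
#'
#' For each spectrum, each ppm segment is shifted by the integer lag (within
#' `max_shift_ppm`) that maximizes its cross-correlation with the median
#' spectrum; the shifted spectra are then integrated into fixed ppm bins.
#' Solvent and reference windows can be masked out of the matrix.
#'
#' @param spectra List of at least 2 [spectrum1d] objects on identical axes.
#' @param bin_width_ppm Bin width (half-open bins).
#' @param segment_width_ppm Width of independently shifted segments.
#' @param max_shift_ppm Maximum allowed per-segment shift; 0 disables
#'   shifting (pure binning).
#' @param exclude_windows List of `c(lo, hi)` ppm windows dropped from the
#'   output (e.g. water 4.7-5.0 for the polar fraction, the CHCl3 window for
#'   the apolar fraction).
#' @param sample_ids Column names; defaults to each spectrum's
#'   `meta$sample_id` or `S1..Sn`.
#' @param fraction Provenance tag stored on the matrix.
#' @return A [feature_matrix] (platform `"nmr"`) whose cells are bin areas;
#'   descriptors are bin lo/hi/centre ppm.
#' @export
align_spectra <- function(spectra, bin_width_ppm = 0.005,
                          segment_width_ppm = 0.1, max_shift_ppm = 0.02,
                          exclude_windows = NULL, sample_ids = NULL,
                          fraction = NA_character_) {
  stopifnot(is.list(spectra), length(spectra) >= 1L, bin_width_ppm > 0)
  ppm <- spectra[[1]]$ppm
  for (s in spectra) {
    if (length(s$ppm) != length(ppm) ||
        max(abs(s$ppm - ppm)) > bin_width_ppm / 2) {
      stop("spectra are not on compatible ppm axes")
    }
  }
  n <- length(ppm)
  dppm <- abs(ppm[2] - ppm[1])
  mat <- vapply(spectra, function(s) s$intensity, numeric(n))
  max_lag <- floor(max_shift_ppm / dppm)
  if (max_lag > 0L && length(spectra) >= 2L) {
    ref <- apply(mat, 1L, stats::median)
    seg_pts <- max(8L, round(segment_width_ppm / dppm))
    starts <- seq(1L, n, by = seg_pts)
    for (j in seq_len(ncol(mat))) {
      x <- mat[, j]
      out <- x
      for (st in starts) {
        en <- min(st + seg_pts - 1L, n)
        lag <- .best_lag(x, ref, st, en, max_lag)
        if (lag != 0L) {
          src <- pmin(pmax(st:en + lag, 1L), n)
          out[st:en] <- x[src]
        }
      }
      mat[, j] <- out
    }
  }
  # fixed half-open bins [lo, hi) laid out over the ascending ppm range
  lo <- min(ppm)
  bin_idx <- floor((ppm - lo) / bin_width_ppm)
  nbins <- max(bin_idx) + 1L
  binned <- rowsum(mat * dppm, group = bin_idx, reorder = TRUE)
  bin_lo <- lo + as.numeric(rownames(binned)) * bin_width_ppm
  keep <- rep(TRUE, nrow(binned))
  for (w in exclude_windows) {
    keep <- keep & !(bin_lo + bin_width_ppm > w[1] & bin_lo < w[2])
  }
  binned <- binned[keep, , drop = FALSE]
  bin_lo <- bin_lo[keep]
  ord <- order(bin_lo, decreasing = TRUE)   # descending ppm convention
  binned <- binned[ord, , drop = FALSE]
  bin_lo <- bin_lo[ord]
  if (is.null(sample_ids)) {
    sample_ids <- vapply(seq_along(spectra), function(i) {
      spectra[[i]]$meta$sample_id %||% paste0("S", i)
    }, character(1))
  }
  colnames(binned) <- sample_ids
  rownames(binned) <- NULL
  desc <- data.frame(ppm_lo = bin_lo, ppm_hi = bin_lo + bin_width_ppm,
                     ppm_center = bin_lo + bin_width_ppm / 2)
  feature_matrix(binned, desc, platform = "nmr", fraction = fraction)
}

# Integer lag in [-max_lag, max_lag] maximizing cross-correlation of
# x[st:en] (shifted) against ref[st:en], via FFT.
.best_lag <- function(x, ref, st, en, max_lag) {
  n <- length(x)
  lo <- max(1L, st - max_lag)
  hi <- min(n, en + max_lag)
  a <- x[lo:hi]
  b <- numeric(hi - lo + 1L)
  b[(st - lo + 1L):(en - lo + 1L)] <- ref[st:en]
  L <- stats::nextn(length(a), 2)
  fa <- stats::fft(c(a, rep(0, L - length(a))))
  fb <- stats::fft(c(b, rep(0, L - length(b))))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  # circular lag k (a advanced by k relative to b): cc index k+1 for k >= 0,
  # L + 1 + k for k < 0
  lags <- -max_lag:max_lag
  vals <- cc[ifelse(lags >= 0, lags + 1L, L + 1L + lags)]
  lags[which.max(vals)]
}

#' Process a raw FID into a calibrated spectrum
#'
#' Convenience chain: [apodize()], [zero_fill()], [transform_fid()],
#' [auto_phase()], [baseline_correct()], [calibrate_ppm()].
#'
#' @param fid A [fid_record].
#' @param reference Calibration reference passed to [calibrate_ppm()];
#'   `NULL` skips calibration.
#' @param target_points Zero-fill length.
#' @param smoothness,asymmetry Baseline parameters.
#' @return A processed [spectrum1d].
#' @export
process_fid <- function(fid, reference = "tmsp", target_points = 131072L,
                        smoothness = 1e4, asymmetry = 0.05) {
  sp <- transform_fid(zero_fill(apodize(fid), target_points))
  sp <- auto_phase(sp)
  sp <- baseline_correct(sp, smoothness = smoothness, asymmetry = asymmetry)
  if (!is.null(reference)) sp <- calibrate_ppm(sp, reference)
  sp
}
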
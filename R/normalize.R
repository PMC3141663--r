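# Internal-standard normalization. The residual CHCl3 proton of the apolar
# NMR solvent is an absolute internal standard (same deuterated solvent for
# every flask); the glycerophospholipid backbone signal (PL, 5.17-5.24 ppm)
# is proportional to membrane amount and hence cell number. The per-flask
# PL/CHCl3 ratio therefore removes the cell-number confounder from every
# platform measured on that flask. GC-MS FAME profiles are instead scaled by
# the summed raw AA + DHA integrals, which track PL.

#' Trapezoidal integral of a spectrum over a ppm window
#'
#' @param spectrum A [spectrum1d].
#' @param lo_ppm,hi_ppm Window bounds, `lo_ppm < hi_ppm`, inside the axis.
#' @return The trapezoidal area of the real intensities over `[lo, hi)`.
#' @export
integrate_region <- function(spectrum, lo_ppm, hi_ppm) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (lo_ppm >= hi_ppm) stop("lo_ppm must be below hi_ppm")
  rng <- range(spectrum$ppm)
  if (lo_ppm < rng[1] || hi_ppm > rng[2]) {
    stop("integration window [", lo_ppm, ", ", hi_ppm,
         "] outside the ppm axis")
  }
  inside <- spectrum$ppm >= lo_ppm & spectrum$ppm < hi_ppm
  if (sum(inside) < 2L) stop("integration window contains < 2 points")
  x <- spectrum$ppm[inside]
  y <- spectrum$intensity[inside]
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Total-signal to CHCl3 ratio of an apolar spectrum
#'
#' Sum of the integrals over all 22 assignment windows of the apolar
#' fraction (TS, total signals) divided by the residual CHCl3 integral —
#' an estimate of total lipid per flask on an absolute scale.
#'
#' @param apolar_spectrum A processed apolar [spectrum1d].
#' @param signal_table Assignment windows (columns lo_ppm, hi_ppm).
#' @param chcl3_window CHCl3 integration window in ppm.
#' @return The TS/CHCl3 ratio.
#' @export
ts_over_chcl3 <- function(apolar_spectrum,
                          signal_table = apolar_assignments(),
                          chcl3_window = c(7.20, 7.32)) {
  chcl3 <- integrate_region(apolar_spectrum, chcl3_window[1],
                            chcl3_window[2])
  if (chcl3 <= 0) stop("CHCl3 integral is not positive")
  ts <- sum(vapply(seq_len(nrow(signal_table)), function(i) {
    integrate_region(apolar_spectrum, signal_table$lo_ppm[i],
                     signal_table$hi_ppm[i])
  }, numeric(1)))
  ts / chcl3
}

#' Phospholipid to CHCl3 ratio (the normalization factor)
#'
#' Integral of the glycerophospholipid backbone signal (5.17-5.24 ppm)
#' divided by the residual CHCl3 integral. Proportional to the number of
#' cells in the flask; dividing any platform's intensities by it removes
#' the cell-number confounder.
#'
#' @param apolar_spectrum A processed apolar [spectrum1d].
#' @param pl_window PL integration window in ppm.
#' @param chcl3_window CHCl3 integration window in ppm.
#' @return The PL/CHCl3 factor (positive).
#' @export
pl_over_chcl3 <- function(apolar_spectrum, pl_window = c(5.17, 5.24),
                          chcl3_window = c(7.20, 7.32)) {
  chcl3 <- integrate_region(apolar_spectrum, chcl3_window[1],
                            chcl3_window[2])
  if (chcl3 <= 0) stop("CHCl3 integral is not positive")
  pl <- integrate_region(apolar_spectrum, pl_window[1], pl_window[2])
  if (pl <= 0) stop("no PL signal in ", pl_window[1], "-", pl_window[2],
                    " ppm")
  pl / chcl3
}

#' Per-flask normalization factors from apolar spectra
#'
#' @param apolar_spectra Named list of processed apolar [spectrum1d]s (names
#'   are flask ids).
#' @param ... Passed to [ts_over_chcl3()] and [pl_over_chcl3()].
#' @return data.frame with flask, ts_over_chcl3, pl_over_chcl3.
#' @export
normalization_factors <- function(apolar_spectra, ...) {
  stopifnot(is.list(apolar_spectra), !is.null(names(apolar_spectra)))
  data.frame(
    flask = names(apolar_spectra),
    ts_over_chcl3 = vapply(apolar_spectra, ts_over_chcl3, numeric(1), ...),
    pl_over_chcl3 = vapply(apolar_spectra, pl_over_chcl3, numeric(1)),
    row.names = NULL)
}

#' Normalize a feature matrix by per-flask PL/CHCl3 factors
#'
#' Each sample column is divided by its flask's factor; the factors come
#' from the apolar spectra of the same flasks, so polar NMR and LC-MS
#' matrices are normalized with factors from the paired apolar fractions.
#' Missing cells stay missing.
#'
#' @param matrix A [feature_matrix].
#' @param factors Either a named numeric vector of factors or a data.frame
#'   with columns `flask` and `pl_over_chcl3`.
#' @param pairing Optional named character vector mapping matrix sample ids
#'   to flask ids; defaults to the identity (sample id = flask id).
#' @return The normalized [feature_matrix].
#' @export
normalize_matrix <- function(matrix, factors, pairing = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.data.frame(factors)) {
    factors <- stats::setNames(factors$pl_over_chcl3, factors$flask)
  }
  ids <- fm_samples(matrix)
  flask <- if (is.null(pairing)) ids else unname(pairing[ids])
  if (anyNA(flask)) {
    stop("no flask pairing for sample(s): ",
         paste(ids[is.na(flask)], collapse = ", "))
  }
  f <- factors[flask]
  if (anyNA(f)) {
    stop("no normalization factor for flask(s): ",
         paste(unique(flask[is.na(f)]), collapse = ", "))
  }
  if (any(f <= 0)) stop("normalization factors must be positive")
  matrix$values <- sweep(matrix$values, 2L, f, `/`)
  matrix
}

#' Normalize GC-MS FAME integrals by the AA + DHA sum
#'
#' Each flask's fatty-acid integrals are divided by that flask's raw
#' (pre-normalization) sum of the arachidonic (C20:4) and docosahexaenoic
#' (C22:6) methyl-ester integrals, which are per-cell constant and so play
#' the role the PL signal plays for the other platforms. PL/CHCl3 factors
#' are never applied to GC-MS data.
#'
#' @param integrals_by_flask Numeric matrix of raw integrals, species in
#'   rows (named), flasks in columns; or a [feature_matrix] whose
#'   descriptors carry a `name` column.
#' @param aa_name,dha_name Row names of the two anchor species.
#' @return A [feature_matrix] (platform `"gcms"`) of normalized profiles.
#' @export
gc_normalize <- function(integrals_by_flask, aa_name = "C20:4 (AA)",
                         dha_name = "C22:6 (DHA)") {
  if (inherits(integrals_by_flask, "feature_matrix")) {
    vals <- fm_values(integrals_by_flask)
    rownames(vals) <- fm_descriptors(integrals_by_flask)$name
  } else {
    vals <- as.matrix(integrals_by_flask)
  }
  if (!all(c(aa_name, dha_name) %in% rownames(vals))) {
    stop("AA and DHA integrals are required for GC-MS normalization")
  }
  denom <- vals[aa_name, ] + vals[dha_name, ]
  denom[is.na(denom)] <- 0
  if (any(denom <= 0)) {
    stop("AA + DHA integral not positive for flask(s): ",
         paste(colnames(vals)[denom <= 0], collapse = ", "))
  }
  out <- sweep(vals, 2L, denom, `/`)
  feature_matrix(out, data.frame(name = rownames(vals)),
                 platform = "gcms", fraction = "apolar")
}
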
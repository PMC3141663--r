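# Core data containers: FID records, 1D spectra, feature matrices.

#' Create a free-induction-decay record
#'
#' Time-domain complex NMR trace plus the acquisition metadata needed to map
#' the Fourier-transformed axis to ppm.
#'
#' @param data Complex vector of time-domain samples.
#' @param sw Spectral width in Hz.
#' @param obs_freq Observe (spectrometer) frequency in MHz.
#' @param ppm_center Chemical shift at the centre of the spectral window.
#' @param meta Named list of acquisition metadata (relaxation delay, scans,
#'   sample id, ...).
#' @return An object of class `fid_record`.
#' @export
fid_record <- function(data, sw = 5000, obs_freq = 400.13, ppm_center = 5.5,
                       meta = list()) {
  data <- as.complex(data)
  if (length(data) < 2L) stop("an FID needs at least 2 points")
  if (sw <= 0) stop("spectral width must be positive")
  structure(list(data = data, npoints = length(data), sw = sw,
                 obs_freq = obs_freq, ppm_center = ppm_center, meta = meta),
            class = "fid_record")
}

#' @export
print.fid_record <- function(x, ...) {
  cat(sprintf("<fid_record: %d points, sw %.0f Hz, %.2f MHz>\n",
              x$npoints, x$sw, x$obs_freq))
  invisible(x)
}

#' Create a 1D spectrum
#'
#' @param ppm Strictly monotone (descending by convention) ppm axis.
#' @param intensity Real intensities; same length as `ppm`.
#' @param complex_values Optional complex spectrum kept for phasing.
#' @param obs_freq Observe frequency in MHz.
#' @param meta Named metadata list.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, complex_values = NULL,
                       obs_freq = 400.13, meta = list()) {
  stopifnot(length(ppm) == length(intensity), length(ppm) >= 2L)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 complex_values = complex_values, obs_freq = obs_freq,
                 meta = meta),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d: %d points, %.2f to %.2f ppm>\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Create a feature matrix
#'
#' The aligned features-by-samples intensity table all downstream statistics
#' run on. Cells may be `NA`: an MS feature absent from a run is missing, not
#' zero.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param descriptors data.frame of per-feature descriptors (ppm bin centre
#'   and width for NMR; m/z and retention time or retention index for MS),
#'   one row per feature, jointly unique.
#' @param platform One of `"nmr"`, `"lcms"`, `"gcms"`.
#' @param fraction `"apolar"`, `"polar"` or `NA`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, platform = "nmr",
                           fraction = NA_character_) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(descriptors), nrow(descriptors) == nrow(values))
  if (is.null(colnames(values))) stop("sample ids (column names) required")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyDuplicated(descriptors)) stop("duplicate feature descriptors")
  structure(list(values = values, descriptors = descriptors,
                 platform = platform, fraction = fraction),
            class = "feature_matrix")
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
fm_values <- function(x) x$values

#' @rdname feature_matrix
#' @export
fm_descriptors <- function(x) x$descriptors

#' @rdname feature_matrix
#' @export
fm_samples <- function(x) colnames(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d features x %d samples [%s%s]>\n",
              nrow(x$values), ncol(x$values), x$platform,
              if (is.na(x$fraction)) "" else paste0("/", x$fraction)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write a feature matrix as a tab-separated table
#'
#' Features are rows; the descriptor columns come first, then one column per
#' sample. Missing cells are written as empty fields. Platform, fraction and
#' the number of descriptor columns are recorded in `#`-comment header lines
#' so the file round-trips through [read_feature_table()].
#'
#' @param matrix A [feature_matrix].
#' @param path Output file path.
#' @export
write_feature_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# platform: %s", matrix$platform),
               sprintf("# fraction: %s", matrix$fraction),
               sprintf("# n_descriptors: %d", ncol(matrix$descriptors))), con)
  tab <- cbind(matrix$descriptors,
               as.data.frame(matrix$values, check.names = FALSE))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_table()]
#'
#' @param path File path.
#' @return A [feature_matrix].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA_character_) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0L) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  platform <- get("platform", "nmr")
  fraction <- get("fraction")
  if (identical(fraction, "NA")) fraction <- NA_character_
  nd <- as.integer(get("n_descriptors", "1"))
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L) stop("no header row in feature table: ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_hdr <- length(fields[[1]])
  nfield <- lengths(fields)
  if (any(nfield > ncol_hdr)) {
    stop("ragged row in feature table: line ",
         which(nfield > ncol_hdr)[1] + length(hdr))
  }
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(tab))) stop("duplicate sample ids in ", path)
  desc <- tab[, seq_len(nd), drop = FALSE]
  vals <- as.matrix(tab[, setdiff(seq_along(tab), seq_len(nd)), drop = FALSE])
  storage.mode(vals) <- "double"
  feature_matrix(vals, desc, platform = platform, fraction = fraction)
}
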
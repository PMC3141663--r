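# Exact monoisotopic mass arithmetic for positive-mode adduct annotation.
#
# Masses are lightest-isotope atomic masses; the proton mass used for adducts
# is the H-atom mass minus the electron mass, which is required to reproduce
# sub-mDa deviations of high-resolution Orbitrap data.

.ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307400,
  O = 15.99491462,
  P = 30.97376200,
  S = 31.97207117
)

.ELECTRON_MASS <- 0.00054858
.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS
.NH3_MASS <- .ATOMIC_MASS[["N"]] + 3 * .ATOMIC_MASS[["H"]]

#' Parse a molecular formula into element counts
#'
#' Accepts plain formulas such as `"C5H9NO2"` over the elements C, H, N, O,
#' P and S. An element symbol without a number has an implicit count of 1.
#' Repeated element symbols are summed.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C5H9NO2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("[\\s_]", "", text, perl = TRUE)
  if (!nzchar(text)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: ", text)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!sym %in% names(.ATOMIC_MASS)) {
      stop("unknown element symbol '", sym, "' in formula ", text)
    }
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (n == 0L) stop("zero count for element ", sym, " in formula ", text)
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  counts
}

#' Monoisotopic mass of a formula
#'
#' @param counts Named element counts as returned by [parse_formula()], or a
#'   formula string.
#' @return Monoisotopic (lightest-isotope) mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  stopifnot(length(counts) >= 1L, all(names(counts) %in% names(.ATOMIC_MASS)))
  sum(.ATOMIC_MASS[names(counts)] * as.numeric(counts))
}

#' Theoretical m/z of a singly charged positive adduct
#'
#' Supported adducts are `[M+H]+` and `[M+NH4]+` (written `"M+H"` and
#' `"M+NH4"`). The electron mass is subtracted from the added H atom, so the
#' proton contributes 1.00727645 Da.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct `"M+H"` or `"M+NH4"`.
#' @return Theoretical m/z in Da (charge 1).
#' @examples
#' adduct_mz(monoisotopic_mass("C5H9NO2"), "M+H")
#' @export
adduct_mz <- function(neutral_mass, adduct = "M+H") {
  stopifnot(is.numeric(neutral_mass), neutral_mass >= 0)
  switch(adduct,
    "M+H" = neutral_mass + .PROTON_MASS,
    "M+NH4" = neutral_mass + .NH3_MASS + .PROTON_MASS,
    stop("unknown adduct: ", adduct)
  )
}

#' Mass deviation in mDa
#'
#' @param experimental_mz,theoretical_mz m/z values in Da.
#' @return `(experimental - theoretical) * 1000`, rounded to 3 decimals as
#'   reported by high-resolution instruments.
#' @export
deviation_mDa <- function(experimental_mz, theoretical_mz) {
  round((experimental_mz - theoretical_mz) * 1000, 3)
}
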
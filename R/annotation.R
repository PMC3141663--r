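# Reference tables and exact-mass / chemical-shift annotation.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "metabopipe")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Packaged compound reference table
#'
#' Polar metabolites identified by LC-nanomate-Orbitrap fragmentation, with
#' experimentally observed protonated parent masses, neutral formulas,
#' adducts, printed mass deviations (mDa) and fragment ions. The `verified`
#' flag marks rows whose printed deviation is reproduced (within 0.002 mDa)
#' from the printed formula and parent mass by [deviation_mDa()]; rows where
#' the printed values are internally inconsistent (sign flips, ion instead of
#' neutral formulas) carry `verified = FALSE` and are used for annotation
#' only.
#'
#' @return A data.frame with columns name, parent_mz, formula, adduct,
#'   deviation_mda, fragments, verified, theoretical_mz.
#' @export
compound_table <- function() {
  tab <- utils::read.delim(.extdata("orbitrap_compounds.tsv"),
                           stringsAsFactors = FALSE)
  tab$verified <- as.logical(tab$verified)
  tab$theoretical_mz <- vapply(seq_len(nrow(tab)), function(i) {
    f <- tab$formula[i]
    if (is.na(f) || !nzchar(trimws(f))) return(NA_real_)
    adduct_mz(monoisotopic_mass(parse_formula(f)), tab$adduct[i])
  }, numeric(1))
  tab
}

#' NMR assignment table of the apolar (lipid) fraction
#'
#' The 22 resonance windows of the apolar-fraction proton spectrum with their
#' assignments and the species label used by the synthetic study generator.
#'
#' @return A data.frame with columns signal, lo_ppm, hi_ppm, center_ppm,
#'   assignment, species.
#' @export
apolar_assignments <- function() {
  utils::read.delim(.extdata("nmr_assignments_apolar.tsv"),
                    stringsAsFactors = FALSE)
}

#' NMR assignment table of the polar (aqueous) fraction
#'
#' Each metabolite's proton resonances collapsed to one line position per
#' listed chemical-shift entry; `quant_ppm` is the least-overlapped line used
#' for metabolite-level quantification windows.
#'
#' @return A data.frame with columns signal, assignment, shifts_ppm (a
#'   semicolon-separated list), quant_ppm.
#' @export
polar_assignments <- function() {
  utils::read.delim(.extdata("nmr_assignments_polar.tsv"),
                    stringsAsFactors = FALSE)
}

#' Fatty-acid methyl ester species table for GC-MS
#'
#' FAME species identified in the apolar fraction plus the two
#' polyunsaturated normalization anchors (arachidonic and docosahexaenoic
#' acid methyl esters). The retention index is a strictly increasing function
#' of carbon count (see [fame_retention_index()]); positional/geometric
#' isomers of one chain composition are separated by small fixed offsets.
#'
#' @return A data.frame with columns name, carbons, double_bonds,
#'   variant_offset, retention_index.
#' @export
fame_table <- function() {
  tab <- utils::read.delim(.extdata("fame_species.tsv"),
                           stringsAsFactors = FALSE)
  tab$retention_index <- fame_retention_index(tab$carbons, tab$double_bonds,
                                              tab$variant_offset)
  tab
}

#' Retention index model for fatty-acid methyl esters
#'
#' `100 * carbons + 20 * double_bonds + variant_offset`: strictly increasing
#' in carbon count for the chain lengths and unsaturation degrees seen in
#' cell lipid profiles, matching identification of FAMEs by elution order.
#'
#' @param carbons,double_bonds,variant_offset Numeric vectors.
#' @export
fame_retention_index <- function(carbons, double_bonds, variant_offset = 0) {
  100 * carbons + 20 * double_bonds + variant_offset
}

#' Annotate LC-MS features by exact mass
#'
#' Matches each feature m/z against the theoretical adduct masses of a
#' compound table; hits within `tol_mda` are ranked by absolute deviation.
#' Features with no hit are labelled `"unknown"`.
#'
#' @param feature_matrix A [feature_matrix] with an `mz` descriptor column,
#'   or a numeric vector of feature m/z values.
#' @param compounds Compound table as from [compound_table()]; rows without a
#'   parseable formula are skipped.
#' @param tol_mda Match tolerance in mDa.
#' @return A data.frame with one row per (feature, hit) pair plus one
#'   `"unknown"` row for unmatched features: columns feature, mz, name,
#'   adduct, theoretical_mz, deviation_mda, rank.
#' @export
annotate_features <- function(feature_matrix, compounds = compound_table(),
                              tol_mda = 5) {
  mz <- if (is.numeric(feature_matrix)) {
    feature_matrix
  } else {
    stopifnot(inherits(feature_matrix, "feature_matrix"))
    fm_descriptors(feature_matrix)$mz
  }
  stopifnot(is.numeric(mz), tol_mda >= 0)
  ref <- compounds[!is.na(compounds$theoretical_mz), , drop = FALSE]
  out <- vector("list", length(mz))
  for (i in seq_along(mz)) {
    dev <- (mz[i] - ref$theoretical_mz) * 1000
    hit <- which(abs(dev) <= tol_mda)
    if (length(hit) == 0L) {
      out[[i]] <- data.frame(feature = i, mz = mz[i], name = "unknown",
                             adduct = NA_character_,
                             theoretical_mz = NA_real_,
                             deviation_mda = NA_real_, rank = NA_integer_,
                             stringsAsFactors = FALSE)
    } else {
      hit <- hit[order(abs(dev[hit]))]
      out[[i]] <- data.frame(feature = i, mz = mz[i], name = ref$name[hit],
                             adduct = ref$adduct[hit],
                             theoretical_mz = ref$theoretical_mz[hit],
                             deviation_mda = round(dev[hit], 3),
                             rank = seq_along(hit),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Look up NMR assignments covering a chemical shift
#'
#' @param ppm Chemical shift to look up.
#' @param assignments Assignment table: the apolar table (windows) or the
#'   polar table (line lists), see [apolar_assignments()] and
#'   [polar_assignments()].
#' @param window_pad Padding in ppm added on both sides of each window (or
#'   around each collapsed line position for the polar table).
#' @return Character vector of matching assignment names (possibly empty).
#' @export
ppm_lookup <- function(ppm, assignments = apolar_assignments(),
                       window_pad = 0) {
  stopifnot(is.numeric(ppm), length(ppm) == 1L, window_pad >= 0)
  if (all(c("lo_ppm", "hi_ppm") %in% names(assignments))) {
    stopifnot(all(assignments$lo_ppm < assignments$hi_ppm))
    hit <- ppm >= assignments$lo_ppm - window_pad &
      ppm <= assignments$hi_ppm + window_pad
  } else {
    pad <- max(window_pad, 0.01)  # a bare line position needs some width
    hit <- vapply(strsplit(assignments$shifts_ppm, ";"), function(s) {
      any(abs(as.numeric(s) - ppm) <= pad)
    }, logical(1))
  }
  assignments$assignment[hit]
}
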
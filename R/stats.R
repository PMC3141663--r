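# The feature-selection cascade: log2 transform with half-minimum flooring,
# one-way ANOVA pre-selection, double-centered PCA, Bonferroni survival and
# a fold-change filter.

#' Log2-transform a feature matrix with half-minimum flooring
#'
#' Missing and non-positive cells are replaced, per feature, by half the
#' smallest positive value of that feature (MS peak absence is treated as a
#' value below the detection limit, not as zero). A feature with no positive
#' value falls back to half the smallest positive value of the whole matrix,
#' or 1 if the matrix has none. The transform is then log2.
#'
#' @param matrix A [feature_matrix] or plain numeric matrix.
#' @param floor Optional fixed floor overriding the half-minimum rule.
#' @return Same type as the input, log2-transformed.
#' @export
log2_matrix <- function(matrix, floor = NULL) {
  fm <- inherits(matrix, "feature_matrix")
  vals <- if (fm) matrix$values else as.matrix(matrix)
  pos <- vals[is.finite(vals) & vals > 0]
  global_floor <- if (length(pos)) min(pos) / 2 else 1
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    bad <- !is.finite(row) | row <= 0
    if (any(bad)) {
      rp <- row[!bad]
      fl <- if (!is.null(floor)) floor else
        if (length(rp)) min(rp) / 2 else global_floor
      vals[i, bad] <- fl
    }
  }
  vals <- log2(vals)
  if (fm) {
    matrix$values <- vals
    matrix
  } else vals
}

#' One-way fixed-effects ANOVA p-value
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; at least 2 groups with at least
#'   2 observations each.
#' @return The F-test p-value; 1 by convention when the total variance is
#'   zero.
#' @export
anova_p <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  stopifnot(length(values) == length(groups))
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  grand <- mean(values)
  ssb <- sum(ng * (gm - grand)^2)
  sst <- sum((values - grand)^2)
  ssw <- sst - ssb
  if (sst <= 0) return(1)
  if (ssw <= 0) return(0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# vectorized one-way ANOVA over matrix rows
.row_anova_p <- function(vals, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- ncol(vals)
  ng <- tabulate(groups)
  idx <- lapply(levels(groups), function(g) which(groups == g))
  grand <- rowMeans(vals)
  ssb <- rep(0, nrow(vals))
  for (j in seq_len(k)) {
    gm <- rowMeans(vals[, idx[[j]], drop = FALSE])
    ssb <- ssb + ng[j] * (gm - grand)^2
  }
  sst <- rowSums((vals - grand)^2)
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[sst <= 1e-300] <- 1
  p[ssw <= 1e-300 & ssb > 1e-300] <- 0
  p
}

#' Double-centered principal component analysis
#'
#' Subtracts row means and column means (adding back the grand mean) before
#' a singular-value decomposition; components are ordered by explained
#' variance.
#'
#' @param matrix Numeric matrix (features x samples) or [feature_matrix].
#' @return A list of class `dc_pca`: `scores` (samples x components),
#'   `loadings` (features x components), `variance_fraction`, `centered`.
#' @export
pca_double_centered <- function(matrix) {
  vals <- if (inherits(matrix, "feature_matrix")) matrix$values else
    as.matrix(matrix)
  rm <- rowMeans(vals)
  cm <- colMeans(vals)
  g <- mean(vals)
  centered <- vals - outer(rm, rep(1, ncol(vals))) -
    outer(rep(1, nrow(vals)), cm) + g
  sv <- svd(centered)
  ncomp <- min(dim(vals))
  scores <- sv$v %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(vals)
  structure(list(scores = scores, loadings = sv$u,
                 variance_fraction = sv$d^2 / sum(sv$d^2),
                 centered = centered),
            class = "dc_pca")
}

#' @export
print.dc_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[seq_len(min(
    3L, length(x$variance_fraction)))], 1)
  cat(sprintf("<dc_pca: %d features x %d samples; PC variance %%: %s>\n",
              nrow(x$loadings), nrow(x$scores),
              paste(vf, collapse = ", ")))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param p Raw p-value(s).
#' @param m Number of tests in the family (the full aligned-feature universe
#'   by default in this pipeline).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Group fold change (ratio of arithmetic means)
#'
#' The TCDD:DMSO ratio (RTD) of each feature: arithmetic mean over TCDD
#' samples divided by arithmetic mean over DMSO samples, on the normalized
#' linear scale. Missing cells are excluded from the means. A non-positive
#' denominator mean gives `NA` (flagged via the `undefined` attribute).
#'
#' @param normalized_matrix A [feature_matrix] or numeric matrix (linear
#'   scale).
#' @param groups Treatment labels per sample column.
#' @param numerator,denominator Group labels forming the ratio.
#' @return Numeric vector of per-feature ratios.
#' @export
group_fold_change <- function(normalized_matrix, groups,
                              numerator = "TCDD", denominator = "DMSO") {
  vals <- if (inherits(normalized_matrix, "feature_matrix"))
    normalized_matrix$values else as.matrix(normalized_matrix)
  stopifnot(length(groups) == ncol(vals))
  num <- rowMeans(vals[, groups == numerator, drop = FALSE], na.rm = TRUE)
  den <- rowMeans(vals[, groups == denominator, drop = FALSE], na.rm = TRUE)
  out <- num / den
  bad <- !is.finite(den) | den <= 0
  out[bad] <- NA_real_
  attr(out, "undefined") <- which(bad)
  out
}

#' Feature-selection cascade
#'
#' The full statistical pipeline applied to a normalized feature matrix:
#' log2 transform, one-way ANOVA pre-selection at `alpha_pre`, double-
#' centered PCA of the surviving features with loadings read off the
#' component that best separates the treatment score centroids, Bonferroni
#' correction over the feature universe, and a fold-change filter at
#' `min_fc` in either direction. A feature is selected when it passes the
#' ANOVA pre-selection, survives Bonferroni at `alpha_bonf` and changes at
#' least `min_fc`-fold.
#'
#' @param matrix Normalized [feature_matrix] (linear scale).
#' @param groups Grouping for the ANOVA: the treatment labels, or
#'   passage-by-treatment labels (the fold change always contrasts
#'   `numerator` vs `denominator`).
#' @param alpha_pre ANOVA pre-selection level.
#' @param alpha_bonf Family-wise level the Bonferroni-adjusted p must stay
#'   below.
#' @param min_fc Minimum fold change (applied as `>= min_fc` or
#'   `<= 1/min_fc`).
#' @param bonferroni_universe `"pre"` (all aligned features, the default) or
#'   `"post"` (only ANOVA survivors).
#' @param numerator,denominator Treatment labels for the fold change.
#' @param treatment Optional treatment labels when `groups` is a finer
#'   grouping; used to pick the treatment-separating component.
#' @return A `metab_selection` object: a data.frame of per-feature
#'   selection records (descriptors, anova_p, bonferroni_p, pca_loading,
#'   fold_change, selected) with the PCA, parameters and universe size as
#'   attributes.
#' @export
select_affected <- function(matrix, groups, alpha_pre = 0.01,
                            alpha_bonf = 0.05, min_fc = 1.2,
                            bonferroni_universe = c("pre", "post"),
                            numerator = "TCDD", denominator = "DMSO",
                            treatment = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  bonferroni_universe <- match.arg(bonferroni_universe)
  groups <- as.character(groups)
  if (is.null(treatment)) treatment <- groups
  stopifnot(length(groups) == ncol(fm_values(matrix)),
            length(treatment) == length(groups))
  if (sum(treatment == numerator) < 2L || sum(treatment == denominator) < 2L) {
    stop("need at least 2 samples per treatment")
  }
  logvals <- fm_values(log2_matrix(matrix))
  p <- .row_anova_p(logvals, groups)
  pass_pre <- p < alpha_pre
  m <- if (bonferroni_universe == "pre") length(p) else max(1L, sum(pass_pre))
  bonf <- bonferroni_adjust(p, m)
  fc <- group_fold_change(matrix, treatment, numerator, denominator)

  loading <- rep(NA_real_, length(p))
  pca <- NULL
  sep_comp <- NA_integer_
  if (sum(pass_pre) >= 2L) {
    pca <- pca_double_centered(logvals[pass_pre, , drop = FALSE])
    sc <- pca$scores
    is_num <- treatment == numerator
    is_den <- treatment == denominator
    sep <- vapply(seq_len(ncol(sc)), function(j) {
      s <- sc[, j]
      pooled <- stats::sd(s)
      if (!is.finite(pooled) || pooled == 0) return(0)
      abs(mean(s[is_num]) - mean(s[is_den])) / pooled
    }, numeric(1))
    sep_comp <- which.max(sep)
    loading[pass_pre] <- pca$loadings[, sep_comp]
  }

  selected <- pass_pre & bonf < alpha_bonf & !is.na(fc) &
    (fc >= min_fc | fc <= 1 / min_fc)
  records <- cbind(
    data.frame(feature = seq_along(p)),
    fm_descriptors(matrix),
    data.frame(anova_p = p, bonferroni_p = bonf, pca_loading = loading,
               fold_change = as.numeric(fc), selected = selected))
  structure(records,
            class = c("metab_selection", "data.frame"),
            params = list(alpha_pre = alpha_pre, alpha_bonf = alpha_bonf,
                          min_fc = min_fc,
                          bonferroni_universe = bonferroni_universe,
                          n_universe = m, separating_component = sep_comp),
            pca = pca)
}

#' @export
print.metab_selection <- function(x, ...) {
  pars <- attr(x, "params")
  cat(sprintf(
    "<metab_selection: %d/%d features selected (ANOVA p < %g, Bonferroni %g over %d, fold change >= %g)>\n",
    sum(x$selected), nrow(x), pars$alpha_pre, pars$alpha_bonf,
    pars$n_universe, pars$min_fc))
  invisible(x)
}

#' @export
summary.metab_selection <- function(object, ...) {
  sel <- object[object$selected, , drop = FALSE]
  sel <- sel[order(sel$anova_p), , drop = FALSE]
  cat(sprintf("%d of %d features selected\n", nrow(sel), nrow(object)))
  if (nrow(sel)) {
    print(utils::head(as.data.frame(sel), 20), row.names = FALSE)
  }
  invisible(sel)
}

#' Export selection results
#'
#' Writes the per-feature selection records as TSV plus a reduced feature
#' matrix containing only the selected features (the "new chromatogram"
#' used for targeted identification follow-up).
#'
#' @param records A `metab_selection`.
#' @param matrix The [feature_matrix] the selection ran on.
#' @param path Report TSV path; the reduced matrix goes to
#'   `<path>.selected.tsv` (or `reduced_path`).
#' @param reduced_path Optional explicit path for the reduced matrix.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_selected_features <- function(records, matrix, path,
                                     reduced_path = NULL) {
  stopifnot(inherits(records, "metab_selection"),
            inherits(matrix, "feature_matrix"))
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(reduced_path)) reduced_path <- paste0(path, ".selected.tsv")
  reduced <- matrix
  keep <- which(records$selected)
  reduced$values <- matrix$values[keep, , drop = FALSE]
  reduced$descriptors <- matrix$descriptors[keep, , drop = FALSE]
  write_feature_table(reduced, reduced_path)
  invisible(c(report = path, reduced = reduced_path))
}
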
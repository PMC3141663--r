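# metabopipe

Untargeted multi-platform metabolomics of cultured cells, as an R package.

When cells are exposed to a toxicant such as TCDD, two things change: the
levels of individual intracellular metabolites, and the number of cells per
flask (TCDD is anti-proliferative). Raw comparisons of treated vs. control
extracts are dominated by the second effect. metabopipe implements the
complete analysis chain that separates the two, for three platforms
measured on the same flasks:

* **1D ¹H-NMR** of the apolar (lipid) and polar (aqueous) extract
  fractions: apodization (squared sine bell, shifted π/2), zero filling to
  128 K, Fourier transformation, automatic phasing, asymmetric-least-squares
  baseline correction, reference calibration, and segment-wise alignment
  into a binned feature matrix.
* **LC-MS / GC-MS** peak lists: smoothing and noise gating, peak picking,
  retention-time correction, and greedy cross-run correspondence
  clustering.
* **Internal-standard normalization**: each flask's PL/CHCl₃ ratio — the
  glycerophospholipid backbone NMR signal (5.17–5.24 ppm) over the residual
  CHCl₃ proton signal — is a cell-number proxy; dividing by it removes the
  cell-number confounder on every platform. GC-MS fatty-acid profiles are
  scaled by the summed raw AA + DHA methyl-ester integrals instead.
* **Feature selection**: log₂ transform (half-minimum flooring of missing
  cells), one-way ANOVA pre-selection at p < 0.01, double-centered PCA
  (row and column means subtracted), Bonferroni survival over the feature
  universe, and a ≥ 1.2 fold-change filter; fold change is the ratio of
  arithmetic group means on the linear normalized scale
  (RTD = TCDD/DMSO).
* **Exact-mass annotation**: monoisotopic masses from lightest-isotope
  atomic masses, [M+H]⁺ / [M+NH₄]⁺ adducts with electron-mass correction
  (proton = H − e⁻), and mDa deviations against a packaged reference table
  of Orbitrap-identified polar metabolites.
* **A synthetic study generator** that emits complete studies — JCAMP-DX
  FIDs for both fractions, LC-MS/GC-MS peak lists, metadata, and a ground-
  truth manifest — with the design (5 passages × 2 treatments × 4
  replicate flasks), the cell-number confounder, passage-dependent effect
  attenuation, and per-metabolite planted fold changes. All
  validation runs against this planted truth.

## Worked example

```r
library(metabopipe)

# a complete synthetic study: 5 passages x {TCDD, DMSO} x 4 flasks
design <- make_study_design(seed = 1)
truth  <- truth_manifest(design, attenuation_range = c(1, 1))
flasks <- simulate_flasks(design, truth)

# process both NMR fractions and normalize by the paired PL/CHCl3 factors
apo <- process_nmr_fraction(simulate_nmr_study(flasks, "apolar", truth),
                            "apolar")
pol <- process_nmr_fraction(simulate_nmr_study(flasks, "polar", truth),
                            "polar")
anorm <- normalize_matrix(apo$matrix, apo$factors)
pnorm <- normalize_matrix(pol$matrix, apo$factors)

g <- flasks$treatment
window_fold_change(anorm, 4.10, 4.32, g)   # triglyceride backbone
window_fold_change(pnorm, 4.56, 4.60, g)   # reduced glutathione
```

On this seed the triglyceride window returns `0.511` against a planted
RTD of 0.51 and the glutathione window `1.741` against a planted 1.58 —
the estimates recover the planted effects once the ~0.7× cell-number
confounder is divided out (unnormalized, the same triglyceride window
reads `0.338`). The selection cascade on the same matrices flags the
planted metabolites:

```r
sel <- select_affected(anorm, g)
print(sel)
#> <metab_selection: 882/2475 features selected (ANOVA p < 0.01,
#>  Bonferroni 0.05 over 2475, fold change >= 1.2)>
```

Exact-mass annotation of an LC-MS feature:

```r
annotate_features(116.07046, tol_mda = 5)[1, c("name", "deviation_mda")]
#>      name deviation_mda
#> 1 Proline        -0.145
```

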
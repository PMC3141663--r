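---
title: "Methods: untargeted multi-platform metabolomics of cultured cells"
author: "metabopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted multi-platform metabolomics of cultured cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Exposing cultured cells to a toxicant changes two things at once: the
concentrations of individual intracellular metabolites, and — because
compounds such as TCDD slow proliferation — the *number of cells* per
culture flask. An untargeted comparison of treated and control extracts that
ignores the second effect sees a global decrease of everything and misses
the specific metabolic signal. metabopipe implements a complete analysis
chain for this situation, for three complementary platforms measured on the
same flasks: 1D ¹H-NMR of the apolar (lipid) and polar (aqueous) extract
fractions, GC-MS of fatty-acid methyl esters (FAMEs) from the apolar
fraction, and positive-mode LC-MS of the polar fraction.

The chain is: spectral processing → alignment into a features × samples
matrix → internal-standard normalization → log₂/ANOVA/PCA/Bonferroni/fold-
change feature selection → exact-mass annotation. Because real instrument
data cannot ship with a package, a first-class synthetic study generator
produces complete studies with planted ground truth, and every stage is
validated against that truth.

# The normalization model

The apolar fraction is dissolved in the same deuterated chloroform for
every flask, so the residual CHCl₃ proton signal (≈ 7.26 ppm) is an
absolute internal standard. Two per-flask ratios are formed from the
processed apolar spectrum:

* **TS/CHCl₃** — the summed integrals of all 22 assigned lipid signals over
  the CHCl₃ integral: total lipid per flask.
* **PL/CHCl₃** — the glycerophospholipid backbone signal (5.17–5.24 ppm)
  over the CHCl₃ integral. Membrane phospholipid per cell is essentially
  constant, so this ratio is a cell-number proxy.

Dividing every platform's intensities for a flask by that flask's PL/CHCl₃
factor removes the cell-number confounder. Polar NMR and LC-MS matrices are
normalized with the factors of the *paired* apolar fractions. GC-MS FAME
profiles are instead scaled by the flask's raw summed arachidonic +
docosahexaenoic methyl-ester integrals (AA + DHA), which track phospholipid;
PL/CHCl₃ factors are never applied to GC-MS.

Whether "intensity" means apex height or area is ambiguous for a ratio of
this kind; integrals (areas) are used throughout, which is the more robust
choice under line-width variation.

# NMR processing

FIDs are acquired as 16 K complex points at a spectral width of 5000 Hz and
400.13 MHz. Processing is:

1. **Apodization** — squared sine bell shifted π/2 (`cos²`), weight 1 at the
   first point, 0 at the last.
2. **Zero filling** to 128 K points.
3. **DFT** with the first FID point halved. The halving removes the
   constant s(0)/2 offset a plain DFT of a truncated decay adds to every
   spectral point; without it that offset, which scales with total signal
   and hence with treatment, leaks into every integral.
4. **Automatic phasing**: zero- and first-order phase chosen by Nelder–Mead
   minimization of the squared negative intensities of the real part. For a
   noiseless absorption spectrum this penalty is zero exactly at the true
   phases, because any rotation mixes in dispersion whose negative lobe
   dominates the Lorentzian tail. On failure the magnitude spectrum is
   returned with a flag.
5. **Baseline correction**: asymmetric least squares (AsLS) on a decimated
   grid of at most 2048 nodes. The node signal is a *lower envelope*
   (block minima widened by a 5-node rolling minimum), which suppresses
   narrow peaks at the node scale so the penalized fit can follow broad
   baseline humps without touching peak apexes. Defaults λ = 10⁴ and
   asymmetry p = 0.05 were chosen so that a hump of width ~0.3 ppm is
   tracked (length scale λ^¼ ≈ 10 nodes ≈ 0.06 ppm) while apex heights of
   synthetic peaks are preserved to well within 5%.
6. **Calibration** on the reference apex (TMSP 0.00 ppm polar, CHCl₃
   7.26 ppm apolar) with 3-point parabolic interpolation.
7. **Alignment and binning**: each 0.1 ppm segment of each spectrum is
   shifted by the integer lag (|lag| ≤ 0.02 ppm) maximizing its
   cross-correlation with the median spectrum, then integrated into fixed
   half-open 0.005 ppm bins. Solvent and reference windows (water
   4.7–5.0 ppm and TMSP for the polar fraction, the CHCl₃ window for the
   apolar one) are masked from the matrix. Binned cross-correlation
   against the median spectrum is a standard, reproducible alignment
   scheme; its parameters (bin 0.005, segment 0.1, max shift 0.02 ppm)
   are package defaults chosen for 400 MHz line widths.

# MS processing

LC-MS and GC-MS data enter as centroided peak lists. Cross-run
correspondence is: (1) landmark peaks (present in ≥ 80% of runs, upper
intensity half) fit a per-run linear retention-time correction — linear
because the simulated (and typical) drift is a gentle monotone stretch;
(2) corrected peaks are pooled and clustered greedily in order of
descending intensity within m/z and RT tolerances (defaults 5 mDa,
0.1 min), at most one peak per run per feature; (3) unmatched cells are
*missing*, not zero — an MS peak below the detection limit was not measured
as zero. Trace-level utilities (Savitzky–Golay smoothing, MAD-based noise
gating at 3σ, parabolic peak picking) support profile data.

GC-MS quantification replaces manual integration with declarative retention
windows, one per FAME species, on a retention-index axis; the index model
is `100·C + 20·DB + isomer offset`, strictly increasing in carbon count so
elution order identifies chain length.

# The selection cascade

On the normalized matrix: missing/non-positive cells are floored to half
the feature's smallest positive value (global fallback if none), then
log₂-transformed. A one-way fixed-effects ANOVA (grouping on treatment, or
passage × treatment) pre-selects features at p < 0.01. The surviving
features enter a double-centered PCA (row means and column means
subtracted, grand mean added, SVD); loadings are read off the component
whose treatment score centroids are farthest apart in pooled-sd units —
chosen by that explicit rule because eyeballing "the separating axis" is
not reproducible. Bonferroni correction is applied over the full aligned
feature universe (pre-ANOVA; switchable to post) with family-wise α = 0.05
— the cascade requires features to "survive" correction but a family-wise
level had to be fixed, and 0.05 is the conventional choice. Finally the
fold change — ratio of arithmetic group means on the *linear* normalized
scale, the convention fold-change tables in this field use — must be
≥ 1.2 in either direction.

# The synthetic study generator

The generator is the package's test bed and defines the study conditions:

* Design: 5 passages × {TCDD, DMSO} × 4 biological replicate flasks. Only
  biological replicates (independent flasks) are modeled — technical
  re-measurement adds little once biological variation dominates — and the
  replicate count is a parameter.
* Cell-number confounder: TCDD flasks draw a `cell_scale` around 0.7
  (mean-one lognormal flask variation, CV 10%). TCDD's anti-proliferative
  effect is well documented but its size in any given experiment is not,
  so 0.7 is a package default, configurable.
* Passage effect: each passage draws an effect-attenuation exponent
  uniformly from [0.6, 1] (applied as RTD^a); culture age is known to
  modulate effect magnitudes, without a quantitative law to plant.
  Validation studies that compare
  estimated to planted fold changes fix the exponent at 1 so the planted
  value is the estimand.
* NMR: one Lorentzian line (1.5 Hz width) per assignment-table entry —
  multiplets collapsed, since nothing downstream uses multiplet structure —
  with amplitude `base × cell_scale × RTD^a × lognormal(CV 10%)`; a
  CHCl₃ (apolar) or TMSP (polar) reference line *independent* of
  cell_scale; one per-sample ppm jitter (sd 0.003 ppm) on all cell-derived
  lines; additive Gaussian FID noise; and a broad randomly placed baseline
  hump (5% of summed amplitude, ~0.3 ppm wide) that the baseline stage must
  remove.
* Planted effects default to fold changes of the size real TCDD
  exposures of hepatoma cells produce: e.g. triglycerides 0.51 and
  cholesterol ester 0.69 (apolar NMR), reduced glutathione 1.58 and
  citrate 1.46 (polar NMR), per-species values in the FAME table for
  GC-MS, and per-compound values for the LC-MS reference compounds. The
  bis-allylic PUFA signal at 2.84 ppm is planted null (RTD 1): long-chain
  PUFAs are membrane constituents that track phospholipid, so it serves
  as the known-constant check on the normalization. AA and DHA are
  per-cell constant, as the GC-MS normalization requires.
* LC-MS: one peak per reference compound at its theoretical [M+H]⁺ (or
  [M+NH₄]⁺) m/z with Gaussian ppm-scale mass error and a per-run monotone
  RT drift; 100 decoy peaks per run; detection floor at 3× the noise
  scale. GC-MS: one peak per FAME at its retention index with a small
  additive per-run shift — retention indices are ladder-calibrated, so a
  multiplicative stretch would be unrealistic.

What the generator does *not* emulate: J-coupling and multiplet structure,
isotope patterns, chromatographic peak shapes, ionization suppression,
batch effects, and peak-overlap pathologies beyond Lorentzian tails.
Passing tests therefore demonstrate correctness of the *computational*
chain under the stated statistical structure, not robustness to every
artifact of real spectra.

# Problem sizes and numerical choices

Validation studies in the test suite use the full 40-flask design with
full-size FIDs (16 K acquired, 128 K transformed) over 20 seeds for
fold-change recovery, a reduced 8-flask design over 20 seeds for the
confounder-removal check, and 100 repeats of 200 × 40 null matrices for
type-I error; unit tests run on 4 K-point FIDs. These sizes were chosen as
the smallest that make the statistical assertions sharp.

Ties and degenerate inputs: a zero-variance feature gets ANOVA p = 1 by
convention; a zero within-group variance with nonzero between-group
variance gets p = 0; fold changes with non-positive control means are
flagged undefined rather than guessed; alignment with `max_shift = 0` is
pure binning; an empty selection still produces valid (header-only)
reports.

# Known limitations

* The AsLS baseline under-subtracts broad humps that sit entirely under a
  dense peak cluster; with the default synthetic noise this biases the
  strongest fold-change estimates by a few percent toward unity.
* The greedy correspondence clustering is order-dependent by design
  (descending intensity); pathological peak densities can split a feature.
* Bonferroni over thousands of correlated NMR bins is conservative;
  neighboring bins of one resonance are not independent tests.
* The phase objective assumes mostly-positive absorption spectra; spectra
  dominated by negative artifacts would need the magnitude fallback.
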
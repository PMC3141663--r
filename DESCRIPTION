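Package: metabopipe
Title: Untargeted Multi-Platform Metabolomics of Cultured Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for untargeted intracellular
    metabolomics of toxicant-exposed cultured cells combining 1D 1H-NMR,
    LC-MS and GC-MS. Provides 1D NMR processing (apodization, zero
    filling, Fourier transformation, automatic phasing, asymmetric
    least-squares baseline correction, segment-wise spectral alignment),
    MetAlign-style peak picking and cross-run alignment for mass
    spectrometry peak lists, internal-standard normalization on the
    glycerophospholipid backbone NMR signal (PL/CHCl3 ratios propagated
    across platforms, AA+DHA scaling for fatty-acid methyl ester
    profiles), a log2/ANOVA/double-centered-PCA/Bonferroni/fold-change
    feature-selection cascade, exact monoisotopic-mass adduct annotation
    with electron-mass correction, and a fully synthetic study generator
    with planted ground truth so every stage of the pipeline can be
    validated without instrument data. JCAMP-DX 1D spectra and
    tab-separated peak lists and feature matrices are the on-disk
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
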
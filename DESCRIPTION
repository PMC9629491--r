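Package: sasconsensus
Title: Consensus Small-Angle Scattering Profiles from Multi-Instrument Campaigns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to combine independently measured small-angle X-ray and
    neutron scattering (SAXS/SANS) profiles of one biomolecule into a single
    consensus profile. Determines per-dataset multiplicative scale factors and
    additive background offsets by Levenberg-Marquardt minimisation of all
    pairwise error-weighted discrepancies on a common q-grid, with optional
    high-error and modified Z-score outlier filtering iterated to convergence.
    Includes automated Guinier analysis, a regularised indirect Fourier
    transform for the pair-distance distribution P(r) with maximum-dimension
    refinement and a background (P(0)-release) check, Porod invariant and
    volume, dimensionless Kratky diagnostics, splicing of low-q and high-q
    measurements with a contamination scan, reduced chi-square and
    correlation-map (longest-run) profile comparison, and a synthetic
    multi-instrument campaign generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, minpack.lm, pracma, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
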
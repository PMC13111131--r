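Package: bonnerspec
Title: Bonner Sphere Spectrometry with MLEM Unfolding and Proton
    Depth-Dose Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing secondary neutron fields around
    proton therapy beams with an extended-range Bonner sphere
    spectrometer.  Provides the forward folding of a fluence spectrum
    through a sphere response matrix, Maximum Likelihood Expectation
    Maximization (MLEM) unfolding of few-channel count vectors on a
    logarithmic energy grid, lethargy-space spectrum analysis (peak
    positions, relative intensities, region fluences), and validation of
    proton beams via analytical Bragg-curve (Bortfeld) fitting with
    R90/R80/R20 range extraction.  A synthetic-data module generates
    realistic spectra, response matrices, Poisson counts and depth-dose
    curves so the full pipeline is testable without transport
    simulations or detector hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
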
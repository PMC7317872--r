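Package: dimerlab
Title: Solution-Biophysics Toolkit for Adhesive Protein Trans-Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis workflow for characterizing adhesive
    protein homodimers, such as the two outermost extracellular repeats of
    cadherin-23, in solution and at the single-molecule level. Implements
    dynamic force spectroscopy with freely-jointed-chain tether fitting,
    tether-compliance loading-rate correction and Bell-Evans kinetics;
    single-molecule FRET efficiency and donor-acceptor distance analysis;
    time-resolved fluorescence anisotropy with biexponential rotational
    fitting; global sedimentation-equilibrium monomer-dimer dissociation
    constant fitting; small-angle X-ray scattering shape parameters
    (Guinier, normalized Kratky, regularized P(r) inversion, volume of
    correlation); and size-exclusion column calibration. Every analysis
    stage is paired with a synthetic-data generator with the statistical
    structure the stage assumes, so the whole pipeline is testable by
    parameter recovery without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
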
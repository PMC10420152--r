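Package: albind
Title: Spectroscopic Analysis of Small-Molecule Binding to Serum Albumin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for fluorescence-based ligand-serum-albumin
    binding studies: inner-filter correction, Stern-Volmer quenching and
    mechanism classification, double-logarithm binding constants, Van't
    Hoff thermodynamics with binding-force classification, Forster
    resonance energy transfer distances, FT-IR amide-I band deconvolution
    and circular-dichroism helix quantification.  Includes a synthetic
    spectra generator with known ground truth so every stage of the
    pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
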
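Package: MREcaliper
Title: Shear-Wave Caliper Analysis for 2D Magnetic Resonance Elastography of Skeletal Muscle
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 2D shear-wave magnetic resonance
    elastography (MRE) of skeletal muscle, modelled on the manual caliper
    workflow used for the upper trapezius. The package synthesizes
    phase-offset MRE acquisitions with known ground-truth stiffness
    (plane-wave phantoms with configurable dispersion, attenuation, fiducial
    markers and Rician noise), extracts the temporal first harmonic and
    animated wave frames, measures shear wavelength by an automated
    electronic-caliper procedure with a five-point wave-quality rubric,
    converts quality-gated wavelengths to shear stiffness via the plane-wave
    relation mu = rho*(lambda*f)^2, computes Rician-corrected magnitude SNR,
    and implements the two-observer reproducibility statistics (Cohen's
    kappa, two-way mixed ICC, Bland-Altman limits of agreement, coefficient
    of variation) together with Friedman and pairwise Wilcoxon factorial
    analyses over an actuator-position by frequency by body-side design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
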
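# MREcaliper

Shear-wave caliper analysis for 2D magnetic resonance elastography (MRE)
of skeletal muscle.

MRE drives an acoustic shear wave into tissue and encodes the resulting
micron-scale displacement into the phase of MR images acquired at several
offsets of the vibration cycle. In muscle studies of the upper trapezius,
stiffness is commonly read off the wave images manually: an observer draws
a 1D profile along the wave propagation direction, measures the distance
between successive peaks (one wavelength λ) with an electronic caliper on
each of eight animated wave frames, scores the wave quality on a 5-point
rubric, averages the wavelengths of frames scoring ≥ 3, and converts to
shear stiffness with the plane-wave relation

    μ = ρ (λ f)²        ρ = 1000 kg/m³, λ in metres, f in Hz,

while magnitude-image quality is summarised as

    SNR = 0.655 · S_ROI / σ_bg,

the 0.655 factor correcting for the Rician distribution of background
magnitude. This package is a reusable, tested implementation of that
entire workflow for methodologists who want to study it quantitatively:

* **Synthetic phantoms with known ground truth** (`makePhantom`,
  `makeRadialPhantom`): plane or radial shear waves with configurable
  wavelength, direction, attenuation and dispersion, fiducial markers, and
  complex Gaussian noise added before magnitude/phase extraction (Rician
  magnitude, signal-dependent phase noise).
* **Wave-image processing** (`extractFirstHarmonic`, `smoothBandpass`,
  `directionalFilter`, `synthesizeFrames`,
  `estimatePropagationDirection`): temporal first harmonic, spatial
  bandpass, optional directional filter, 8-frame synthesis, and automatic
  propagation-direction estimation.
* **The caliper core** (`extractProfile`, `measureWavelength`,
  `scoreWaveQuality`, `estimateStiffness`, `computeSNR`): automated
  profile placement, prominence-gated extrema with sub-sample refinement,
  the 5-point quality rubric, quality-gated stiffness, and Rician-corrected
  SNR.
* **Reproducibility statistics** (`cohensKappa`, `iccTwoWayMixed`,
  `blandAltman`, `cvPercent`, `friedmanAnalysis`, `pairwiseWilcoxon`):
  the two-observer agreement and factorial machinery of an
  actuator-position × frequency × side study.
* **A full synthetic study** (`runStudy`, `summarizeTable`,
  `checkFindings`): the 2 × 3 × 2 × 9 = 108-dataset design with two
  simulated observers, per-cell agreement reports and the 12-condition
  Friedman / pairwise-Wilcoxon analysis.

## Worked example

Simulate one noisy 60 Hz acquisition with ground-truth stiffness 4.25 kPa,
then measure it back:

```r
library(MREcaliper)

ph  <- makePhantom(phantomSpec(mu0Pa = 4250, noiseSigma = 3, seed = 8L),
                   acquisitionMeta(60))
estimateStiffness(ph$dataset, ph$roi, background = ph$background)
#> StiffnessResult: mu = 4.342 kPa (lambda = 34.73 mm, f = 60 Hz, 6/8 frames used, score 5)

computeSNR(magnitude(ph$dataset), ph$roi, ph$background)
#> SNRResult: SNR = 35.46 (S = 100, sigma_bg = 1.85)
```

The recovered 4.34 kPa is within ~2% of the 4.25 kPa ground truth; the
34.7 mm wavelength is what μ = ρ(λf)² implies at 60 Hz; six of the eight
wave frames passed the ≥ 3 quality gate and the dataset scored 5 (two or
more wavelengths visible in the ROI). The SNR of ~35 sits above the
study's floor of 20.

A reduced synthetic study (3 subjects, 64-pixel matrix; the default is
9 subjects at 128):

```r
study <- runStudy(studyDesign(nSubjects = 3L, matrixSize = 64L), seed = 2)
tab   <- summarizeTable(study)
tab[tab$side == "left", c("position", "frequencyHz", "stiffnessMeanKPa",
                          "icc", "biasKPa", "cvPercent")]
#>  position frequencyHz stiffnessMeanKPa   icc  biasKPa cvPercent
#>       VAP          60             4.04 0.557 -0.03914     4.496
#>       VAP          80             4.86 0.923  0.10925     2.423
#>       VAP         100             5.65 0.998 -0.05121     0.755
#>       HAP          60             1.45    NA  0.00683     0.688
#>       HAP          80             1.69 0.999  0.00932     1.544
#>       HAP         100             1.78 0.992  0.04089     1.368

study$factorialStiffness
#> FactorialResult: chi2 = 20.769, df = 11, p = 0.0358 (66 pairwise)
```

Stiffness measured with the actuator driving waves along the muscle fibres
(VAP) is higher than across them (HAP) and rises with frequency only along
the fibres — the dispersion pattern the design builds in; the Friedman
test across the 12 position × frequency × side conditions has df = 11.
`checkFindings(study)` evaluates the four qualitative findings (VAP > HAP,
VAP-only dispersion, no HAP frequency effect, no left–right asymmetry)
with Bonferroni-adjusted Wilcoxon tests. Cells where a statistic is
undefined (e.g. both observers gave every subject the same score, so
chance agreement is 1) are reported as `NA`.

Datasets round-trip to disk as NIfTI + JSON sidecar via `saveDataset()` /
`loadDataset()`, masks via `saveROIMask()`, and tables via
`writeResultsCSV()`.

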
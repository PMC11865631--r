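---
title: "Shear-wave caliper analysis for 2D muscle MRE: models, parameters and design"
author: "MREcaliper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-wave caliper analysis for 2D muscle MRE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MREcaliper)
```

## The measurement model

Magnetic resonance elastography (MRE) encodes a propagating acoustic shear
wave into the phase of MR images. For a plane shear wave of wavelength
$\lambda$ (metres) driven at vibration frequency $f$ (Hz) in a medium of
density $\rho$ (assumed 1000 kg/m$^3$ for muscle), the effective shear
stiffness is

$$\mu = \rho\,(\lambda f)^2,$$

the standard $\mu = \rho c^2$ with phase speed $c = \lambda f$. A quick
dimensional check fixes the interpretation: at $\mu = 4.25$ kPa and
$f = 60$ Hz this gives $\lambda \approx 3.4$ cm, about 24 pixels at the
1.40625 mm spacing of an 18 cm field of view on a 128 matrix — exactly the
kind of wave a reader can span with a caliper. (Reading the relation as
$\rho \lambda f^2$ instead would imply a sub-pixel 1.2 mm wavelength,
incompatible with any visible wave propagation.)

The package implements the manual workflow used for the upper trapezius
(UT): wave images are produced from the phase-offset stack, an observer
draws a 1D profile along the propagation direction, reads the distance
between like extrema (one full wavelength) with an electronic caliper on
each of eight animation frames, scores wave quality on a five-point rubric,
averages the wavelengths of frames scoring at least 3, and converts to
stiffness with the relation above. Magnitude-image quality is summarised as
$\mathrm{SNR} = 0.655\, S_{\mathrm{ROI}} / \sigma_{\mathrm{bg}}$, where the
0.655 factor ($\sqrt{2 - \pi/2}$) corrects for the background magnitude
being Rician (Rayleigh) rather than Gaussian.

## Wave-image processing

Four phase offsets $p_k$ sample one vibration cycle. The temporal first
harmonic is

$$H(x,y) = \frac{2}{N}\sum_{k=0}^{N-1} p_k(x,y)\, e^{+2\pi i k/N},$$

so $|H|$ is the local wave amplitude and static phase vanishes. The sign of
the kernel is a convention; it is chosen so that the eight synthesized
frames $\mathrm{frame}_k = \mathrm{Re}\{H e^{-2\pi i k/8}\}$ reproduce the
sampled oscillation and re-extracting the harmonic from the frames returns
$H$ exactly (a tested round-trip identity). Under this convention
$\arg H$ increases by $2\pi$ per wavelength along the propagation
direction.

Before measurement the harmonic is masked to tissue and bandpassed:

* **Tissue masking.** Air pixels carry uniform random phase, whose
  harmonic is large; left in place, the spatial filter rings it tens of
  millimetres into the tissue edge and injects spurious extrema into
  profiles. Pixels whose magnitude falls below 30% of the mean ROI
  magnitude are zeroed before filtering.
* **Bandpass.** A Gaussian-edged annulus in 2D spatial frequency passes
  wavelengths between 4 pixels and twice the ROI extent (defaults), with
  unit in-band gain and hard DC removal. A pure in-band plane wave keeps
  its wavelength exactly and its amplitude to within ~2% (spectral
  leakage at the window edge).
* **Directional filter** (off by default, matching the main analysis): a
  cone in frequency space around the propagation direction with a
  raised-cosine edge; the counter-propagating wave is suppressed more than
  20-fold. It is provided because some caliper variants use it.

The propagation direction is estimated automatically as the principal
eigenvector of the $|H|^2$-weighted structure tensor of the local phase
gradient, computed with the wrap-robust complex ratio
$\arg\{H(x+1)\overline{H(x)}\}$, and oriented toward increasing phase
delay. On noise-free plane waves it is accurate to better than 2 degrees.

## The automated caliper and quality rubric

The profile runs through the ROI centroid along the propagation direction.
Samples are taken by bilinear interpolation every quarter pixel. Local
maxima and minima with topographic prominence of at least 10% of the trace
range are kept, their positions refined by a three-point parabola, and the
wavelength is the mean of consecutive peak-to-peak and trough-to-trough
spacings. If fewer than two peaks and fewer than two troughs survive, the
frame yields no measurement.

Two geometric details matter and were settled empirically:

* The sampled profile extends up to 50% of the ROI extent *downstream* of
  the ROI (staying on tissue): with only ~1.3 wavelengths visible, edge
  extrema lack prominence and measurements fail, while an observer would
  simply read the next peak beyond the delineated muscle boundary. The
  extension is downstream only because the attenuation envelope has a kink
  at the wave-source edge; profiles crossing the kink mix shifted and
  unshifted extrema and bias the wavelength by several percent, whereas a
  uniform exponential decay shifts every extremum equally and leaves
  spacings unbiased.
* The quality rubric counts wavelengths over the ROI extent itself, not
  over the extended profile.

The five-point wave-quality rubric is automated as follows. Score 1: mean
$|H|$ in the ROI below 3 times the noise floor (no coherent waves). The
floor is predicted from the magnitude images —
per-offset phase noise $\sigma_c/S$, harmonic noise
$\sigma_c/S\cdot\sqrt{2/N}$, Rayleigh mean $\times\sqrt{\pi/2}$ — because
the background *harmonic* itself is dominated by uniform air phase and
would grossly overestimate the tissue floor. Score 2: coherent but not
planar — circular variance of the weighted phase-gradient directions above
0.3, or no dominant direction. Otherwise the number of wavelengths $W$
across the ROI (range of unwrapped phase along the profile divided by
$2\pi$) maps to 3 ($W<1$), 4 ($1\le W<2$) or 5 ($W\ge 2$). Per-frame scores
feed the $\ge 3$ averaging gate; the dataset-level score is the maximum
over the eight frames (the clearest frame).

## The synthetic phantom

No imaging data are distributed with the package; every consumer is
exercised on synthetic acquisitions with known ground truth. The phantom
emulates a single oblique-axial slice: a body disc (magnitude 100,
arbitrary units) with three bright fiducial capsules, a band-shaped muscle
ROI, a signal-free air background, and a displacement field

$$u(x, t_k) = A\, e^{-\alpha d}\cos(2\pi k/N - 2\pi d/\lambda),$$

with $d$ the distance from the upstream ROI edge along the propagation
direction. The phase stack is $\phi_0 + \varepsilon\, u$ with encoding
efficiency $\varepsilon$; complex Gaussian noise is added to
$M e^{i\phi}$ *before* magnitude/phase extraction, so magnitude noise is
Rician (the zero-signal background SD is $0.655\sigma$, verified by Monte
Carlo) and phase noise is signal-dependent (uniform in air). Defaults,
chosen once as realistic acquisition conditions: $A = 20$ um and
$\varepsilon = 0.05$ rad/um (peak phase ~1 rad, safely below wrapping),
$\alpha = 0.05$/mm, noise SD 3 (magnitude SNR ~33, above the study floor
of 20), 128 matrix / 18 cm FOV / 4 offsets. A radial-source variant
exercises quality score 2.

Stiffness dispersion is emulated as a power law
$\mu(f) = \mu_0 (f/f_0)^\gamma$ — the study reports the effect (apparent
stiffness rising with frequency along fibres, flat across fibres) but no
functional form, and a power law is the simplest positive, monotone
choice with a single interpretable exponent.

## The synthetic factorial study

`runStudy()` reproduces the design: 2 actuator positions (waves along vs
across the muscle fibres) x 3 vibration frequencies (60/80/100 Hz) x 2
body sides x 9 subjects = 108 datasets, each measured once by each of two
simulated observers. Ground-truth cell means default to the published
group means, with the effect structure built in: along-fibre cells follow
the fitted dispersion law per side ($\gamma \approx 1.3$ left, $\approx
1.7$ right, anchored at the 60 Hz mean), cross-fibre cells are
frequency-flat at the side's average. Between-subject variability is
lognormal with each cell's coefficient of variation matched to the
published SD/mean, and a hierarchical correlation structure: half the
log-variance is a global subject effect, a further 40% is shared across
frequencies within one position and side (dispersion is a tissue property,
so a subject's stiffness moves coherently with frequency), the rest is
cell-specific. ROI bands are 60 x 24 mm along fibres and 32 x 20 mm across
(the muscle is long along its fibres and narrow across them), so roughly
1-2 wavelengths are visible either way, matching the published mean
quality scores of about 4-4.6 and giving the two observers genuine
boundary cases to disagree on.

Observers are simulated as perturbations of the caliper *geometry* —
Gaussian jitter of the profile endpoints (SD 2 mm) and of detected
extremum positions (SD 0.5 mm) — rather than as noise on the final
stiffness, which qualitatively reproduces the frequency dependence of the
limits of agreement (shorter wavelengths amplify endpoint error). The
published per-subject values do not exist to calibrate these jitters
against; the defaults land the agreement statistics in the published
qualitative bands (kappa mostly substantial-to-almost-perfect, ICC
good-to-excellent) and this is documented, not asserted. Seeding is
hierarchical: one master seed spawns per-dataset and per-observer
sub-seeds, so any subset reruns identically.

## Agreement and factorial statistics

Per cell (9 subjects, 2 observers): unweighted Cohen's kappa on the
quality scores with the conventional bands (0.61-0.80 substantial,
0.81-1 almost perfect, etc.); two-way mixed single-rater ICC on stiffness
— the consistency form ICC(3,1)
$(\mathrm{MS}_S - \mathrm{MS}_E)/(\mathrm{MS}_S + (k-1)\mathrm{MS}_E)$,
with absolute agreement available behind a flag, since "two-way mixed"
alone does not pin the form down; Bland–Altman bias, SD of differences,
limits of agreement $1.96\,\mathrm{SD}$ and a $t$-based 95% CI for the
bias; and the coefficient of variation as the per-pair SD over the pair
mean, averaged and expressed in percent. The published CV definition
("ratio of the SD to the overall mean of the two measurements") is
ambiguous between this per-pair reading and a pooled one; both are
implemented (`method = "perPair"` default, `"pooled"` optional) and
neither is claimed to reproduce the published CV values, which are
numerically closer to between-subject variability.

Across conditions: Friedman's test on the subjects x 12-conditions matrix
(df = 11), via the tie-corrected mid-rank statistic, with fully tied
blocks mapped to $\chi^2 = 0,\ p = 1$; post hoc paired two-sided Wilcoxon
signed-rank tests (exact where the zero-trimmed sample is small and
untied, normal approximation with continuity correction otherwise) with
Bonferroni correction. `checkFindings()` encodes the study's qualitative
conclusions as four assertions: along-fibre stiffness exceeds cross-fibre
at every frequency (sides pooled within frequency, Bonferroni over 3 —
per-cell $n=9$ with a family of 6 cannot reach $\alpha=0.05$ even under
perfect separation, and the published $p<0.001$ for these comparisons
implies pooling); monotone, pairwise-significant dispersion along fibres
per side; no significant frequency effect across fibres; and no
significant left-right asymmetry.

## Numerical choices and degenerate inputs

* NIfTI images are written as FLOAT64 so the save/load round trip is
  bit-exact for R doubles; pixel coordinates are 1-based (row, col) with
  physical position $(\mathrm{index}-1)\times$ spacing.
* Harmonic extraction requires at least 3 offsets; 2 leave the first
  harmonic under-determined.
* Identical constant ratings make chance agreement 1 and kappa undefined:
  `cohensKappa()` errors, and the study report records NA for such cells.
* Wilcoxon comparisons whose differences are all zero return $p = 1$ and
  are flagged.
* The Friedman $\chi^2$ approximation is a *tail* approximation: against
  full enumeration of within-block orderings at 5 subjects x 3 conditions
  it agrees to ~0.01 in the rejection region but can deviate by ~0.1 at
  mid-range p-values. The tests pin the enumeration oracle in the tail.
* Phantom wavelengths below 3 pixels are rejected as unresolvable.

## Problem sizes and what the tests show

The test suite runs phantoms at 128 and 64 pixel matrices and reduced
studies of 3-6 subjects alongside one full 108-dataset study; these sizes
were chosen so the whole suite exercises every pipeline stage end-to-end
in well under a minute while keeping every geometric quantity (ROI sizes
in mm, wavelengths, noise levels) at the study's own scale. Noise-free
recovery of the published group means is accurate to within ~4% and
recovery under noise at the study's SNR floor to within ~8%.

The phantom is deliberately idealised: a single plane (or radial) wave
with exponential decay, no reflections from bone, no mode conversion, no
through-plane motion, no $B_0$/$B_1$ artefacts, and observers reduced to
geometric jitter. Passing tests therefore demonstrate the correctness of
the measurement chain and the statistics under known ground truth — not
that the pipeline reproduces human-observer numbers on real acquisitions,
which are not available. Inversion-based elastograms, viscoelastic
modelling and 3D acquisitions are out of scope.
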
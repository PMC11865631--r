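test_that("profile extraction interpolates bilinearly along the line", {
  sp <- 180 / 128
  # constant image: every sample equals the constant
  img <- matrix(7.5, 64, 64)
  tr <- extractProfile(img, profileLine(c(10, 5), c(50, 60), sp / 4), sp)
  expect_equal(tr@values, rep(7.5, length(tr@values)), tolerance = 1e-12)
  expect_equal(diff(tr@distancesMM)[1], sp / 4)

  # a line along the propagation of a 20 mm plane wave sees period 20 mm
  fld <- planeWaveField(n = 128, lambdaMM = 20)
  w <- Re(harmonic(fld))
  tr <- extractProfile(w, profileLine(c(64, 8), c(64, 120), sp / 4), sp)
  wl <- measureWavelength(tr)
  expect_equal(wl$lambdaMM, 20, tolerance = 0.01)

  # perpendicular to propagation: constant on wavefronts
  trP <- extractProfile(w, profileLine(c(8, 64), c(120, 64), sp / 4), sp)
  expect_lt(diff(range(trP@values)), 1e-9)

  expect_error(extractProfile(img, profileLine(c(1, 1), c(80, 80), sp / 4),
                              sp), "exits")
})

test_that("caliper wavelength matches the generator and the obliquity law", {
  sp <- 0.5
  # pure sinusoid, lambda = 20 mm, 3 periods at 0.5 mm sampling
  x <- seq(0, 60, by = 0.5)
  tr <- new("ProfileTrace", distancesMM = x,
            values = sin(2 * pi * x / 20))
  expect_equal(measureWavelength(tr)$lambdaMM, 20, tolerance = 0.01)

  # a trace spanning only 0.6 wavelength has no pair of like extrema
  xs <- seq(0, 12, by = 0.5)
  short <- new("ProfileTrace", distancesMM = xs,
               values = sin(2 * pi * xs / 20))
  out <- measureWavelength(short)
  expect_true(is.na(out$lambdaMM))
  expect_identical(out$reason, "insufficient extrema")

  # obliquity: profile at angle theta reads lambda / cos(theta)
  fld <- planeWaveField(n = 160, lambdaMM = 20)
  w <- Re(harmonic(fld))
  spm <- meta(fld)@pixelSpacingMM
  for (theta in c(30, 45, 60)) {
    a <- theta * pi / 180
    len <- 70 / spm   # px
    line <- profileLine(c(80 - len * sin(a) / 2, 80 - len * cos(a) / 2),
                        c(80 + len * sin(a) / 2, 80 + len * cos(a) / 2),
                        spm / 4)
    wl <- measureWavelength(extractProfile(w, line, spm))
    expect_equal(wl$lambdaMM, 20 / cos(a), tolerance = 0.03)
  }

  expect_error(measureWavelength(new("ProfileTrace", distancesMM = numeric(0),
                                     values = numeric(0))))
})

test_that("caliper recovery is within 2% for noise-free wavelengths of 8-40 px", {
  # mild attenuation so at least two like extrema stay prominent even at
  # the longest wavelength (the default 0.05/mm hides the second peak of a
  # 56 mm wave below the prominence threshold)
  sp <- 180 / 128
  for (lamPx in c(8, 16, 24, 32, 40)) {
    lam <- lamPx * sp
    mu <- 1000 * (lam / 1000 * 60)^2
    ph <- makePhantom(phantomSpec(mu, noiseSigma = 0,
                                  attenuationPerMM = 0.015),
                      acquisitionMeta(60))
    res <- estimateStiffness(ph$dataset, ph$roi, background = ph$background)
    expect_lt(abs(res@lambdaMeanM * 1000 - lam) / lam, 0.02)
  }
})

test_that("the automated rubric maps wavelength counts to scores 3-5", {
  m <- acquisitionMeta(60)
  sp <- m@pixelSpacingMM
  base <- makePhantom(phantomSpec(4000, noiseSigma = 0), m)
  ext <- roiExtentAlongMM(base$roi, c(1, 0), sp)
  scoreFor <- function(W) {
    lam <- ext / W
    mu <- 1000 * (lam / 1000 * 60)^2
    ph <- makePhantom(phantomSpec(mu, noiseSigma = 0), m)
    scoreWaveQuality(extractFirstHarmonic(ph$dataset), ph$roi,
                     background = ph$background,
                     magnitudeImg = magnitude(ph$dataset))
  }
  expect_identical(scoreFor(2.5), 5L)
  expect_identical(scoreFor(1.5), 4L)
  expect_identical(scoreFor(0.8), 3L)

  # radial source: coherent but not planar
  phr <- makeRadialPhantom(phantomSpec(4000, noiseSigma = 0), m)
  expect_identical(
    scoreWaveQuality(extractFirstHarmonic(phr$dataset), phr$roi,
                     background = phr$background,
                     magnitudeImg = magnitude(phr$dataset)), 2L)

  # pure noise: no coherent waves
  phn <- makePhantom(phantomSpec(4000, amplitudeUm = 0, noiseSigma = 3), m)
  expect_identical(
    scoreWaveQuality(extractFirstHarmonic(phn$dataset), phn$roi,
                     background = phn$background,
                     magnitudeImg = magnitude(phn$dataset)), 1L)

  expect_error(scoreWaveQuality(extractFirstHarmonic(phn$dataset),
                                roiMask(matrix(TRUE, 2, 2))), "shape")
})

test_that("quality score never decreases with a larger visible extent", {
  m <- acquisitionMeta(60)
  sp <- m@pixelSpacingMM
  ph <- makePhantom(phantomSpec(4250, noiseSigma = 0), m)  # lambda 34.4 mm
  fld <- extractFirstHarmonic(ph$dataset)
  scores <- sapply(c(30, 45, 60, 80, 100), function(len) {
    roi <- bandROI(128, sp, len, 20)
    scoreWaveQuality(fld, roi, background = ph$background,
                     magnitudeImg = magnitude(ph$dataset))
  })
  expect_true(all(diff(scores) >= 0))
})

test_that("stiffness formula and SNR follow their defining equations", {
  expect_equal(computeStiffness(0.02, 100, 1000), 4000)
  # inverted at the printed 60 Hz group mean
  lam <- sqrt(4250 / 1000) / 60
  expect_equal(computeStiffness(lam, 60, 1000), 4250, tolerance = 1e-12)
  expect_equal(computeStiffness(0.03436, 60, 1000), 1000 * (0.03436 * 60)^2)
  expect_error(computeStiffness(-1, 60))

  mag <- matrix(0.655, 40, 40)
  mag[1:10, 1:40] <- 100
  roiM <- roiMask(rbind(matrix(TRUE, 10, 40), matrix(FALSE, 30, 40)))
  set.seed(5)
  bgm <- matrix(FALSE, 40, 40); bgm[25:40, ] <- TRUE
  mag[bgm] <- rnorm(sum(bgm), 10, 0.655 / 0.655)
  snr <- computeSNR(mag, roiM, roiMask(bgm))
  expect_equal(snr@sRoi, 100)
  expect_equal(snr@snr, 0.655 * 100 / snr@sigmaBg)

  expect_error(computeSNR(mag, roiM, roiM), "overlap")
  small <- matrix(FALSE, 40, 40); small[1, 1:5] <- TRUE
  expect_error(computeSNR(mag, roiMask(bgm), roiMask(small)), "30")

  # Monte-Carlo: the 0.655 factor converts the Rayleigh background SD back
  # to the per-channel sigma, so SNR ~ S / sigma_c
  spec <- phantomSpec(4250, noiseSigma = 4, seed = 21L)
  ph <- makePhantom(spec, acquisitionMeta(60))
  est <- computeSNR(magnitude(ph$dataset), ph$roi, ph$background)
  expect_equal(est@snr, 100 / 4, tolerance = 0.05)
})

test_that("stiffness estimation gates on quality and handles dispersion-free phantoms", {
  m60 <- acquisitionMeta(60)
  ph <- makePhantom(phantomSpec(4250, noiseSigma = 0), m60)
  res <- estimateStiffness(ph$dataset, ph$roi, background = ph$background)
  expect_equal(res@muPa, 4250, tolerance = 0.1)
  expect_true(all(res@measurement@perFrameQuality[res@framesUsed] >= 3L))
  expect_equal(res@muPa,
               res@rhoKgM3 * (res@lambdaMeanM * res@fHz)^2)

  # frames forced below the gate: impossible coherence threshold
  th <- defaultQualityThresholds(); th$coherenceMin <- Inf
  expect_error(estimateStiffness(ph$dataset, ph$roi,
                                 background = ph$background,
                                 thresholds = th),
               "insufficient wave quality")

  # gamma = 0 phantom measured at 60 and 100 Hz recovers equal stiffness
  spec <- phantomSpec(4000, gamma = 0, noiseSigma = 0)
  r60 <- estimateStiffness(makePhantom(spec, acquisitionMeta(60))$dataset,
                           ph$roi, background = ph$background)
  ph100 <- makePhantom(spec, acquisitionMeta(100))
  r100 <- estimateStiffness(ph100$dataset, ph100$roi,
                            background = ph100$background)
  expect_lt(abs(r60@muPa - r100@muPa) / r60@muPa, 0.05)
})

test_that("stiffness recovery under noise stays within 15% at SNR >= 20", {
  hits <- 0L
  nrep <- 12L
  for (i in seq_len(nrep)) {
    ph <- makePhantom(phantomSpec(4250, noiseSigma = 5, seed = 300L + i),
                      acquisitionMeta(60))
    set.seed(600L + i)
    res <- estimateStiffness(ph$dataset, ph$roi, background = ph$background)
    if (abs(res@muPa - 4250) / 4250 <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, nrep - 1L)  # >= 95% nominal
})
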
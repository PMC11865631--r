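test_that("dispersion law evaluates the power law and fits the printed means", {
  expect_equal(dispersionLaw(4000, 60, 60, 2.3), 4000)
  expect_equal(dispersionLaw(4000, 120, 60, 1), 8000)
  expect_error(dispersionLaw(4000, -60, 60, 1))
  expect_error(dispersionLaw(4000, 60, 60, -0.5))

  # gamma fitted to the along-fibre 60/80/100 Hz group means; oracle is the
  # direct power-law evaluation at the fitted exponent
  f <- c(60, 80, 100)
  mu <- c(4.25, 6.38, 8.35) * 1000
  g <- fitDispersionGamma(f, mu, 60)
  x <- log(f / 60); y <- log(mu / mu[1])
  expect_equal(g, sum(x * y) / sum(x * x))
  oracle <- 4250 * (100 / 60)^g
  expect_equal(dispersionLaw(4250, 100, 60, g), oracle)
  # the fitted curve lands near the printed 100 Hz mean
  expect_lt(abs(oracle - 8350) / 8350, 0.02)
})

test_that("phantom ground truth and noise-free wave structure are exact", {
  # mu = 4000 Pa, rho = 1000, f = 100 Hz -> lambda = 20 mm by hand
  ph <- makePhantom(phantomSpec(4000, noiseSigma = 0), acquisitionMeta(100))
  expect_equal(ph$truth$lambdaMM, 20)

  # phase amplitude at the source edge equals encoding_scale * amplitude
  m <- acquisitionMeta(60)
  spec <- phantomSpec(4250, noiseSigma = 0, attenuationPerMM = 0,
                      backgroundPhaseRad = 0)
  ph <- makePhantom(spec, m)
  stack <- phaseStack(ph$dataset)
  roi <- maskMatrix(ph$roi)
  # across the 4 offsets each in-ROI pixel sweeps a full cosine
  amp <- apply(stack, c(1, 2), function(v) (max(v) - min(v)) / 2)
  # max over pixels: the 4 offsets sample the cosine at whatever phase the
  # pixel sits at, so the per-pixel swing reaches the full amplitude only
  # where a sample lands on the crest; across the ROI it does to ~1e-4
  peak <- max(amp[roi])
  expect_equal(peak, m@encodingScaleRadPerUm * spec@amplitudeUm,
               tolerance = 1e-3)

  # first-harmonic phase gradient magnitude = 2*pi/lambda inside the ROI
  fld <- extractFirstHarmonic(ph$dataset)
  H <- harmonic(fld)
  sp <- m@pixelSpacingMM
  gx <- Arg(H[, -1] * Conj(H[, -ncol(H)])) / sp
  inner <- roi[, -ncol(roi)] & roi[, -1]
  inner[c(1:3, (nrow(inner) - 2):nrow(inner)), ] <- FALSE
  grads <- abs(gx[inner])
  expect_lt(max(abs(grads - 2 * pi / ph$truth$lambdaMM)) /
              (2 * pi / ph$truth$lambdaMM), 0.005)
})

test_that("zero-signal magnitude noise is Rician with the 0.655 background SD", {
  spec <- phantomSpec(4000, amplitudeUm = 0, tissueLevel = 0,
                      noiseSigma = 2.5, matrixSize = 512L,
                      markerPositions = matrix(numeric(0), ncol = 2),
                      seed = 99L)
  ph <- makePhantom(spec, acquisitionMeta(60))
  mag <- magnitude(ph$dataset)   # 262144 pure-noise samples
  expect_equal(mean(mag) / 2.5, sqrt(pi / 2), tolerance = 0.01)
  expect_equal(sd(mag) / 2.5, sqrt(2 - pi / 2), tolerance = 0.01)
})

test_that("phantom generation is deterministic and validates its inputs", {
  spec <- phantomSpec(4250, noiseSigma = 3, seed = 7L)
  m <- acquisitionMeta(60)
  a <- makePhantom(spec, m)
  b <- makePhantom(spec, m)
  expect_identical(magnitude(a$dataset), magnitude(b$dataset))
  expect_identical(phaseStack(a$dataset), phaseStack(b$dataset))
  expect_identical(maskMatrix(a$roi), maskMatrix(b$roi))

  # sub-resolvable wavelength (3 px limit)
  expect_error(makePhantom(phantomSpec(30), acquisitionMeta(100)),
               "resolvability")
  # ROI that cannot fit the image
  expect_error(
    makePhantom(phantomSpec(4250,
                            roiGeometry = list(lengthMM = 500, widthMM = 20)),
                acquisitionMeta(60)), "fit")
})

test_that("study input grid has the factorial size and is seed-stable", {
  des <- studyDesign(nSubjects = 2L, matrixSize = 64L)
  inp <- makeStudyInputs(des, seed = 5)
  expect_length(inp$entries, 24L)   # 2 x 3 x 2 x 2
  expect_identical(dim(inp$truthKPa), c(2L, 12L))

  inp2 <- makeStudyInputs(des, seed = 5)
  expect_identical(inp$truthKPa, inp2$truthKPa)
  expect_identical(magnitude(inp$entries[[5]]$dataset),
                   magnitude(inp2$entries[[5]]$dataset))
  expect_identical(phaseStack(inp$entries[[17]]$dataset),
                   phaseStack(inp2$entries[[17]]$dataset))

  # default design: 12 cells x 9 subjects = 108 datasets
  expect_identical(12L * studyDesign()$nSubjects, 108L)
})
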
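# End-to-end synthetic reproduction of the factorial study design:
# 2 actuator positions x 3 vibration frequencies x 2 body sides x
# n subjects, two simulated observers, per-cell agreement statistics and
# the Friedman / pairwise-Wilcoxon factorial analysis.

#' Default per-cell ground-truth stiffness table
#'
#' Mean and SD of shear stiffness (kPa) for every actuator-position x
#' frequency x side cell, taken from the published group means of the upper
#' trapezius: a strong along-fibre (VAP) versus cross-fibre (HAP) contrast
#' and an along-fibre dispersion (stiffness rising with frequency) that is
#' absent across fibres.
#'
#' @return data.frame with columns \code{position}, \code{frequencyHz},
#'   \code{side}, \code{meanKPa}, \code{sdKPa}.
#' @export
defaultCellTable <- function() {
  data.frame(
    position = rep(c("VAP", "HAP"), each = 6),
    frequencyHz = rep(c(60, 80, 100), times = 4),
    side = rep(rep(c("left", "right"), each = 3), times = 2),
    meanKPa = c(4.25, 6.38, 8.35, 4.22, 7.19, 10.1,
                1.92, 1.85, 1.95, 1.68, 1.81, 2.28),
    sdKPa = c(0.64, 1.92, 3.04, 1.56, 2.97, 3.64,
              0.96, 0.86, 0.62, 0.76, 0.80, 1.09),
    stringsAsFactors = FALSE
  )
}

#' Factorial study design
#'
#' @param nSubjects number of subjects (default 9).
#' @param cellTable per-cell ground-truth means and SDs; see
#'   \code{\link{defaultCellTable}}.
#' @param subjectShare fraction of the log-scale stiffness variance shared
#'   by a subject across all 12 cells (a stiff subject is stiff
#'   everywhere); the per-cell marginal CV always matches \code{cellTable}.
#' @param conditionShare additional variance fraction shared across the
#'   three frequencies within one position x side (dispersion is a tissue
#'   property, so within a subject stiffness moves coherently with
#'   frequency); \code{subjectShare + conditionShare <= 1}.
#' @param matrixSize phantom matrix size.
#' @param noiseSigma per-channel complex noise SD in the phantoms.
#' @return A list of class \code{"StudyDesign"}.
#' @export
studyDesign <- function(nSubjects = 9L, cellTable = defaultCellTable(),
                        subjectShare = 0.5, conditionShare = 0.4,
                        matrixSize = 128L, noiseSigma = 3) {
  if (nSubjects < 2L) stop("need at least 2 subjects")
  need <- c("position", "frequencyHz", "side", "meanKPa", "sdKPa")
  if (!all(need %in% names(cellTable)))
    stop("cellTable must have columns ", paste(need, collapse = ", "))
  if (nrow(cellTable) != 12L)
    stop("cellTable must specify all 12 position x frequency x side cells")
  if (subjectShare < 0 || conditionShare < 0 ||
      subjectShare + conditionShare > 1)
    stop("subjectShare and conditionShare must be >= 0 and sum to <= 1")
  structure(list(nSubjects = as.integer(nSubjects), cellTable = cellTable,
                 subjectShare = subjectShare,
                 conditionShare = conditionShare,
                 matrixSize = as.integer(matrixSize),
                 noiseSigma = noiseSigma),
            class = "StudyDesign")
}

# Effective per-cell ground-truth means: along fibres (VAP) stiffness
# follows the power-law dispersion with gamma fitted per side to the
# printed means (anchored at 60 Hz); across fibres (HAP) it is
# frequency-flat at the side's average. This builds the study's effect
# structure -- dispersion only along fibres -- into the ground truth.
.effectiveCellMeans <- function(cellTable) {
  out <- cellTable$meanKPa
  for (p in unique(cellTable$position)) {
    for (s in unique(cellTable$side)) {
      sel <- which(cellTable$position == p & cellTable$side == s)
      f <- cellTable$frequencyHz[sel]
      mu <- cellTable$meanKPa[sel]
      if (p == "VAP") {
        g <- fitDispersionGamma(f, mu, 60)
        out[sel] <- mu[f == 60] * (f / 60)^g
      } else {
        out[sel] <- mean(mu)
      }
    }
  }
  out
}

# Per-subject, per-cell lognormal stiffness draws with a hierarchical
# log-scale deviation: sqrt(s1)*z_subject + sqrt(s2)*z_{subject,pos,side} +
# sqrt(1-s1-s2)*z_cell. The marginal per-cell CV equals the cell table's
# SD/mean; frequencies within one position x side are the most correlated.
# Returns a matrix [subject, cell] in kPa.
.drawSubjectStiffness <- function(design, seed) {
  ct <- design$cellTable
  nS <- design$nSubjects
  nC <- nrow(ct)
  grp <- as.integer(factor(paste(ct$position, ct$side)))
  set.seed(seed)
  zSub <- stats::rnorm(nS)
  zGrp <- matrix(stats::rnorm(nS * max(grp)), nS, max(grp))
  zCell <- matrix(stats::rnorm(nS * nC), nS, nC)
  s1 <- design$subjectShare
  s2 <- design$conditionShare
  effMean <- .effectiveCellMeans(ct)
  out <- matrix(0, nS, nC)
  for (j in seq_len(nC)) {
    cv <- ct$sdKPa[j] / ct$meanKPa[j]
    sdl <- sqrt(log1p(cv^2))
    ml <- log(effMean[j]) - sdl^2 / 2
    z <- sqrt(s1) * zSub + sqrt(s2) * zGrp[, grp[j]] +
      sqrt(1 - s1 - s2) * zCell[, j]
    out[, j] <- exp(ml + sdl * z)
  }
  out
}

#' Generate the full grid of synthetic study datasets
#'
#' One phantom per position x frequency x side x subject cell (12 x
#' nSubjects datasets; 108 for the default 9 subjects). VAP cells use
#' horizontal (along-fibre) wave propagation, HAP cells vertical
#' (cross-fibre); per-subject ground-truth stiffness is drawn lognormally
#' around the cell means with subject effects shared across cells.
#' Deterministic under a fixed seed.
#'
#' @param design a \code{\link{studyDesign}}.
#' @param seed master RNG seed.
#' @return A list with \code{entries} (one element per dataset: the phantom
#'   output plus factor levels and per-dataset seeds) and \code{truthKPa}
#'   (subject x cell matrix).
#' @export
makeStudyInputs <- function(design, seed = 1L) {
  stopifnot(inherits(design, "StudyDesign"))
  ct <- design$cellTable
  nS <- design$nSubjects
  nC <- nrow(ct)
  streams <- .seedStreams(seed, 1L + 3L * nS * nC)
  truth <- .drawSubjectStiffness(design, streams[1L])
  entries <- vector("list", nS * nC)
  e <- 0L
  for (j in seq_len(nC)) {
    for (s in seq_len(nS)) {
      e <- e + 1L
      base <- 1L + 3L * (e - 1L)
      muPa <- truth[s, j] * 1000
      angle <- if (ct$position[j] == "VAP") 0 else 90
      # visible extent along the propagation direction: the muscle is long
      # along its fibres (VAP waves run along it) but narrow across them
      # (HAP waves cross it), so roughly 1-2 wavelengths are in view either
      # way, as in the published score distribution
      geo <- if (ct$position[j] == "VAP")
        list(lengthMM = 60, widthMM = 24)
      else list(lengthMM = 32, widthMM = 20)
      spec <- phantomSpec(mu0Pa = muPa, gamma = 0, f0Hz = ct$frequencyHz[j],
                          propagationAngleDeg = angle,
                          roiGeometry = geo,
                          noiseSigma = design$noiseSigma,
                          matrixSize = design$matrixSize,
                          seed = streams[base + 1L])
      m <- acquisitionMeta(frequencyHz = ct$frequencyHz[j],
                           actuatorPosition = ct$position[j],
                           side = ct$side[j],
                           subjectId = sprintf("S%02d", s))
      ph <- makePhantom(spec, m)
      entries[[e]] <- c(ph, list(position = ct$position[j],
                                 frequencyHz = ct$frequencyHz[j],
                                 side = ct$side[j], subject = s,
                                 cell = j,
                                 observerSeeds = streams[base + 2:3]))
    }
  }
  list(entries = entries, truthKPa = truth, design = design)
}

#' Run the full synthetic two-observer study
#'
#' For every dataset in the grid the caliper pipeline is run once per
#' observer (each observer is an independently seeded jitter of the profile
#' geometry); per-cell agreement statistics and the 12-condition Friedman /
#' pairwise-Wilcoxon factorial analyses for stiffness and for quality
#' scores are assembled. Fully deterministic under a fixed seed.
#'
#' @param design a \code{\link{studyDesign}}.
#' @param observers list of two \code{\link{observerModel}}s.
#' @param seed master RNG seed.
#' @return A list of class \code{"StudyResult"}: \code{measurements}
#'   (long data.frame, one row per dataset x observer), \code{cells}
#'   (per-cell list with the \code{\link{AgreementReport}}),
#'   \code{factorialStiffness} and \code{factorialQuality}
#'   (\code{\link{FactorialResult}}), \code{snr} (per-dataset SNR table),
#'   \code{truthKPa}, and \code{design}.
#' @export
runStudy <- function(design = studyDesign(),
                     observers = list(observerModel(), observerModel()),
                     seed = 1L) {
  stopifnot(length(observers) == 2L)
  inputs <- makeStudyInputs(design, seed)
  entries <- inputs$entries
  rows <- vector("list", 2L * length(entries))
  snrRows <- vector("list", length(entries))
  failures <- character(0)
  for (i in seq_along(entries)) {
    en <- entries[[i]]
    # noise-free phantoms have zero background variance; SNR is undefined
    snrVal <- tryCatch(
      computeSNR(magnitude(en$dataset), en$roi, en$background)@snr,
      error = function(e) NA_real_)
    snrRows[[i]] <- data.frame(position = en$position,
                               frequencyHz = en$frequencyHz, side = en$side,
                               subject = en$subject, snr = snrVal)
    for (o in 1:2) {
      set.seed(en$observerSeeds[o])
      res <- tryCatch(
        estimateStiffness(en$dataset, en$roi, background = en$background,
                          observer = observers[[o]]),
        error = function(e) NULL)
      rows[[2L * (i - 1L) + o]] <- data.frame(
        position = en$position, frequencyHz = en$frequencyHz,
        side = en$side, subject = en$subject, observer = o,
        muKPa = if (is.null(res)) NA_real_ else res@muPa / 1000,
        lambdaMM = if (is.null(res)) NA_real_ else res@lambdaMeanM * 1000,
        quality = if (is.null(res)) NA_integer_ else res@datasetScore,
        muTrueKPa = inputs$truthKPa[en$subject, en$cell],
        stringsAsFactors = FALSE)
      if (is.null(res))
        failures <- c(failures,
                      sprintf("%s/%g Hz/%s subject %d observer %d",
                              en$position, en$frequencyHz, en$side,
                              en$subject, o))
    }
  }
  meas <- do.call(rbind, rows)
  snrTab <- do.call(rbind, snrRows)

  ct <- design$cellTable
  cells <- vector("list", nrow(ct))
  for (j in seq_len(nrow(ct))) {
    sel <- meas$position == ct$position[j] &
      meas$frequencyHz == ct$frequencyHz[j] & meas$side == ct$side[j]
    a <- meas[sel & meas$observer == 1L, ]
    b <- meas[sel & meas$observer == 2L, ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    ok <- !is.na(a$muKPa) & !is.na(b$muKPa)
    rep <- if (sum(ok) >= 2L)
      agreementReport(a$quality[ok], b$quality[ok], a$muKPa[ok], b$muKPa[ok])
    else NULL
    cells[[j]] <- list(position = ct$position[j],
                       frequencyHz = ct$frequencyHz[j], side = ct$side[j],
                       n = sum(ok), report = rep,
                       meanQuality = mean(c(a$quality[ok], b$quality[ok])),
                       stiffMeanKPa = mean((a$muKPa[ok] + b$muKPa[ok]) / 2),
                       stiffSDKPa = if (sum(ok) >= 2L)
                         stats::sd((a$muKPa[ok] + b$muKPa[ok]) / 2)
                       else NA_real_)
  }

  condLabel <- function(p, f, s) sprintf("%s_%g_%s", p, f, s)
  condMat <- function(value) {
    m <- matrix(NA_real_, design$nSubjects, nrow(ct),
                dimnames = list(NULL, condLabel(ct$position, ct$frequencyHz,
                                                ct$side)))
    for (j in seq_len(nrow(ct))) {
      sel <- meas$position == ct$position[j] &
        meas$frequencyHz == ct$frequencyHz[j] & meas$side == ct$side[j]
      sub <- meas[sel, ]
      agg <- tapply(sub[[value]], sub$subject, mean)
      m[as.integer(names(agg)), j] <- agg
    }
    m
  }
  # complete-case blocks: a subject with any failed measurement drops out
  # of the factorial analysis (the failure stays recorded)
  stiffMat <- condMat("muKPa")
  qualMat <- condMat("quality")
  keep <- stats::complete.cases(stiffMat)
  allPairs <- t(utils::combn(ncol(stiffMat), 2))
  factStiff <- if (sum(keep) >= 2L)
    friedmanAnalysis(stiffMat[keep, , drop = FALSE], pairwise = allPairs)
  else NULL
  keepQ <- stats::complete.cases(qualMat)
  factQual <- if (sum(keepQ) >= 2L)
    friedmanAnalysis(qualMat[keepQ, , drop = FALSE]) else NULL

  structure(list(measurements = meas, cells = cells,
                 factorialStiffness = factStiff, factorialQuality = factQual,
                 snr = snrTab, stiffnessByCondition = stiffMat,
                 qualityByCondition = qualMat,
                 truthKPa = inputs$truthKPa, design = design,
                 failures = failures, seed = seed),
            class = "StudyResult")
}

#' Per-cell summary table in the published layout
#'
#' One row per position x frequency x side with the cell's mean quality
#' score, kappa, stiffness mean and SD, ICC, limits of agreement, bias and
#' CV. Cells whose statistics are undefined are reported as NA.
#'
#' @param result a \code{\link{runStudy}} result.
#' @return data.frame with 12 rows.
#' @export
summarizeTable <- function(result) {
  stopifnot(inherits(result, "StudyResult"))
  rows <- lapply(result$cells, function(cl) {
    r <- cl$report
    data.frame(position = cl$position, frequencyHz = cl$frequencyHz,
               side = cl$side, n = cl$n,
               meanQualityScore = cl$meanQuality,
               kappa = if (is.null(r)) NA_real_ else r@kappa,
               stiffnessMeanKPa = cl$stiffMeanKPa,
               stiffnessSDKPa = cl$stiffSDKPa,
               icc = if (is.null(r)) NA_real_ else r@icc,
               loaKPa = if (is.null(r)) NA_real_ else r@loa,
               ubKPa = if (is.null(r)) NA_real_ else r@ub,
               lbKPa = if (is.null(r)) NA_real_ else r@lb,
               biasKPa = if (is.null(r)) NA_real_ else r@bias,
               cvPercent = if (is.null(r)) NA_real_ else r@cvPercent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check the study's qualitative findings on a StudyResult
#'
#' Four assertions, each with the supporting adjusted p-values:
#' (a) stiffness under along-fibre propagation (VAP) exceeds cross-fibre
#' (HAP) at every frequency and side (paired Wilcoxon, Bonferroni over the
#' 6 comparisons); (b) VAP stiffness increases monotonically with frequency
#' with significant pairwise differences (per-side family of 3 frequency
#' comparisons); (c) no significant frequency effect under HAP (same
#' families); (d) no significant left-right asymmetry (6 side comparisons,
#' Bonferroni).
#'
#' @param result a \code{\link{runStudy}} result.
#' @return A list with one element per assertion: \code{holds} plus the
#'   relevant statistics.
#' @export
checkFindings <- function(result) {
  stopifnot(inherits(result, "StudyResult"))
  m <- result$stiffnessByCondition
  lbl <- function(p, f, s) sprintf("%s_%g_%s", p, f, s)

  # paired Wilcoxon with pairwise-complete deletion
  pairP <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) return(NA_real_)
    if (all(a[ok] == b[ok])) return(1)
    suppressWarnings(stats::wilcox.test(a[ok], b[ok], paired = TRUE)$p.value)
  }
  bonf <- function(p, k) pmin(1, k * p)

  # (a) VAP > HAP at each frequency, sides pooled (subject x side pairs),
  # Bonferroni over the 3 frequencies; cell means must also be ordered
  pA <- vapply(c(60, 80, 100), function(f) {
    a <- c(m[, lbl("VAP", f, "left")], m[, lbl("VAP", f, "right")])
    b <- c(m[, lbl("HAP", f, "left")], m[, lbl("HAP", f, "right")])
    pairP(a, b)
  }, numeric(1))
  cellDiff <- vapply(seq_len(6), function(i) {
    f <- rep(c(60, 80, 100), 2)[i]
    s <- rep(c("left", "right"), each = 3)[i]
    mean(m[, lbl("VAP", f, s)], na.rm = TRUE) -
      mean(m[, lbl("HAP", f, s)], na.rm = TRUE)
  }, numeric(1))
  a <- list(holds = all(bonf(pA, 3) < 0.05) && all(cellDiff > 0),
            pAdj = bonf(pA, 3), cellMeanDiff = cellDiff)

  # (b) VAP dispersion: per-side family of the 3 frequency comparisons
  dispHolds <- TRUE
  dispP <- list()
  for (s in c("left", "right")) {
    cols <- lbl("VAP", c(60, 80, 100), s)
    p3 <- c(`80v60` = pairP(m[, cols[2L]], m[, cols[1L]]),
            `100v80` = pairP(m[, cols[3L]], m[, cols[2L]]),
            `100v60` = pairP(m[, cols[3L]], m[, cols[1L]]))
    mono <- mean(m[, cols[1L]], na.rm = TRUE) <
      mean(m[, cols[2L]], na.rm = TRUE) &&
      mean(m[, cols[2L]], na.rm = TRUE) < mean(m[, cols[3L]], na.rm = TRUE)
    dispHolds <- dispHolds && mono && all(bonf(p3, 3) < 0.05)
    dispP[[s]] <- bonf(p3, 3)
  }
  b <- list(holds = dispHolds, pAdj = dispP)

  # (c) HAP: no significant frequency effect (same families)
  hapP <- list()
  for (s in c("left", "right")) {
    cols <- lbl("HAP", c(60, 80, 100), s)
    p3 <- c(`80v60` = pairP(m[, cols[2L]], m[, cols[1L]]),
            `100v80` = pairP(m[, cols[3L]], m[, cols[2L]]),
            `100v60` = pairP(m[, cols[3L]], m[, cols[1L]]))
    hapP[[s]] <- bonf(p3, 3)
  }
  cRes <- list(holds = all(unlist(hapP) >= 0.05), pAdj = hapP)

  # (d) no left-right asymmetry (6 comparisons, Bonferroni)
  pD <- vapply(seq_len(6), function(i) {
    p <- rep(c("VAP", "HAP"), each = 3)[i]
    f <- rep(c(60, 80, 100), 2)[i]
    pairP(m[, lbl(p, f, "left")], m[, lbl(p, f, "right")])
  }, numeric(1))
  d <- list(holds = all(bonf(pD, 6) >= 0.05), pAdj = bonf(pD, 6))

  list(vapExceedsHap = a, vapDispersion = b, hapNoFrequencyEffect = cRes,
       noSideAsymmetry = d)
}
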
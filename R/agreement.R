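# Two-observer reproducibility and factorial statistics: Cohen's kappa with
# qualitative bands, two-way mixed ICC, Bland-Altman limits of agreement,
# coefficient of variation, Friedman test and pairwise Wilcoxon with
# Bonferroni correction.

#' Qualitative band for a Cohen's kappa value
#'
#' Cut-points: 0 poor; (0, 0.20] slight; (0.20, 0.40] fair; (0.40, 0.60]
#' moderate; (0.60, 0.80] substantial; (0.80, 1] almost perfect. Negative
#' values are labelled poor.
#'
#' @param kappa numeric kappa value.
#' @return A band label.
#' @export
kappaBandLabel <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Unweighted Cohen's kappa for two raters
#'
#' kappa = (p_o - p_e) / (1 - p_e), with p_o the observed agreement and p_e
#' the chance agreement from the raters' marginal distributions over the
#' stated category set.
#'
#' @param ratingsA,ratingsB equal-length vectors of ordinal ratings.
#' @param categories the full category set (default: union of observed
#'   values).
#' @return A list with \code{kappa} and \code{band}.
#' @examples
#' cohensKappa(c(1, 1, 2, 2), c(1, 2, 1, 2))  # kappa = 0
#' @export
cohensKappa <- function(ratingsA, ratingsB, categories = NULL) {
  if (length(ratingsA) != length(ratingsB))
    stop("rating vectors must have equal length")
  if (length(ratingsA) == 0L) stop("no ratings supplied")
  if (is.null(categories))
    categories <- sort(unique(c(ratingsA, ratingsB)))
  fa <- factor(ratingsA, levels = categories)
  fb <- factor(ratingsB, levels = categories)
  if (anyNA(fa) || anyNA(fb))
    stop("ratings contain values outside the stated categories")
  n <- length(fa)
  po <- mean(fa == fb)
  pe <- sum((table(fa) / n) * (table(fb) / n))
  if (1 - pe < .Machine$double.eps)
    stop("chance agreement is 1; kappa is undefined")
  k <- (po - pe) / (1 - pe)
  list(kappa = k, band = kappaBandLabel(k))
}

#' Two-way mixed-model intraclass correlation
#'
#' Single-rater ICC from the two-way (subjects x raters) ANOVA
#' decomposition. The default, consistency form is
#' ICC(3,1) = (MS_rows - MS_err) / (MS_rows + (k-1) * MS_err); the
#' absolute-agreement form additionally charges the rater variance:
#' (MS_rows - MS_err) / (MS_rows + (k-1)MS_err + k(MS_col - MS_err)/n).
#'
#' @param mat numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, >= 3 subjects and >= 2 raters.
#' @param type \code{"consistency"} (default) or \code{"agreement"}.
#' @return The ICC value.
#' @export
iccTwoWayMixed <- function(mat, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must have no missing cells")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 raters")
  grand <- mean(mat)
  rowM <- rowMeans(mat)
  colM <- colMeans(mat)
  ssRow <- k * sum((rowM - grand)^2)
  ssCol <- n * sum((colM - grand)^2)
  ssTot <- sum((mat - grand)^2)
  ssErr <- ssTot - ssRow - ssCol
  if (ssTot < .Machine$double.eps)
    stop("zero total variance; ICC is undefined")
  msRow <- ssRow / (n - 1)
  msCol <- ssCol / (k - 1)
  msErr <- ssErr / ((n - 1) * (k - 1))
  if (type == "consistency")
    (msRow - msErr) / (msRow + (k - 1) * msErr)
  else
    (msRow - msErr) /
      (msRow + (k - 1) * msErr + k * (msCol - msErr) / n)
}

#' Qualitative band for an ICC value (Koo-Li cut-points)
#'
#' < 0.5 poor; 0.5-0.75 moderate; 0.75-0.9 good; > 0.9 excellent.
#' @param icc numeric ICC value.
#' @return A band label.
#' @export
iccBandLabel <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good" else "excellent"
}

#' Bland-Altman agreement analysis
#'
#' Differences d_i = a_i - b_i; bias = mean(d), sd_diff = sample SD(d),
#' limits of agreement LoA = 1.96 * sd_diff, upper/lower bounds
#' ub/lb = bias +/- LoA, and a 95\% t-based confidence interval for the
#' bias.
#'
#' @param a,b equal-length paired measurement vectors (>= 2 pairs).
#' @return A list with \code{bias}, \code{sdDiff}, \code{loa}, \code{ub},
#'   \code{lb} and \code{biasCI} (length 2).
#' @examples
#' blandAltman(c(0, 2), c(0, 0))  # bias 1, loa ~ 2.772
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sdDiff <- stats::sd(d)
  loa <- 1.96 * sdDiff
  n <- length(d)
  half <- stats::qt(0.975, n - 1) * sdDiff / sqrt(n)
  list(bias = bias, sdDiff = sdDiff, loa = loa,
       ub = bias + loa, lb = bias - loa,
       biasCI = c(bias - half, bias + half))
}

#' Mean per-pair coefficient of variation, in percent
#'
#' For each pair the CV is the sample SD of the two values divided by their
#' mean; the reported value is 100 times the average over pairs. (A pooled
#' alternative, 100 * SD of all differences-based residual over the grand
#' mean, is available via \code{method = "pooled"}.)
#'
#' @param a,b equal-length paired measurement vectors with positive pair
#'   means.
#' @param method \code{"perPair"} (default) or \code{"pooled"}.
#' @return CV in percent.
#' @examples
#' cvPercent(3, 5)  # 35.36
#' @export
cvPercent <- function(a, b, method = c("perPair", "pooled")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  means <- (a + b) / 2
  if (any(means <= 0)) stop("all pair means must be positive")
  if (method == "perPair") {
    cvs <- abs(a - b) / sqrt(2) / means
    100 * mean(cvs)
  } else {
    sdw <- sqrt(mean((a - b)^2 / 2))
    100 * sdw / mean(means)
  }
}

#' Friedman test over a complete block design
#'
#' Within-subject mid-ranks with tie correction; chi-squared statistic with
#' df = k - 1 and upper-tail p-value (delegates to
#' \code{stats::friedman.test}).
#'
#' @param mat numeric matrix, subjects (blocks) in rows, conditions in
#'   columns; complete, >= 2 rows and columns.
#' @param pairwise optional 2-column matrix of condition-index pairs to
#'   compare post hoc with \code{\link{pairwiseWilcoxon}}.
#' @return A \code{\link{FactorialResult}}.
#' @export
friedmanAnalysis <- function(mat, pairwise = NULL) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("incomplete blocks: matrix must have no missing cells")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 subjects and 2 conditions")
  ft <- stats::friedman.test(mat)
  # fully tied blocks (e.g. identical columns) make the tie-corrected
  # statistic 0/0; there is no evidence against the null
  if (is.nan(ft$statistic)) {
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  pw <- if (is.null(pairwise)) {
    data.frame(a = integer(0), b = integer(0), pRaw = numeric(0),
               pAdj = numeric(0), flag = character(0))
  } else {
    pairwiseWilcoxon(mat, pairwise)
  }
  new("FactorialResult", chi2 = unname(ft$statistic),
      df = as.integer(ft$parameter), p = unname(ft$p.value), pairwise = pw)
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' For each requested pair of conditions a paired two-sided Wilcoxon
#' signed-rank test is run (exact null distribution when the number of
#' non-zero differences is small and untied, normal approximation with
#' continuity correction otherwise, as in \code{stats::wilcox.test});
#' adjusted p = min(1, m * p_raw) with m the number of comparisons. Pairs
#' whose differences are all zero get p = 1 and are flagged.
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns.
#' @param comparisons 2-column matrix (or data.frame) of column indices or
#'   column names to compare.
#' @return data.frame with columns \code{a}, \code{b}, \code{pRaw},
#'   \code{pAdj}, \code{flag}.
#' @export
pairwiseWilcoxon <- function(mat, comparisons) {
  mat <- as.matrix(mat)
  cmp <- as.matrix(comparisons)
  if (ncol(cmp) != 2L) stop("comparisons must have two columns")
  m <- nrow(cmp)
  res <- data.frame(a = character(m), b = character(m), pRaw = numeric(m),
                    pAdj = numeric(m), flag = character(m),
                    stringsAsFactors = FALSE)
  colIdx <- function(x) {
    if (is.character(x)) match(x, colnames(mat)) else as.integer(x)
  }
  for (i in seq_len(m)) {
    ia <- colIdx(cmp[i, 1L]); ib <- colIdx(cmp[i, 2L])
    if (is.na(ia) || is.na(ib)) stop("unknown condition in comparison ", i)
    x <- mat[, ia]; y <- mat[, ib]
    d <- x - y
    if (all(d == 0)) {
      p <- 1
      flag <- "all differences zero"
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE)$p.value)
      flag <- ""
    }
    nmA <- if (!is.null(colnames(mat))) colnames(mat)[ia] else as.character(ia)
    nmB <- if (!is.null(colnames(mat))) colnames(mat)[ib] else as.character(ib)
    res$a[i] <- nmA; res$b[i] <- nmB
    res$pRaw[i] <- p
    res$flag[i] <- flag
  }
  res$pAdj <- pmin(1, m * res$pRaw)
  res
}

#' Assemble the full agreement report for one study cell
#'
#' @param scoresA,scoresB the two observers' wave-quality scores.
#' @param stiffA,stiffB the two observers' stiffness measurements (kPa).
#' @param categories kappa category set (default 1:5).
#' @return An \code{\link{AgreementReport}}. Kappa and ICC are \code{NA}
#'   (with \code{NA} band) when undefined for the supplied data.
#' @export
agreementReport <- function(scoresA, scoresB, stiffA, stiffB,
                            categories = 1:5) {
  kap <- tryCatch(cohensKappa(scoresA, scoresB, categories),
                  error = function(e) list(kappa = NA_real_,
                                           band = NA_character_))
  icc <- tryCatch(iccTwoWayMixed(cbind(stiffA, stiffB)),
                  error = function(e) NA_real_)
  ba <- blandAltman(stiffA, stiffB)
  cv <- tryCatch(cvPercent(stiffA, stiffB), error = function(e) NA_real_)
  new("AgreementReport", kappa = kap$kappa, kappaBand = kap$band, icc = icc,
      bias = ba$bias, sdDiff = ba$sdDiff, loa = ba$loa, ub = ba$ub,
      lb = ba$lb, biasCI = ba$biasCI, cvPercent = cv)
}
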
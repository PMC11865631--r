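test_that("Cohen's kappa matches hand computation and banding", {
  r <- cohensKappa(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$kappa, 1)
  expect_identical(r$band, "almost perfect")

  # hand case: p_o = 0.5, p_e = 0.5, kappa = 0
  r0 <- cohensKappa(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(r0$kappa, 0)
  expect_identical(r0$band, "poor")

  expect_identical(kappaBandLabel(0.83), "almost perfect")
  expect_identical(kappaBandLabel(0.80), "substantial")
  expect_identical(kappaBandLabel(0.61), "substantial")
  expect_identical(kappaBandLabel(0.45), "moderate")

  expect_error(cohensKappa(1:3, 1:4), "length")
  expect_error(cohensKappa(c(2, 2), c(2, 2)), "undefined")

  # permutation invariance over subjects
  set.seed(8)
  a <- sample(1:5, 30, TRUE); b <- pmin(5, a + sample(0:1, 30, TRUE))
  p <- sample(30)
  expect_equal(cohensKappa(a, b, 1:5)$kappa,
               cohensKappa(a[p], b[p], 1:5)$kappa)
})

test_that("two-way mixed ICC matches its variance-component construction", {
  set.seed(11)
  x <- rnorm(20)
  expect_equal(iccTwoWayMixed(cbind(x, x)), 1)

  # subjects ~ var 4, independent rater error ~ var 1 -> ICC ~ 0.8
  n <- 10000
  s <- rnorm(n, 0, 2)
  m <- cbind(s + rnorm(n), s + rnorm(n))
  expect_equal(iccTwoWayMixed(m), 0.8, tolerance = 0.025)

  # independent noise columns -> ICC ~ 0
  m0 <- cbind(rnorm(n), rnorm(n))
  expect_lt(abs(iccTwoWayMixed(m0)), 0.03)

  # oracle: mean squares from aov on a small balanced layout
  set.seed(12)
  y <- matrix(rnorm(18), 6, 3)
  df <- data.frame(y = as.vector(y),
                   subj = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  ms <- anova(aov(y ~ subj + rater, df))[["Mean Sq"]]
  oracle <- (ms[1] - ms[3]) / (ms[1] + 2 * ms[3])
  expect_equal(iccTwoWayMixed(y), oracle, tolerance = 1e-10)

  expect_error(iccTwoWayMixed(matrix(1, 5, 2)), "undefined")
  expect_error(iccTwoWayMixed(matrix(rnorm(4), 2, 2)), "3 subjects")

  # permutation invariance
  yv <- matrix(rnorm(24), 12, 2)
  expect_equal(iccTwoWayMixed(yv), iccTwoWayMixed(yv[sample(12), ]))
})

test_that("Bland-Altman reproduces the hand examples and its identities", {
  r <- blandAltman(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$bias, 0); expect_equal(r$loa, 0)

  r1 <- blandAltman(c(2, 3, 4, 5), c(1, 2, 3, 4))   # d = {1,1,1,1}
  expect_equal(r1$bias, 1); expect_equal(r1$sdDiff, 0)
  expect_equal(r1$ub, 1); expect_equal(r1$lb, 1)

  r2 <- blandAltman(c(0, 2), c(0, 0))   # d = {0, 2}
  expect_equal(r2$bias, 1)
  expect_equal(r2$sdDiff, sqrt(2))
  expect_equal(r2$loa, 1.96 * sqrt(2))   # ~ 2.772
  expect_equal(r2$ub - r2$lb, 2 * r2$loa)

  # antisymmetry of the bias
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(blandAltman(a, b)$bias, -blandAltman(b, a)$bias)

  expect_error(blandAltman(1, 2), "2 pairs")
})

test_that("coefficient of variation is the per-pair mean and scale-invariant", {
  expect_equal(cvPercent(c(4, 4), c(4, 4)), 0)
  expect_equal(cvPercent(3, 5), 100 * (2 / sqrt(2)) / 4)  # 35.36%
  set.seed(6)
  a <- runif(8, 2, 6); b <- runif(8, 2, 6)
  expect_equal(cvPercent(a, b), cvPercent(3 * a, 3 * b))
  expect_error(cvPercent(c(1, -1), c(1, 1)), "positive")
})

test_that("Friedman analysis has the factorial df and matches enumeration", {
  # identical columns: no evidence, chi2 = 0, p = 1
  same <- matrix(rep(c(3, 1, 4, 1, 5), 3), 5, 3)
  r <- friedmanAnalysis(same)
  expect_equal(r@chi2, 0)
  expect_equal(r@p, 1)

  # 12 conditions -> df = 11
  set.seed(13)
  m12 <- matrix(rnorm(9 * 12), 9, 12)
  expect_identical(friedmanAnalysis(m12)@df, 11L)

  # rank invariance under monotone within-block transformations
  m <- matrix(rnorm(15), 5, 3)
  expect_equal(friedmanAnalysis(m)@chi2, friedmanAnalysis(exp(m))@chi2)

  # permutation oracle, 3 conditions x 5 subjects: in the rejection region
  # the chi-squared tail agrees with full enumeration of the 6^5
  # within-block orderings to within 0.01 (mid-range p-values differ more;
  # the approximation is a tail approximation)
  set.seed(14)
  m5 <- matrix(rnorm(15, sd = 0.5) + rep(c(0, 2, 4), each = 5), 5, 3)
  pChi <- friedmanAnalysis(m5)@p
  pPerm <- friedmanPermP(m5)
  expect_lt(pPerm, 0.05)
  expect_lt(abs(pChi - pPerm), 0.01)

  expect_error(friedmanAnalysis(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
})

test_that("pairwise Wilcoxon applies Bonferroni and equals sign enumeration", {
  # identical conditions: flagged, adjusted p = 1
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 3, 4, 6))
  res <- pairwiseWilcoxon(m, rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(res$pAdj[1], 1)
  expect_match(res$flag[1], "zero")
  # Bonferroni definition: adjusted = m * raw, capped at 1
  expect_equal(res$pAdj, pmin(1, 3 * res$pRaw))

  # exact test equals brute-force enumeration of all sign assignments
  set.seed(15)
  for (n in c(6, 9)) {
    d <- round(rnorm(n, 0.6), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n, 0.6), 3)
    x <- cumsum(runif(n)); y <- x - d
    pPkg <- pairwiseWilcoxon(cbind(x, y), rbind(c(1, 2)))$pRaw
    expect_equal(pPkg, wilcoxonEnumP(d), tolerance = 1e-12)
  }
})

test_that("agreementReport assembles all components and degrades to NA", {
  set.seed(16)
  sA <- c(4, 5, 4, 4, 5, 3, 4, 5, 4)
  sB <- c(4, 5, 4, 5, 5, 3, 4, 4, 4)
  a <- rlnorm(9, log(4), 0.3); b <- a * rlnorm(9, 0, 0.05)
  rep <- agreementReport(sA, sB, a, b)
  expect_equal(rep@kappa, cohensKappa(sA, sB, 1:5)$kappa)
  expect_equal(rep@icc, iccTwoWayMixed(cbind(a, b)))
  expect_equal(rep@loa, 1.96 * rep@sdDiff)
  expect_true(rep@lb <= rep@bias && rep@bias <= rep@ub)

  # degenerate: both observers constant and identical -> kappa NA
  repc <- agreementReport(rep(5, 9), rep(5, 9), a, b)
  expect_true(is.na(repc@kappa))
})
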
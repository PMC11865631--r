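# Fixtures built in code.

# A pure plane-wave harmonic field: H = A * exp(i*2*pi*d/lambda), d the
# projection onto the unit direction (dx, dy), optional exponential
# amplitude decay. arg(H) increases along propagation, matching the
# package's harmonic convention.
planeWaveField <- function(n = 96, lambdaMM = 20, angleDeg = 0,
                           spacingMM = 180 / 128, amplitude = 1,
                           attenuationPerMM = 0, frequencyHz = 60) {
  a <- angleDeg * pi / 180
  dx <- cos(a); dy <- sin(a)
  cc <- matrix(rep(seq_len(n), each = n), n)
  rr <- matrix(rep(seq_len(n), n), n)
  d <- ((cc - 1) * dx + (rr - 1) * dy) * spacingMM
  H <- amplitude * exp(-attenuationPerMM * pmax(d, 0)) *
    exp(2i * pi * d / lambdaMM)
  m <- acquisitionMeta(frequencyHz, pixelSpacingMM = spacingMM)
  new("WaveField", harmonic = H, meta = m)
}

# Full-image rectangular ROI with a margin.
marginROI <- function(n, margin = 8) {
  msk <- matrix(FALSE, n, n)
  msk[(margin + 1):(n - margin), (margin + 1):(n - margin)] <- TRUE
  roiMask(msk)
}

# A band ROI of given extent (mm) along the +x axis, centred in the image.
bandROI <- function(n, spacingMM, lengthMM, widthMM = 24, angleDeg = 0) {
  a <- angleDeg * pi / 180
  dx <- cos(a); dy <- sin(a)
  ctr <- (n + 1) / 2
  cc <- matrix(rep(seq_len(n), each = n), n)
  rr <- matrix(rep(seq_len(n), n), n)
  x <- (cc - ctr) * spacingMM
  y <- (rr - ctr) * spacingMM
  along <- x * dx + y * dy
  across <- -x * dy + y * dx
  roiMask(abs(along) <= lengthMM / 2 & abs(across) <= widthMM / 2)
}

# Brute-force two-sided paired Wilcoxon signed-rank p-value by enumerating
# all 2^n sign assignments (no ties/zeros assumed).
wilcoxonEnumP <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  tObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tAll <- as.vector(signs %*% r)
  pLo <- mean(tAll <= tObs)
  pHi <- mean(tAll >= tObs)
  min(1, 2 * min(pLo, pHi))
}

# Brute-force Friedman permutation p-value: enumerate all within-block
# column permutations and compare the tie-corrected statistic.
friedmanPermP <- function(mat) {
  stat <- function(m) {
    s <- stats::friedman.test(m)$statistic
    if (is.nan(s)) 0 else unname(s)
  }
  tObs <- stat(mat)
  k <- ncol(mat)
  # all k! orderings of one block, then every combination across blocks
  ordmat <- as.matrix(do.call(rbind, combinat_perms(seq_len(k))))
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(ordmat))),
                                   nrow(mat))))
  tot <- nrow(idx)
  ge <- 0
  for (i in seq_len(tot)) {
    m2 <- mat
    for (b in seq_len(nrow(mat))) m2[b, ] <- mat[b, ordmat[idx[i, b], ]]
    if (stat(m2) >= tObs - 1e-12) ge <- ge + 1
  }
  ge / tot
}

# Minimal permutations generator (avoids extra dependencies).
combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}
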
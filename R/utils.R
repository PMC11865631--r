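# Internal numerical helpers shared across modules.

# Bilinear interpolation of a real matrix at continuous (row, col) positions.
# Positions are 1-based pixel-centre coordinates; caller guarantees they lie
# inside [1, nrow] x [1, ncol].
.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(r), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1L), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

# Strict local maxima of a vector (interior points only).
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- 2:(n - 1L)
  idx[v[idx] > v[idx - 1L] & v[idx] >= v[idx + 1L]]
}

# Topographic prominence of peaks at indices `idx`: on each side walk until a
# strictly higher sample (or the signal edge) is met, take the minimum seen,
# and subtract the higher of the two side minima from the peak height.
.prominence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    leftMin <- h
    j <- i - 1L
    while (j >= 1L && v[j] <= h) {
      if (v[j] < leftMin) leftMin <- v[j]
      j <- j - 1L
    }
    rightMin <- h
    j <- i + 1L
    while (j <= length(v) && v[j] <= h) {
      if (v[j] < rightMin) rightMin <- v[j]
      j <- j + 1L
    }
    h - max(leftMin, rightMin)
  }, numeric(1))
}

# Sub-sample refinement of an extremum position by a parabola through the
# three samples around index i; returns the fractional index offset in
# [-0.5, 0.5].
.parabolicOffset <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}

# Peak positions (in units of `positions`) passing a prominence threshold,
# with parabolic sub-sample refinement. Returns numeric vector, possibly
# empty.
.refinedPeaks <- function(values, positions, minProminence) {
  idx <- .localMaxima(values)
  if (length(idx) == 0L) return(numeric(0))
  keep <- .prominence(values, idx) >= minProminence
  idx <- idx[keep]
  if (length(idx) == 0L) return(numeric(0))
  step <- positions[2L] - positions[1L]
  vapply(idx, function(i) positions[i] + .parabolicOffset(values, i) * step,
         numeric(1))
}

# Deterministic sub-seed table derived from one master seed; used so that
# independent simulation streams (per dataset, per observer) can be re-run
# in isolation. All seeds stay below 2^31.
.seedStreams <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(masterSeed))
  sample.int(.Machine$integer.max - 1L, n)
}

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
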
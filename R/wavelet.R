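# Periodic orthonormal Daubechies (4-tap) discrete wavelet transform.
# Implemented in-package: perfect reconstruction is unit-tested, and only
# this one filter family is needed for motion-artifact rejection.

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # scaling (low-pass)
  g <- rev(h) * c(1, -1, 1, -1)                           # wavelet (high-pass)
  list(h = h, g = g)
}

# One periodic analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x) {
  f <- daub4_filters()
  n <- length(x)
  idx <- function(i) ((i - 1) %% n) + 1
  k <- seq(1, n, by = 2)
  a <- d <- numeric(n / 2)
  for (m in 0:3) {
    xm <- x[idx(k + m)]
    a <- a + f$h[m + 1] * xm
    d <- d + f$g[m + 1] * xm
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  f <- daub4_filters()
  n2 <- length(a) * 2
  x <- numeric(n2)
  idx <- function(i) ((i - 1) %% n2) + 1
  k <- seq(1, n2, by = 2)
  for (m in 0:3) {
    pos <- idx(k + m)
    contrib <- f$h[m + 1] * a + f$g[m + 1] * d
    x[pos] <- x[pos] + contrib
  }
  x
}

# Multi-level periodic DWT. Length is padded by reflection to a multiple of
# 2^levels; pad length is recorded for exact truncation on inversion.
dwt_daub4 <- function(x, levels = 4) {
  n0 <- length(x)
  mult <- 2^levels
  npad <- (mult - n0 %% mult) %% mult
  if (npad > 0) x <- c(x, rev(x)[seq_len(npad)])
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details, levels = levels, n = n0, npad = npad)
}

idwt_daub4 <- function(w) {
  a <- w$approx
  for (j in rev(seq_len(w$levels))) a <- idwt_step(a, w$details[[j]])
  a[seq_len(w$n)]
}

# Zero detail coefficients lying outside median +/- mult * IQR per level —
# the outlier-rejection rule used for wavelet motion-artifact suppression.
# The series is mirror-extended (c(x, rev(x))) before the periodic DWT so
# the wrap-around point is continuous; the two mirrored reconstructions are
# averaged.
wavelet_despike <- function(x, levels = 4, iqr_mult = 4) {
  n <- length(x)
  if (n < 2^levels) return(x)
  y <- despike_once(c(x, rev(x)), levels, iqr_mult)
  (y[seq_len(n)] + rev(y[(n + 1):(2 * n)])) / 2
}

despike_once <- function(x, levels, iqr_mult) {
  w <- dwt_daub4(x, levels)
  for (j in seq_len(levels)) {
    d <- w$details[[j]]
    # skip levels with too few coefficients: the IQR estimate is unstable
    # there and the coarse band overlaps genuine signal
    if (length(d) < 128) next
    qs <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    if (iqr > 0) {
      out <- d < qs[2] - iqr_mult * iqr | d > qs[2] + iqr_mult * iqr
      d[out] <- 0
      w$details[[j]] <- d
    }
  }
  idwt_daub4(w)
}
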
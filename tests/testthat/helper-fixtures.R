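# Shared builders and independent brute-force oracles.

# hb_series from plain matrices (channels auto-named)
make_hb <- function(hbo, hbr = -0.5 * hbo, fs = 3.9063) {
  ch <- sprintf("S%03d-D%03d", seq_len(nrow(hbo)), seq_len(nrow(hbo)))
  rownames(hbo) <- rownames(hbr) <- ch
  hb_series(hbo, hbr, fs, ch)
}

# random hb cohort: independent Gaussian noise, optional common signal
make_noise_cohort <- function(n = 6, nch = 8, nT = 200, fs = 3.9063,
                              signal = NULL, signal_ch = integer(0)) {
  out <- lapply(seq_len(n), function(p) {
    hbo <- matrix(rnorm(nch * nT), nch, nT)
    hbr <- matrix(rnorm(nch * nT), nch, nT)
    if (length(signal_ch)) {
      hbo[signal_ch, ] <- hbo[signal_ch, ] +
        matrix(rep(signal, length(signal_ch)), length(signal_ch), byrow = TRUE)
      hbr[signal_ch, ] <- hbr[signal_ch, ] -
        0.8 * matrix(rep(signal, length(signal_ch)), length(signal_ch),
                     byrow = TRUE)
    }
    make_hb(hbo, hbr, fs)
  })
  names(out) <- sprintf("P%02d", seq_len(n))
  out
}

# small canonical effect cohort via the generator (shared by several tests)
small_effect_cohort <- function(seed = 7, n = 8, nch = 12, n_signal = 4,
                                duration_s = 150) {
  par <- cohort_params(n_participants = n, n_long_channels = nch,
                       n_short_channels = 2, duration_s = duration_s,
                       signal_channels_intact = seq_len(n_signal),
                       signal_channels_scrambled = seq_len(max(1, n_signal %/% 2)))
  generate_cohort(par, seed = seed)
}

# independently scramble every participant (deterministic given seed)
phase_scramble_cohort_helper <- function(hb, seed) {
  out <- lapply(seq_along(hb), function(p)
    phase_scramble(hb[[p]], seed = seed * 1000 + p))
  names(out) <- names(hb)
  out
}

# Brute-force Benjamini-Hochberg: independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Brute-force one-sample one-tailed t per column
t_oracle <- function(m) {
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    mean(x) / (sd(x) / sqrt(length(x)))
  }, numeric(1))
}

# Brute-force max-t correction: explicit loops over surrogates and channels
maxt_oracle <- function(isc, surrogates, alpha = 0.05) {
  t_obs <- t_oracle(isc)
  maxima <- numeric(length(surrogates))
  for (b in seq_along(surrogates)) {
    ts <- t_oracle(surrogates[[b]])
    maxima[b] <- max(ts)
  }
  p <- numeric(length(t_obs))
  for (ch in seq_along(t_obs)) p[ch] <- mean(maxima >= t_obs[ch])
  list(t = t_obs, p = p, significant = p < alpha)
}

# Brute-force OLS residual of y on [1, X]
ols_resid_oracle <- function(y, X) {
  D <- cbind(1, X)
  beta <- solve(t(D) %*% D, t(D) %*% y)
  as.numeric(y - D %*% beta)
}
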
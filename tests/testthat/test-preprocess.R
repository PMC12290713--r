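make_rec <- function(intens, fs = 3.9063, n_short = 0,
                     wavelengths = c(760, 850), age = 23.3) {
  nch <- dim(intens)[1]
  mont <- default_montage(nch - n_short, n_short, wavelengths)
  raw_recording("P01", age, "Intact", "story", fs, intens, mont)
}

test_that("optical density follows the log-ratio closed forms", {
  intens <- array(2, c(1, 2, 50))
  od <- intensity_to_od(make_rec(intens))
  expect_equal(max(abs(od$od)), 0)                # constant intensity -> 0
  # one sample at half the series mean: OD difference to a flat sample = ln 2
  v <- rep(1, 100)
  intens2 <- array(NA_real_, c(1, 2, 100))
  for (w in 1:2) intens2[1, w, ] <- v
  # solve x so that x = mean(c(rep(1, 99), x)) / 2  =>  x = 99/199,
  # series mean m = 198/199: OD at the dip is ln 2 relative to the log-mean
  # reference, OD elsewhere is ln m; centering cancels in the difference
  intens2[1, , 50] <- 99 / 199
  od2 <- intensity_to_od(make_rec(intens2))
  expect_equal(od2$od[1, 1, 50] - od2$od[1, 1, 1], log(2) - log(198 / 199),
               tolerance = 1e-12)
  # every series has exactly zero mean
  expect_lt(max(abs(apply(od2$od, c(1, 2), mean))), 1e-12)
  intens2[1, 1, 3] <- -1
  expect_error(intensity_to_od(make_rec(intens2)), "intensity")
})

test_that("optical density matches the forward Beer-Lambert product", {
  # known concentration changes -> forward intensities -> OD == eps*dc*dpf*rho
  nT <- 80
  dc_hbo <- 1e-6 * sin(seq(0, 6 * pi, length.out = nT))   # molar
  dc_hbr <- -0.4e-6 * sin(seq(0, 6 * pi, length.out = nT))
  ext <- extinction_for(c(760, 850))
  dpf <- c(6.1, 5.0); rho <- 3
  intens <- array(NA_real_, c(1, 2, nT))
  for (w in 1:2)
    intens[1, w, ] <- exp(-(ext$eps_hbo[w] * dc_hbo + ext$eps_hbr[w] * dc_hbr) *
                            dpf[w] * rho)
  od <- intensity_to_od(make_rec(intens))
  for (w in 1:2) {
    expected <- (ext$eps_hbo[w] * dc_hbo + ext$eps_hbr[w] * dc_hbr) * dpf[w] * rho
    expected <- expected - mean(expected)
    expect_equal(od$od[1, w, ], expected, tolerance = 1e-9)
  }
})

test_that("DPF model is positive, wavelength-ordered and inside the cohort envelope", {
  # cohort mean age 23.3: printed DPF means 6.060 (760 nm) and 5.037 (850 nm)
  expect_lt(abs(compute_dpf(23.3, 760) - 6.060), 3 * 0.095)
  expect_lt(abs(compute_dpf(23.3, 785) - 6.045), 3 * 0.073)
  expect_lt(abs(compute_dpf(23.3, 808) - 5.849), 3 * 0.073)
  expect_lt(abs(compute_dpf(23.3, 830) - 5.521), 3 * 0.073)
  expect_lt(abs(compute_dpf(23.3, 850) - 5.037), 3 * 0.091)
  expect_lt(compute_dpf(25, 850), compute_dpf(25, 760))
  grid <- expand.grid(age = 19:31, wl = c(760, 785, 808, 830, 850))
  expect_true(all(compute_dpf(grid$age, grid$wl) > 0))
  expect_error(compute_dpf(-1, 760), "age")
  expect_error(compute_dpf(25, 1500), "wavelength")
})

test_that("modified Beer-Lambert inversion recovers known concentrations", {
  nT <- 60
  hbo_uM <- 0.8 * sin(seq(0, 4 * pi, length.out = nT))
  hbr_uM <- -0.5 * sin(seq(0, 4 * pi, length.out = nT)) + 0.1
  build <- function(wls, dpf, rho = 3) {
    ext <- extinction_for(wls)
    mont <- default_montage(1, 0, wls)
    mont$rho <- rho
    od <- array(NA_real_, c(1, length(wls), nT))
    for (w in seq_along(wls))
      od[1, w, ] <- (ext$eps_hbo[w] * hbo_uM + ext$eps_hbr[w] * hbr_uM) *
        1e-6 * dpf[w] * rho
    od_to_hemoglobin(od_series(od, 3.9, mont), mont, extinction_table(), dpf)
  }
  # 2-wavelength device: exact 2x2 inversion
  hb2 <- build(c(760, 850), c(6.1, 5.0))
  expect_equal(as.numeric(hb2$hbo), hbo_uM, tolerance = 1e-9)
  expect_equal(as.numeric(hb2$hbr), hbr_uM, tolerance = 1e-9)
  # 4-wavelength device: consistent least-squares system
  hb4 <- build(c(785, 808, 830, 850), c(6.0, 5.8, 5.5, 5.0))
  expect_equal(as.numeric(hb4$hbo), hbo_uM, tolerance = 1e-9)
  expect_equal(as.numeric(hb4$hbr), hbr_uM, tolerance = 1e-9)
  # zero OD -> zero concentrations
  mont <- default_montage(1, 0, c(760, 850))
  hb0 <- od_to_hemoglobin(od_series(array(0, c(1, 2, 10)), 3.9, mont),
                          mont, extinction_table(), c(6, 5))
  expect_equal(max(abs(hb0$hbo)), 0)
  # ill-conditioned extinction matrix is refused
  bad_ext <- data.frame(wavelength = c(760, 850),
                        eps_hbo = c(100, 100.000001),
                        eps_hbr = c(50, 50.0000005))
  expect_error(od_to_hemoglobin(od_series(array(0.1, c(1, 2, 10)), 3.9, mont),
                                mont, bad_ext, c(6, 5)), "ill-conditioned")
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band content", {
  fs <- 3.9063; nT <- 4000
  t <- (seq_len(nT) - 1) / fs
  inband <- sin(2 * pi * 0.05 * t)
  outband <- sin(2 * pi * 1.0 * t)
  hb <- make_hb(rbind(inband, outband, 1 + 0 * t), fs = fs)
  out <- bandpass_filter(hb, 0.005, 0.20, 3)
  mid <- 500:3500
  expect_gt(sd(out$hbo[1, mid]) / sd(inband[mid]), 0.95)   # passband
  expect_lt(sd(out$hbo[2, mid]) / sd(outband[mid]), 0.05)  # 1 Hz attenuated
  expect_lt(abs(mean(out$hbo[3, mid])), 0.05)              # DC removed
  expect_error(bandpass_filter(hb, 0.005, 3), "band")
})

test_that("short-channel quality detects the cardiac spectral peak", {
  fs <- 3.9063; nT <- 1000
  t <- (seq_len(nT) - 1) / fs
  mont <- default_montage(1, 2, c(760, 850))
  intens <- array(NA_real_, c(3, 2, nT))
  for (w in 1:2) {
    intens[1, w, ] <- 1 + 0.01 * rnorm(nT)
    intens[2, w, ] <- 1 + 0.05 * sin(2 * pi * 1.1 * t) + 0.01 * rnorm(nT)
    intens[3, w, ] <- 1 + 0.01 * rnorm(nT)              # no cardiac: bad
  }
  rec <- raw_recording("P01", 25, "Intact", "story", fs, intens, mont)
  good <- assess_short_channel_quality(rec)
  expect_true(good[[mont$channel_id[2]]])
  expect_false(good[[mont$channel_id[3]]])
  rec_nolong <- raw_recording("P01", 25, "Intact", "story", fs,
                              intens[1, , , drop = FALSE],
                              default_montage(1, 0, c(760, 850)))
  expect_error(assess_short_channel_quality(rec_nolong), "short")
})

test_that("PCA short-channel regression matches the OLS oracle", {
  set.seed(42)
  nT <- 300
  short <- matrix(rnorm(4 * nT), 4, nT)       # 2 short channels x 2 chrom
  hb_short <- make_hb(short[1:2, ], short[3:4, ])
  resid_true <- rnorm(nT)
  resid_true <- ols_resid_oracle(resid_true, t(short))  # orthogonalize
  long <- 0.7 * short[1, ] - 0.4 * short[3, ] + resid_true
  hb_long <- make_hb(matrix(long, 1), matrix(long, 1))
  out <- short_channel_regression(hb_long, hb_short)
  expect_equal(as.numeric(out$hbo), resid_true, tolerance = 1e-8)
  # independent reference: residual of OLS on raw short channels
  oracle <- ols_resid_oracle(long, t(short))
  expect_equal(as.numeric(out$hbo), oracle, tolerance = 1e-8)
})

test_that("regression never increases residual variance and shapes persist", {
  set.seed(7)
  hb_long <- make_hb(matrix(rnorm(3 * 200), 3), matrix(rnorm(3 * 200), 3))
  hb_short <- make_hb(matrix(rnorm(2 * 200), 2), matrix(rnorm(2 * 200), 2))
  out <- short_channel_regression(hb_long, hb_short)
  expect_identical(dim(out$hbo), dim(hb_long$hbo))
  v_in <- apply(hb_long$hbo, 1, var)
  v_out <- apply(out$hbo, 1, var)
  expect_true(all(v_out <= v_in + 1e-12))
  # uncorrelated short channels leave long channels essentially unchanged
  expect_gt(min(diag(cor(t(out$hbo), t(hb_long$hbo)))), 0.95)
  zero <- make_hb(matrix(0, 2, 200), matrix(0, 2, 200))
  expect_error(short_channel_regression(hb_long, zero), "variance")
})

test_that("standardization is idempotent and flagged", {
  hb <- make_hb(matrix(rnorm(300), 3) * 5 + 2)
  s1 <- standardize_hb(hb)
  s2 <- standardize_hb(s1)
  expect_true(s1$standardized)
  expect_lt(max(abs(rowMeans(s1$hbo))), 1e-8)
  expect_equal(apply(s1$hbo, 1, sd), rep(1, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(s1$hbo, s2$hbo, tolerance = 1e-12)
})

test_that("full preprocessing recovers the latent signal and is deterministic", {
  par <- cohort_params(n_participants = 2, n_long_channels = 5,
                       n_short_channels = 2, duration_s = 90,
                       noise_sd = 0, scalp_sd = 0, cardiac_amp = 0.02,
                       measurement_noise_sd = 0,
                       signal_channels_intact = 1:4,
                       signal_channels_scrambled = 1:2)
  co <- generate_cohort(par, seed = 3)
  rec <- co$recordings[[1]][["Intact"]]
  out <- run_preprocessing(rec)
  expect_true(out$standardized)
  expect_lt(max(abs(rowMeans(out$hbo))), 1e-8)
  truth <- standardize_hb(bandpass_filter(truth_hb(co, 1, "Intact"),
                                          0.005, 0.20))
  cors <- nirsisc:::row_cor(out$hbo[1:4, ], truth$hbo[1:4, ])
  expect_true(all(cors > 0.99))
  out2 <- run_preprocessing(rec)
  expect_identical(out$hbo, out2$hbo)
})

test_that("participants without good short channels are signalled for exclusion", {
  par <- cohort_params(n_participants = 1, n_long_channels = 3,
                       n_short_channels = 2, duration_s = 90,
                       cardiac_amp = 0,        # no cardiac peak anywhere
                       signal_channels_intact = 1:2,
                       signal_channels_scrambled = 1)
  co <- generate_cohort(par, seed = 6)
  expect_error(run_preprocessing(co$recordings[[1]][["Intact"]]),
               class = "nirsisc_exclusion")
})
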
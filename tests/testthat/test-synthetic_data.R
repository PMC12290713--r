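test_that("same params and seed give bit-identical cohorts", {
  par <- cohort_params(n_participants = 3, n_long_channels = 4,
                       n_short_channels = 2, duration_s = 40,
                       signal_channels_intact = 1:2,
                       signal_channels_scrambled = 1)
  a <- generate_cohort(par, seed = 11)
  b <- generate_cohort(par, seed = 11)
  expect_identical(a$recordings[[2]][["Intact"]]$intensity,
                   b$recordings[[2]][["Intact"]]$intensity)
  expect_identical(a$truth$latent, b$truth$latent)
  c_ <- generate_cohort(par, seed = 12)
  expect_false(identical(a$recordings[[2]][["Intact"]]$intensity,
                         c_$recordings[[2]][["Intact"]]$intensity))
})

test_that("generated intensities are strictly positive", {
  par <- cohort_params(n_participants = 2, n_long_channels = 4,
                       n_short_channels = 2, duration_s = 40,
                       signal_channels_intact = 1:2,
                       signal_channels_scrambled = 1,
                       shared_signal_sd = 3, noise_sd = 4, cardiac_amp = 0.1)
  co <- generate_cohort(par, seed = 3)
  for (p in seq_along(co$recordings))
    for (cond in names(co$recordings[[p]]))
      expect_true(all(co$recordings[[p]][[cond]]$intensity > 0))
})

test_that("cohort with no shared signal has ISC centered at zero", {
  zs <- replicate(10, {
    par <- cohort_params(n_participants = 6, n_long_channels = 8,
                         n_short_channels = 2, duration_s = 60,
                         shared_signal_sd = 0, scalp_sd = 0,
                         signal_channels_intact = 1:3,
                         signal_channels_scrambled = 1)
    co <- generate_cohort(par, seed = sample.int(1e6, 1))
    mean(loo_isc(cohort_hb(co, "Intact")))
  })
  expect_lt(abs(mean(zs)), 0.03)
})

test_that("doubling the shared-signal sd strictly increases signal-channel ISC", {
  mean_isc <- function(ssd, seed) {
    par <- cohort_params(n_participants = 8, n_long_channels = 8,
                         n_short_channels = 2, duration_s = 120,
                         shared_signal_sd = ssd,
                         signal_channels_intact = 1:4,
                         signal_channels_scrambled = 1:2)
    co <- generate_cohort(par, seed = seed)
    mean(loo_isc(cohort_hb(co, "Intact"))[, 1:4])
  }
  base <- mean(vapply(1:4, function(s) mean_isc(1, s), numeric(1)))
  dbl <- mean(vapply(1:4, function(s) mean_isc(2, s + 100), numeric(1)))
  expect_gt(dbl, base)
})

test_that("default scales place signal-channel ISC near 0.3", {
  par <- cohort_params(n_participants = 10, n_long_channels = 20,
                       n_short_channels = 4,
                       signal_channels_intact = 1:5,
                       signal_channels_scrambled = 1:2)
  co <- generate_cohort(par, seed = 21)
  z <- loo_isc(cohort_hb(co, "Intact"))
  expect_gt(mean(z[, 1:5]), 0.2)
  expect_lt(mean(z[, 1:5]), 0.45)
})

test_that("HbO and HbR are anticorrelated on signal channels as noise vanishes", {
  par <- cohort_params(n_participants = 2, n_long_channels = 4,
                       n_short_channels = 2, duration_s = 60,
                       noise_sd = 0.01, scalp_sd = 0,
                       signal_channels_intact = 1:4,
                       signal_channels_scrambled = 1:2)
  co <- generate_cohort(par, seed = 8)
  h <- co$hb[[1]][["Intact"]]
  cors <- vapply(1:4, function(ch) cor(h$hbo[ch, ], h$hbr[ch, ]), numeric(1))
  expect_true(all(cors < -0.9))
})

test_that("forward model inverts exactly through the preprocessing equations", {
  par <- cohort_params(n_participants = 2, n_long_channels = 4,
                       n_short_channels = 2, duration_s = 60,
                       noise_sd = 0, scalp_sd = 0, cardiac_amp = 0,
                       measurement_noise_sd = 0,
                       signal_channels_intact = 1:3,
                       signal_channels_scrambled = 1:2)
  co <- generate_cohort(par, seed = 5)
  rec <- co$recordings[[1]][["Intact"]]
  od <- intensity_to_od(rec)
  dpf <- compute_dpf(rec$age, attr(rec$montage, "wavelengths"))
  hb <- od_to_hemoglobin(od, rec$montage, extinction_table(), dpf)
  truth <- co$hb[[1]][["Intact"]]
  cent <- function(m) m - rowMeans(m)
  err <- max(abs(cent(hb$hbo[1:3, ]) - cent(truth$hbo[1:3, ]))) /
    max(abs(cent(truth$hbo[1:3, ])))
  expect_lt(err, 1e-6)
})

test_that("motion artifact injection matches its Poisson rate and leaves rate-0 input untouched", {
  par <- cohort_params(n_participants = 1, n_long_channels = 3,
                       n_short_channels = 1, duration_s = 120,
                       signal_channels_intact = 1:2,
                       signal_channels_scrambled = 1)
  co <- generate_cohort(par, seed = 2)
  rec <- co$recordings[[1]][["Intact"]]
  expect_identical(inject_motion_artifacts(rec, 0), rec)
  counts <- vapply(1:50, function(s) {
    out <- inject_motion_artifacts(rec, rate = 3, seed = s)
    length(out$provenance$artifacts$times %||% integer(0))
  }, numeric(1))
  lambda <- 3 * 120 / 60
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 50))
})

test_that("injected spikes exceed their nominal amplitude above baseline", {
  par <- cohort_params(n_participants = 1, n_long_channels = 2,
                       n_short_channels = 1, duration_s = 120,
                       signal_channels_intact = 1,
                       signal_channels_scrambled = 1)
  co <- generate_cohort(par, seed = 2)
  rec <- co$recordings[[1]][["Intact"]]
  out <- inject_motion_artifacts(rec, rate = 2, amplitude = 10, seed = 4)
  arts <- out$provenance$artifacts
  spikes <- arts$times[arts$types == "spike"]
  skip_if(length(spikes) == 0, "no spike drawn for this seed")
  od_before <- -log(rec$intensity[1, 1, ])
  od_after <- -log(out$intensity[1, 1, ])
  excess <- abs(od_after - od_before)[spikes]
  expect_true(all(excess > 5 * sd(od_before)))
})

test_that("suspense ratings stay in range and track the latent signal", {
  par <- cohort_params(n_participants = 2, n_long_channels = 3,
                       n_short_channels = 1, duration_s = 200,
                       signal_channels_intact = 1:2,
                       signal_channels_scrambled = 1)
  co <- generate_cohort(par, seed = 13)
  # target_corr = 1: exact monotone affine transform of the sampled latent
  r1 <- generate_suspense_ratings(co$truth, "Intact", target_corr = 1,
                                  seed = 1)
  s <- co$truth$latent[["Intact"]]
  per <- round(2 * co$truth$fs)
  sbin <- vapply(seq_along(r1$values), function(k)
    mean(s[((k - 1) * per + 1):(k * per)]), numeric(1))
  expect_gt(cor(r1$values, sbin), 1 - 1e-10)
  expect_true(all(r1$values >= 1 & r1$values <= 10))
  expect_true(all(diff(r1$times) > 0))
  # realized correlation near target across seeds
  rs <- vapply(1:20, function(sd_) {
    r <- generate_suspense_ratings(co$truth, "Intact", target_corr = 0.6,
                                   seed = sd_)
    cor(r$values, sbin)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.1)
  expect_error(generate_suspense_ratings(co$truth, "Intact", 1.5), "target")
  expect_error(generate_suspense_ratings(co$truth, "nope"), "condition")
})
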
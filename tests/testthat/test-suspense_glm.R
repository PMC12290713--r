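make_ratings <- function(values, interval = 2) {
  structure(list(times = seq_along(values) * interval, values = values,
                 interval_s = interval), class = "suspense_ratings")
}

test_that("resampling to the rating grid has the right length and averages", {
  fs <- 3.9063
  nT <- round(478 * fs)                       # a ~478 s recording
  ratings <- make_ratings(rep(5, 239))
  hb <- make_hb(matrix(rnorm(2 * nT), 2), fs = fs)
  rs <- resample_to_ratings(hb, ratings)
  expect_identical(ncol(rs$hbo), 239L)
  const <- make_hb(matrix(3.5, 1, nT), fs = fs)
  rc <- resample_to_ratings(const, ratings)
  expect_true(all(rc$hbo == 3.5))
  long_ratings <- make_ratings(rep(5, 400))
  expect_error(resample_to_ratings(hb, long_ratings), "beyond")
})

test_that("interval averaging tracks slow signals like point sampling", {
  fs <- 3.9063
  nT <- round(400 * fs)
  t <- (seq_len(nT) - 1) / fs
  slow <- sin(2 * pi * 0.05 * t)
  hb <- make_hb(matrix(slow, 1), fs = fs)
  ratings <- make_ratings(rep(5, 199))
  avg <- resample_to_ratings(hb, ratings)
  pts <- resample_to_ratings(hb, ratings, method = "decimate")
  expect_gt(cor(avg$hbo[1, ], pts$hbo[1, ]), 0.99)
})

test_that("a known suspense effect is recovered and flagged", {
  set.seed(31)
  nK <- 150; nch <- 6
  s <- as.numeric(scale(cumsum(rnorm(nK))))     # smooth-ish ratings signal
  ratings <- make_ratings(1 + 9 * (s - min(s)) / diff(range(s)))
  sz <- as.numeric(scale(ratings$values))
  nuis <- matrix(rnorm(nch * nK), nch)
  beta <- 1
  yi <- matrix(NA_real_, nch, nK)
  for (ch in 1:nch)
    yi[ch, ] <- beta * sz + as.numeric(scale(nuis[ch, ])) + rnorm(nK, 0, 0.5)
  mk_rs <- function(hbo, hbr) {
    ch <- sprintf("S%03d-D%03d", 1:nch, 1:nch)
    rownames(hbo) <- rownames(hbr) <- ch
    structure(list(hbo = hbo, hbr = hbr, times = ratings$times,
                   channels = ch), class = "resampled_hb")
  }
  res <- suspense_glm(mk_rs(yi, -yi), mk_rs(nuis, -nuis), ratings)
  hbo_rows <- res[res$chromophore == "HbO", ]
  expect_equal(hbo_rows$beta, rep(beta, nch), tolerance = 0.1)
  expect_true(all(hbo_rows$significant))
  expect_equal(unique(res$dof), nK - 3)          # samples minus regressors
  # HbR effect mirrors HbO with opposite sign
  hbr_rows <- res[res$chromophore == "HbR", ]
  expect_true(all(hbr_rows$t < 0))
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("suspense orthogonal to the series stays at the nominal type-I rate", {
  set.seed(32)
  hits <- 0; total <- 0
  for (r in 1:10) {
    nK <- 120; nch <- 10
    ratings <- make_ratings(runif(nK, 1, 10))
    nuis <- matrix(rnorm(nch * nK), nch)
    yi <- matrix(rnorm(nch * nK), nch) + nuis
    ch <- sprintf("S%03d-D%03d", 1:nch, 1:nch)
    rownames(yi) <- rownames(nuis) <- ch
    rs_i <- structure(list(hbo = yi, hbr = -yi, times = ratings$times,
                           channels = ch), class = "resampled_hb")
    rs_s <- structure(list(hbo = nuis, hbr = -nuis, times = ratings$times,
                           channels = ch), class = "resampled_hb")
    res <- suspense_glm(rs_i, rs_s, ratings)
    # HbR rows mirror HbO exactly here (hbr = -hbo): count one chromophore
    keep <- res$chromophore == "HbO" & !is.na(res$p)
    hits <- hits + sum(res$p[keep] < 0.05)
    total <- total + sum(keep)
  }
  rate <- hits / total
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("generator-driven suspense GLM finds opposite-signed chromophore betas", {
  par <- cohort_params(n_participants = 6, n_long_channels = 6,
                       n_short_channels = 2, duration_s = 240,
                       noise_sd = 0.8, scalp_sd = 0.2,
                       signal_channels_intact = 1:4,
                       signal_channels_scrambled = 1:2)
  co <- generate_cohort(par, seed = 17)
  ratings <- generate_suspense_ratings(co$truth, "Intact", target_corr = 0.95,
                                       seed = 2)
  gi <- resample_to_ratings(group_average_hb(cohort_hb(co, "Intact",
                                                       standardize = FALSE)),
                            ratings)
  gs <- resample_to_ratings(group_average_hb(cohort_hb(co, "Scrambled",
                                                       standardize = FALSE)),
                            ratings)
  res <- suspense_glm(gi, gs, ratings)
  sig_ch <- co$truth$montage$channel_id[3:4]    # intact-only signal channels
  hbo_t <- res$t[res$chromophore == "HbO" & res$channel %in% sig_ch]
  hbr_t <- res$t[res$chromophore == "HbR" & res$channel %in% sig_ch]
  expect_true(all(hbo_t > 0))
  expect_true(all(sign(hbr_t) == -sign(hbo_t)))
})
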
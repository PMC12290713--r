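#' Synthetic cohort parameters
#'
#' Parameters of the synthetic fNIRS cohort generator. The generator
#' emulates the statistical structure a narrative-stimulus ISC analysis
#' assumes: a band-limited latent "narrative" signal shared across
#' participants in a subset of long channels during Intact conditions (a
#' smaller, independent one for Scrambled conditions), a participant-specific
#' scalp-physiology component common to short and long channels,
#' anticorrelated HbR, participant noise, a ~1 Hz cardiac oscillation in the
#' raw intensities (stronger on short channels), and multiplicative
#' measurement noise.
#'
#' Defaults mirror a typical adult continuous-wave acquisition: 26
#' participants, 121 long + 8 short channels, 3.9063 Hz sampling, ~302 s per
#' condition, ages drawn from N(23.3, 3.1) clipped to 19-31. Signal and
#' noise scales (\code{shared_signal_sd = 1}, \code{noise_sd = 2},
#' \code{scalp_sd = 0.5}, \code{hbr_ratio = -0.8}, in uM) put
#' chromophore-averaged ISC in signal channels near 0.3.
#'
#' @param n_participants,n_long_channels,n_short_channels cohort shape.
#' @param fs sampling rate, Hz.
#' @param duration_s recording length per condition, seconds.
#' @param signal_channels_intact indices (into the long channels) carrying
#'   the shared signal in Intact conditions.
#' @param signal_channels_scrambled subset of the Intact set carrying an
#'   independent shared signal in Scrambled conditions (focal synchrony).
#' @param shared_signal_sd,noise_sd,scalp_sd component scales in uM.
#' @param hbr_ratio negative scaling of the HbR shared+scalp part relative
#'   to HbO; must lie in [-1, 0).
#' @param cardiac_amp relative amplitude of the cardiac intensity
#'   oscillation on long channels (x4 on short channels).
#' @param cardiac_freq_hz cardiac frequency (Hz).
#' @param measurement_noise_sd multiplicative intensity noise sd.
#' @param motion_rate motion artifacts per minute injected into the raw
#'   intensities (0 = clean; artifacts can also be added later with
#'   \code{\link{inject_motion_artifacts}}).
#' @param ages optional numeric vector of ages (drawn if NULL).
#' @param wavelengths device wavelengths, nm.
#' @param conditions condition labels.
#' @param stimulus stimulus name.
#' @return list of class \code{cohort_params}.
#' @export
cohort_params <- function(n_participants = 26,
                          n_long_channels = 121, n_short_channels = 8,
                          fs = 3.9063, duration_s = 302,
                          signal_channels_intact = 1:24,
                          signal_channels_scrambled = 1:8,
                          shared_signal_sd = 1, noise_sd = 2,
                          scalp_sd = 0.5, hbr_ratio = -0.8,
                          cardiac_amp = 0.02, cardiac_freq_hz = 1.1,
                          measurement_noise_sd = 0.005,
                          motion_rate = 0, ages = NULL,
                          wavelengths = c(760, 850),
                          conditions = c("Intact", "Scrambled"),
                          stimulus = "synthetic") {
  if (hbr_ratio >= 0 || hbr_ratio < -1)
    abort_nirsisc("hbr_ratio must lie in [-1, 0)", "nirsisc_parameter")
  if (any(c(shared_signal_sd, noise_sd, scalp_sd) < 0))
    abort_nirsisc("component sds must be >= 0", "nirsisc_parameter")
  if (round(duration_s * fs) < 64)
    abort_nirsisc("duration * fs must be >= 64 samples", "nirsisc_parameter")
  if (!all(signal_channels_scrambled %in% signal_channels_intact))
    abort_nirsisc("scrambled signal set must be a subset of the intact set",
                  "nirsisc_parameter")
  if (max(signal_channels_intact) > n_long_channels ||
      min(signal_channels_intact) < 1)
    abort_nirsisc("signal channel indices outside the long-channel range",
                  "nirsisc_validation")
  structure(as.list(environment()), class = "cohort_params")
}

# Band-limited Gaussian process: white noise pushed through the same
# zero-phase Butterworth design used by the preprocessing band-pass, scaled
# to unit sd. Guarantees the latent signal survives the analysis filter.
bandlimited_noise <- function(n, fs, low = 0.005, high = 0.20, order = 3) {
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Generate a synthetic fNIRS cohort
#'
#' Draws one latent shared signal per condition (band-limited to the
#' analysis band), builds per-participant hemoglobin series
#' \eqn{\Delta HbO_i = w_i s(t) 1[i \in signal set] + scalp(t) + noise},
#' \eqn{\Delta HbR = hbr\_ratio (w_i s + scalp) + noise}, and forward-models
#' raw light intensities per wavelength via
#' \eqn{I = I_0 \exp(-(\epsilon_{HbO}\Delta HbO + \epsilon_{HbR}\Delta HbR)
#' \cdot DPF \cdot \rho)} with a cardiac sinusoid and multiplicative
#' measurement noise. Short channels carry the scalp component (and
#' attenuated noise) but never the shared signal.
#'
#' @param params a \code{\link{cohort_params}}.
#' @param seed integer seed; the same params + seed give a bit-identical
#'   cohort.
#' @return list of class \code{synthetic_cohort} with elements
#'   \code{recordings[[participant]][[condition]]} (raw recordings),
#'   \code{hb[[participant]][[condition]]} (realized noisy hemoglobin
#'   series, uM, all channels) and \code{truth} (latent signals, mixing
#'   weights, ages, scales — enough to reconstruct the noiseless series).
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  p <- params
  nT <- round(p$duration_s * p$fs)
  montage <- default_montage(p$n_long_channels, p$n_short_channels,
                             p$wavelengths)
  ext <- extinction_for(p$wavelengths)
  long_ids <- long_channels(montage)
  short_ids <- short_channels(montage)
  with_seed(seed, {
    ages <- p$ages %||% pmin(pmax(stats::rnorm(p$n_participants, 23.3, 3.1),
                                  19), 31)
    if (length(ages) != p$n_participants)
      abort_nirsisc("ages must have one entry per participant",
                    "nirsisc_validation")
    weights <- stats::runif(p$n_long_channels, 0.5, 1.5)
    names(weights) <- long_ids
    latent <- lapply(stats::setNames(p$conditions, p$conditions), function(cond)
      p$shared_signal_sd * bandlimited_noise(nT, p$fs))
    sigset <- list(Intact = p$signal_channels_intact,
                   Scrambled = p$signal_channels_scrambled)
    tvec <- (seq_len(nT) - 1) / p$fs
    recordings <- vector("list", p$n_participants)
    hb <- vector("list", p$n_participants)
    for (pp in seq_len(p$n_participants)) {
      pid <- sprintf("P%02d", pp)
      rec_p <- list(); hb_p <- list()
      phase <- stats::runif(1, 0, 2 * pi)
      for (cond in p$conditions) {
        s <- latent[[cond]]
        idx <- sigset[[cond]]
        scalp <- p$scalp_sd * bandlimited_noise(nT, p$fs)
        nlong <- p$n_long_channels
        neural <- matrix(0, nlong, nT)
        neural[idx, ] <- outer(weights[idx], s)
        hbo_l <- neural + matrix(rep(scalp, nlong), nlong, byrow = TRUE) +
          matrix(stats::rnorm(nlong * nT, 0, p$noise_sd), nlong)
        hbr_l <- p$hbr_ratio *
          (neural + matrix(rep(scalp, nlong), nlong, byrow = TRUE)) +
          matrix(stats::rnorm(nlong * nT, 0, p$noise_sd), nlong)
        nsh <- p$n_short_channels
        if (nsh > 0) {
          hbo_s <- matrix(rep(scalp, nsh), nsh, byrow = TRUE) +
            matrix(stats::rnorm(nsh * nT, 0, 0.5 * p$noise_sd), nsh)
          hbr_s <- p$hbr_ratio * matrix(rep(scalp, nsh), nsh, byrow = TRUE) +
            matrix(stats::rnorm(nsh * nT, 0, 0.5 * p$noise_sd), nsh)
        } else hbo_s <- hbr_s <- matrix(0, 0, nT)
        hbo <- rbind(hbo_l, hbo_s); hbr <- rbind(hbr_l, hbr_s)
        rownames(hbo) <- rownames(hbr) <- montage$channel_id
        hb_p[[cond]] <- hb_series(hbo, hbr, p$fs, montage$channel_id,
                                  provenance = list(origin = "synthetic"))
        # forward model to raw intensities
        dpf <- compute_dpf(ages[pp], p$wavelengths)
        intens <- array(NA_real_,
                        c(nrow(montage), length(p$wavelengths), nT))
        card_amp <- p$cardiac_amp * ifelse(montage$is_short, 4, 1)
        cardiac <- sin(2 * pi * p$cardiac_freq_hz * tvec + phase)
        for (w in seq_along(p$wavelengths)) {
          x <- (ext$eps_hbo[w] * hbo + ext$eps_hbr[w] * hbr) * 1e-6 *
            dpf[w] * montage$rho
          fac <- 1 + card_amp * matrix(rep(cardiac, nrow(montage)),
                                       nrow(montage), byrow = TRUE)
          if (p$measurement_noise_sd > 0)
            fac <- fac * (1 + matrix(stats::rnorm(length(x), 0,
                                                  p$measurement_noise_sd),
                                     nrow(x)))
          intens[, w, ] <- exp(-x) * pmax(fac, 0.05)
        }
        rec <- raw_recording(pid, ages[pp], cond, p$stimulus, p$fs,
                             intens, montage,
                             provenance = list(origin = "synthetic"))
        if (p$motion_rate > 0)
          rec <- inject_motion_artifacts(rec, p$motion_rate,
                                         seed = derive_seed(seed, pp * 97L))
        rec_p[[cond]] <- rec
      }
      recordings[[pp]] <- rec_p
      hb[[pp]] <- hb_p
    }
    names(recordings) <- names(hb) <- sprintf("P%02d", seq_len(p$n_participants))
    structure(list(recordings = recordings, hb = hb,
                   truth = list(latent = latent, weights = weights,
                                signal_channels = sigset, ages = ages,
                                fs = p$fs, n_samples = nT,
                                montage = montage, params = p, seed = seed)),
              class = "synthetic_cohort")
  })
}

#' Extract one condition's hemoglobin series from a cohort
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param condition condition label.
#' @param channels \code{"long"}, \code{"short"} or \code{"all"}.
#' @param standardize standardize each channel (as the preprocessing chain
#'   would) before returning.
#' @return list of \code{hb_series}, one per participant.
#' @export
cohort_hb <- function(cohort, condition = "Intact", channels = "long",
                      standardize = TRUE) {
  mont <- cohort$truth$montage
  keep <- switch(channels,
                 long = long_channels(mont),
                 short = short_channels(mont),
                 all = mont$channel_id)
  lapply(cohort$hb, function(hp) {
    h <- hp[[condition]]
    out <- hb_series(h$hbo[keep, , drop = FALSE],
                     h$hbr[keep, , drop = FALSE], h$fs, keep,
                     provenance = h$provenance)
    if (standardize) standardize_hb(out) else out
  })
}

#' Noiseless ground-truth hemoglobin series for one participant
#'
#' Reconstructs the neural component only (\eqn{w_i s(t)} on the condition's
#' signal channels) from the stored truth record.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param participant participant index.
#' @param condition condition label.
#' @return an \code{hb_series} over the long channels.
#' @export
truth_hb <- function(cohort, participant, condition = "Intact") {
  tr <- cohort$truth
  long_ids <- long_channels(tr$montage)
  s <- tr$latent[[condition]]
  idx <- tr$signal_channels[[condition]]
  hbo <- matrix(0, length(long_ids), tr$n_samples,
                dimnames = list(long_ids, NULL))
  hbo[idx, ] <- outer(tr$weights[idx], s)
  hbr <- tr$params$hbr_ratio * hbo
  hb_series(hbo, hbr, tr$fs, long_ids,
            provenance = list(origin = "truth"))
}

#' Inject motion artifacts into a raw recording
#'
#' Adds spike (single-sample excursion) and baseline-shift artifacts at
#' Poisson-drawn times, expressed in optical-density units and applied
#' multiplicatively to the stored intensities (an OD excursion of size d
#' multiplies intensity by exp(-d)). Artifacts hit all channels at the same
#' instant, as head motion does. Positions and types are appended to the
#' recording's provenance.
#'
#' @param recording a \code{\link{raw_recording}}.
#' @param rate artifacts per minute (>= 0).
#' @param amplitude spike size as a multiple of each channel's OD standard
#'   deviation; baseline shifts use half this.
#' @param seed integer seed.
#' @return modified \code{raw_recording}.
#' @export
inject_motion_artifacts <- function(recording, rate, amplitude = 10,
                                    seed = 1L) {
  if (rate < 0) abort_nirsisc("rate must be >= 0", "nirsisc_parameter")
  if (rate == 0) return(recording)
  nT <- dim(recording$intensity)[3]
  dur_min <- nT / recording$fs / 60
  with_seed(seed, {
    n_art <- stats::rpois(1, rate * dur_min)
    if (n_art == 0) {
      recording
    } else {
      times <- sort(sample.int(nT, min(n_art, nT)))
      types <- sample(c("spike", "shift"), length(times), replace = TRUE)
      intens <- recording$intensity
      for (w in seq_len(dim(intens)[2])) {
        od_sd <- apply(log(intens[, w, , drop = FALSE]), 1, stats::sd)
        for (k in seq_along(times)) {
          t0 <- times[k]
          if (types[k] == "spike") {
            intens[, w, t0] <- intens[, w, t0] * exp(-amplitude * od_sd)
          } else {
            span <- t0:nT
            intens[, w, span] <- intens[, w, span] *
              exp(-(amplitude / 2) * od_sd)
          }
        }
      }
      rec <- recording
      rec$intensity <- intens
      rec$provenance <- c(rec$provenance,
                          list(artifacts = list(times = times, types = types,
                                                amplitude = amplitude)))
      rec
    }
  })
}

#' Generate synthetic suspense ratings
#'
#' Produces continuous suspense ratings on a 1-10 scale sampled every 2 s,
#' correlated with the condition's latent shared signal: the latent signal
#' is interval-averaged to the rating grid, mixed with Gaussian noise to a
#' target correlation, then affinely mapped into [1, 10].
#'
#' @param truth the \code{truth} element of a \code{synthetic_cohort}.
#' @param condition condition label.
#' @param target_corr desired correlation with the sampled latent signal
#'   (|target_corr| <= 1).
#' @param seed integer seed.
#' @param interval_s rating interval, seconds.
#' @return list of class \code{suspense_ratings} with \code{times} (s) and
#'   \code{values} in [1, 10].
#' @export
generate_suspense_ratings <- function(truth, condition = "Intact",
                                      target_corr = 0.7, seed = 1L,
                                      interval_s = 2) {
  if (abs(target_corr) > 1)
    abort_nirsisc("|target_corr| must be <= 1", "nirsisc_parameter")
  if (!condition %in% names(truth$latent))
    abort_nirsisc("condition not present in truth", "nirsisc_validation")
  s <- truth$latent[[condition]]
  per <- round(interval_s * truth$fs)
  nbin <- floor(length(s) / per)
  sbin <- vapply(seq_len(nbin),
                 function(k) mean(s[((k - 1) * per + 1):(k * per)]),
                 numeric(1))
  sz <- as.numeric(scale(sbin))
  with_seed(seed, {
    eps <- stats::rnorm(nbin)
    y <- target_corr * sz + sqrt(1 - target_corr^2) * as.numeric(scale(eps))
    rng <- range(y)
    values <- if (diff(rng) == 0) rep(5.5, nbin) else
      1 + 9 * (y - rng[1]) / diff(rng)
    structure(list(times = seq_len(nbin) * interval_s, values = values,
                   interval_s = interval_s),
              class = "suspense_ratings")
  })
}
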
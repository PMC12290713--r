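#' Convert light intensity to optical density change
#'
#' \eqn{\Delta OD(t) = -\ln(I(t) / \bar I)} per channel and wavelength, with
#' the series mean as reference intensity (HOMER convention), zero-centered
#' so each series has exactly zero mean.
#'
#' @param recording a \code{\link{raw_recording}} with strictly positive
#'   intensities.
#' @return an \code{od_series} with the same dimensions as the intensity.
#' @export
intensity_to_od <- function(recording) {
  intens <- recording$intensity
  d <- dim(intens)
  od <- array(NA_real_, d, dimnames = dimnames(intens))
  for (w in seq_len(d[2])) {
    m <- intens[, w, , drop = TRUE]
    if (d[1] == 1L) m <- matrix(m, nrow = 1)
    v <- -log(m / rowMeans(m))
    od[, w, ] <- v - rowMeans(v)
  }
  od_series(od, recording$fs, recording$montage,
            provenance = c(recording$provenance, list("intensity_to_od")))
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert law per channel and time point:
#' \deqn{\Delta OD_\lambda / (DPF_\lambda \, \rho) =
#'   \epsilon_{HbO,\lambda}\,\Delta HbO + \epsilon_{HbR,\lambda}\,\Delta HbR}
#' by the exact 2x2 inverse for two wavelengths and the least-squares
#' pseudoinverse for more. Concentrations are returned in micromolar.
#'
#' @param od an \code{od_series}.
#' @param montage the montage (provides \code{rho} per channel).
#' @param extinction extinction table (see \code{\link{extinction_table}}).
#' @param dpf numeric vector of differential pathlength factors, one per
#'   wavelength (ascending wavelength order).
#' @return an \code{\link{hb_series}} over all montage channels.
#' @export
od_to_hemoglobin <- function(od, montage = od$montage,
                             extinction = extinction_table(), dpf) {
  wl <- attr(montage, "wavelengths")
  if (length(wl) < 2)
    abort_nirsisc("need at least 2 wavelengths", "nirsisc_validation")
  if (length(dpf) != length(wl))
    abort_nirsisc("dpf must have one entry per wavelength", "nirsisc_parameter")
  ext <- extinction_for(wl, extinction)
  E <- cbind(hbo = ext$eps_hbo, hbr = ext$eps_hbr)
  if (kappa(E, exact = TRUE) > 1e6)
    abort_nirsisc(sprintf(
      "extinction matrix ill-conditioned for wavelengths %s",
      paste(wl, collapse = "/")), "nirsisc_numerical")
  Einv <- solve(crossprod(E)) %*% t(E)      # pseudoinverse; exact for 2 wl
  nch <- nrow(montage); nT <- dim(od$od)[3]
  hbo <- matrix(NA_real_, nch, nT, dimnames = list(montage$channel_id, NULL))
  hbr <- hbo
  for (ch in seq_len(nch)) {
    y <- od$od[ch, , , drop = TRUE] / (dpf * montage$rho[ch])  # wl x time
    if (nT == 1L) y <- matrix(y, ncol = 1)
    sol <- Einv %*% y * 1e6                 # moles/l -> uM
    hbo[ch, ] <- sol[1, ]
    hbr[ch, ] <- sol[2, ]
  }
  hb_series(hbo, hbr, od$fs, montage$channel_id,
            provenance = c(od$provenance, list("od_to_hemoglobin")))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel of both chromophores. The default 0.005-0.20 Hz band isolates
#' slow stimulus-driven hemodynamics while rejecting drift, respiratory and
#' cardiac frequencies.
#'
#' @param hb an \code{\link{hb_series}}.
#' @param low,high band edges in Hz (0 < low < high < fs/2).
#' @param order Butterworth order of one pass.
#' @return filtered \code{hb_series}.
#' @export
bandpass_filter <- function(hb, low = 0.005, high = 0.20, order = 3) {
  if (low <= 0 || high <= low || high >= hb$fs / 2)
    abort_nirsisc("band must satisfy 0 < low < high < fs/2",
                  "nirsisc_parameter")
  flt <- signal::butter(order, c(low, high) / (hb$fs / 2), type = "pass")
  frow <- function(m) t(apply(m, 1, function(v) signal::filtfilt(flt, v)))
  hb_series(frow(hb$hbo), frow(hb$hbr), hb$fs, hb$channels,
            provenance = c(hb$provenance,
                           list(bandpass = c(low = low, high = high,
                                             order = order))))
}

# Welch-averaged periodogram: mean raw periodogram over k non-overlapping
# demeaned segments. Returns data.frame(freq, power).
welch_psd <- function(v, fs, segments = 8) {
  L <- floor(length(v) / segments)
  if (L < 8) { segments <- 1; L <- length(v) }
  acc <- NULL
  for (k in seq_len(segments)) {
    seg <- v[((k - 1) * L + 1):(k * L)]
    seg <- seg - mean(seg)
    p <- Mod(stats::fft(seg))^2 / L
    acc <- if (is.null(acc)) p else acc + p
  }
  p <- acc / segments
  nf <- floor(L / 2)
  data.frame(freq = (1:nf) * fs / L, power = p[2:(nf + 1)])
}

#' Assess short-channel quality via the cardiac spectral peak
#'
#' A short channel is of good quality when its raw light intensity carries a
#' visible cardiac oscillation: for every wavelength, the Welch-averaged
#' periodogram must have a local maximum inside \code{band} whose height
#' exceeds \code{prominence_mult} times the median in-band power.
#'
#' @param recording a \code{\link{raw_recording}} containing short channels.
#' @param band frequency band searched (Hz).
#' @param prominence_mult required peak-to-median power ratio.
#' @param segments Welch segments.
#' @return named logical vector over short channels (TRUE = good).
#' @export
assess_short_channel_quality <- function(recording, band = c(0.5, 2.0),
                                         prominence_mult = 3, segments = 8) {
  mont <- recording$montage
  sc <- which(mont$is_short)
  if (!length(sc))
    abort_nirsisc("recording has no short channels", "nirsisc_validation")
  wl_n <- dim(recording$intensity)[2]
  good <- vapply(sc, function(ch) {
    all(vapply(seq_len(wl_n), function(w) {
      ps <- welch_psd(recording$intensity[ch, w, ], recording$fs, segments)
      inb <- ps$freq >= band[1] & ps$freq <= band[2]
      if (sum(inb) < 3) return(FALSE)
      pw <- ps$power[inb]
      i <- which.max(pw)
      is_local_max <- (i == 1 || pw[i] > pw[i - 1]) &&
        (i == length(pw) || pw[i] > pw[i + 1])
      is_local_max && pw[i] >= prominence_mult * stats::median(pw)
    }, logical(1)))
  }, logical(1))
  stats::setNames(good, mont$channel_id[sc])
}

#' PCA-based short-channel regression
#'
#' Stacks all good-quality short-channel HbO and HbR series as variables,
#' extracts their principal components by singular value decomposition, and
#' regresses the full component set (with intercept) out of every
#' long-channel series of both chromophores by ordinary least squares. The
#' residuals retain cortical signal while shared scalp/systemic physiology
#' is removed; one common component set is used for both chromophores.
#'
#' @param hb_long \code{hb_series} over long channels.
#' @param hb_short_good \code{hb_series} over the good short channels.
#' @return residual \code{hb_series}, same shape as \code{hb_long}.
#' @export
short_channel_regression <- function(hb_long, hb_short_good) {
  X <- t(rbind(hb_short_good$hbo, hb_short_good$hbr))  # time x (2*n_short)
  if (ncol(X) < 1 || all(apply(X, 2, stats::sd) == 0))
    abort_nirsisc("short-channel set has zero variance", "nirsisc_numerical")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  design <- cbind(1, scores)
  qr_d <- qr(design)
  resid_rows <- function(m) {
    r <- t(qr.resid(qr_d, t(m)))
    rownames(r) <- rownames(m)
    r
  }
  hb_series(resid_rows(hb_long$hbo), resid_rows(hb_long$hbr),
            hb_long$fs, hb_long$channels,
            provenance = c(hb_long$provenance,
                           list(short_channel_regression =
                                  list(n_components = sum(keep)))))
}

#' Full preprocessing chain
#'
#' Applies, in order: intensity to optical density, hybrid spline/wavelet
#' motion correction, modified Beer-Lambert conversion (with per-participant
#' age-dependent DPF), zero-phase band-pass, short-channel quality
#' assessment and PCA regression, and per-channel standardization. Returns
#' the standardized long-channel hemoglobin series; provenance lists every
#' step with its parameters.
#'
#' A participant whose recording contains short channels but none of good
#' quality is signalled for exclusion via an error of class
#' \code{nirsisc_exclusion} (catch it to drop the participant). Recordings
#' without any short channels skip the regression step.
#'
#' @param recording a \code{\link{raw_recording}}.
#' @param config an \code{\link{analysis_config}}.
#' @param extinction extinction table.
#' @return standardized \code{\link{hb_series}} over long channels.
#' @export
run_preprocessing <- function(recording, config = analysis_config(),
                              extinction = extinction_table()) {
  od <- intensity_to_od(recording)
  od <- correct_motion_hybrid(
    od,
    spline_params = list(window_s = config$motion$window_s,
                         sd_thresh = config$motion$sd_thresh),
    wavelet_params = list(levels = config$motion$wavelet_levels,
                          iqr_mult = config$motion$iqr_mult))
  wl <- attr(recording$montage, "wavelengths")
  dpf <- compute_dpf(recording$age, wl)
  hb <- od_to_hemoglobin(od, recording$montage, extinction, dpf)
  hb <- bandpass_filter(hb, config$low_cut, config$high_cut,
                        config$filter_order)
  mont <- recording$montage
  li <- long_channels(mont)
  hb_long <- hb_series(hb$hbo[li, , drop = FALSE], hb$hbr[li, , drop = FALSE],
                       hb$fs, li, provenance = hb$provenance)
  if (any(mont$is_short)) {
    good <- assess_short_channel_quality(
      recording, band = config$short_quality$band,
      prominence_mult = config$short_quality$prominence_mult,
      segments = config$short_quality$segments)
    if (!any(good))
      abort_nirsisc(sprintf(
        "participant %s has no good-quality short channels",
        recording$participant_id), "nirsisc_exclusion")
    gi <- names(good)[good]
    hb_short <- hb_series(hb$hbo[gi, , drop = FALSE],
                          hb$hbr[gi, , drop = FALSE], hb$fs, gi)
    hb_long <- short_channel_regression(hb_long, hb_short)
  }
  out <- standardize_hb(hb_long)
  out$provenance <- c(out$provenance,
                      list(participant = recording$participant_id,
                           condition = recording$condition))
  out
}

#' Preprocess a whole cohort, dropping excluded participants
#'
#' Runs \code{\link{run_preprocessing}} on every recording of one condition,
#' catching participant-exclusion signals (no good short channels).
#'
#' @param cohort a \code{synthetic_cohort} or list shaped like its
#'   \code{recordings} element.
#' @param condition condition label.
#' @param config an \code{\link{analysis_config}}.
#' @return named list of \code{hb_series}; excluded participants omitted
#'   (with a message).
#' @export
preprocess_cohort <- function(cohort, condition = "Intact",
                              config = analysis_config()) {
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  out <- list()
  for (nm in names(recs)) {
    res <- tryCatch(run_preprocessing(recs[[nm]][[condition]], config),
                    nirsisc_exclusion = function(e) {
                      message(conditionMessage(e), " - excluded")
                      NULL
                    })
    if (!is.null(res)) out[[nm]] <- res
  }
  out
}
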
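#' Raw fNIRS recording
#'
#' One participant's raw light intensities for one stimulus condition:
#' a strictly positive \code{channels x wavelengths x time} array plus the
#' montage, sampling rate and participant age (needed for the DPF).
#'
#' @param participant_id identifier.
#' @param age years.
#' @param condition \code{"Intact"} or \code{"Scrambled"}.
#' @param stimulus stimulus name.
#' @param fs sampling rate in Hz.
#' @param intensity array \code{channels x wavelengths x time}, strictly
#'   positive (required for the log transform to optical density).
#' @param montage an \code{\link{fnirs_montage}}; channel order of
#'   \code{intensity} must match \code{montage$channel_id}.
#' @param provenance list of processing/generation notes.
#' @return object of class \code{raw_recording}.
#' @export
raw_recording <- function(participant_id, age, condition, stimulus, fs,
                          intensity, montage, provenance = list()) {
  if (!condition %in% c("Intact", "Scrambled"))
    abort_nirsisc("condition must be 'Intact' or 'Scrambled'",
                  "nirsisc_validation")
  if (!is.numeric(fs) || fs <= 0)
    abort_nirsisc("fs must be > 0", "nirsisc_validation")
  d <- dim(intensity)
  if (length(d) != 3L)
    abort_nirsisc("intensity must be a 3-d array (channel x wavelength x time)",
                  "nirsisc_format")
  if (d[3] < 2L)
    abort_nirsisc("need at least 2 time samples", "nirsisc_validation")
  wl <- attr(montage, "wavelengths")
  if (d[1] != nrow(montage) || d[2] != length(wl))
    abort_nirsisc("intensity dimensions do not match montage", "nirsisc_format")
  bad <- which(apply(intensity <= 0 | !is.finite(intensity), 1, any))
  if (length(bad))
    abort_nirsisc(sprintf(
      "nonpositive/nonfinite intensity in channel(s): %s",
      paste(montage$channel_id[bad], collapse = ", ")), "nirsisc_validation")
  dimnames(intensity) <- list(montage$channel_id, as.character(wl), NULL)
  structure(list(participant_id = as.character(participant_id),
                 age = as.numeric(age),
                 condition = condition, stimulus = as.character(stimulus),
                 fs = as.numeric(fs), intensity = intensity,
                 montage = montage, provenance = provenance),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<raw_recording> %s [%s/%s] %d ch x %d wl x %d samples @ %.4f Hz\n",
              x$participant_id, x$stimulus, x$condition, d[1], d[2], d[3], x$fs))
  invisible(x)
}

# Optical-density change series: same layout as the source intensity.
od_series <- function(od, fs, montage, provenance = list()) {
  structure(list(od = od, fs = fs, montage = montage,
                 provenance = provenance),
            class = "od_series")
}

#' Hemoglobin concentration-change series
#'
#' Per-channel time series of oxy- (\code{hbo}) and deoxy-hemoglobin
#' (\code{hbr}) concentration changes in micromolar, rows ordered as in the
#' montage's long channels (or all channels for intermediate objects).
#'
#' @param hbo,hbr numeric matrices \code{channels x time} of equal shape.
#' @param fs sampling rate, Hz.
#' @param channels character vector of channel ids (row names).
#' @param standardized logical; TRUE once each channel has been scaled to
#'   mean 0, sd 1.
#' @param provenance list of applied processing steps.
#' @return object of class \code{hb_series}.
#' @export
hb_series <- function(hbo, hbr, fs, channels = rownames(hbo),
                      standardized = FALSE, provenance = list()) {
  if (!identical(dim(hbo), dim(hbr)))
    abort_nirsisc("hbo and hbr must have identical shape", "nirsisc_validation")
  if (any(!is.finite(hbo)) || any(!is.finite(hbr)))
    abort_nirsisc("hemoglobin series must be finite", "nirsisc_validation")
  rownames(hbo) <- rownames(hbr) <- channels
  structure(list(hbo = hbo, hbr = hbr, fs = as.numeric(fs),
                 channels = channels, standardized = isTRUE(standardized),
                 provenance = provenance),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> %d channels x %d samples @ %.4f Hz%s\n",
              nrow(x$hbo), ncol(x$hbo), x$fs,
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Standardize hemoglobin series channel-wise
#'
#' Subtracts each channel's mean and divides by its standard deviation, for
#' both chromophores. Idempotent up to numerical precision.
#'
#' @param hb an \code{\link{hb_series}}.
#' @return standardized \code{hb_series}.
#' @export
standardize_hb <- function(hb) {
  zrow <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    s[s == 0] <- 1
    (m - mu) / s
  }
  hb_series(zrow(hb$hbo), zrow(hb$hbr), hb$fs, hb$channels,
            standardized = TRUE,
            provenance = c(hb$provenance, list("standardize")))
}
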
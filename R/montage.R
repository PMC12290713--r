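#' Build an fNIRS montage
#'
#' A montage describes the optode geometry of a probe: one row per channel
#' (source-detector pair) with its Euclidean source-detector separation
#' \code{rho} (cm) and the shared list of laser/LED wavelengths (nm).
#' Channels with \code{rho <= 1} cm are short channels, sensitive only to
#' scalp and systemic physiology; long channels (around 3 cm) interrogate
#' the cortex. Channels are ordered lexicographically by
#' (source_id, detector_id) and every downstream matrix inherits that order.
#'
#' @param channel_id character vector of unique channel identifiers.
#' @param source_id,detector_id character vectors of optode identifiers.
#' @param rho numeric vector of source-detector distances in cm (> 0).
#' @param wavelengths numeric vector of wavelengths in nm shared by all
#'   channels; stored sorted ascending.
#' @return A data frame of class \code{fnirs_montage} with columns
#'   \code{channel_id}, \code{source_id}, \code{detector_id}, \code{rho},
#'   \code{is_short}, and a \code{wavelengths} attribute.
#' @examples
#' m <- fnirs_montage(c("S1-D1", "S1-D2"), c("S1", "S1"), c("D1", "D2"),
#'                    rho = c(3, 0.8), wavelengths = c(850, 760))
#' attr(m, "wavelengths")  # ascending: 760 850
#' @export
fnirs_montage <- function(channel_id, source_id, detector_id, rho,
                          wavelengths) {
  if (anyDuplicated(channel_id))
    abort_nirsisc("channel_id values must be unique", "nirsisc_validation")
  if (any(!is.finite(rho)) || any(rho <= 0))
    abort_nirsisc("rho must be finite and > 0", "nirsisc_validation")
  if (length(wavelengths) < 1 || any(wavelengths <= 0))
    abort_nirsisc("wavelengths must be positive", "nirsisc_validation")
  m <- data.frame(channel_id = as.character(channel_id),
                  source_id = as.character(source_id),
                  detector_id = as.character(detector_id),
                  rho = as.numeric(rho),
                  stringsAsFactors = FALSE)
  m <- m[order(m$source_id, m$detector_id), , drop = FALSE]
  rownames(m) <- NULL
  m$is_short <- m$rho <= 1.0
  attr(m, "wavelengths") <- sort(unique(as.numeric(wavelengths)))
  class(m) <- c("fnirs_montage", "data.frame")
  m
}

#' Long / short channel ids of a montage
#' @param montage an \code{fnirs_montage}.
#' @return character vector of channel ids.
#' @export
long_channels <- function(montage) montage$channel_id[!montage$is_short]

#' @rdname long_channels
#' @export
short_channels <- function(montage) montage$channel_id[montage$is_short]

#' Simple synthetic probe layout
#'
#' Convenience constructor used by the cohort generator: \code{n_long}
#' channels at 3 cm and \code{n_short} at 0.8 cm, one source and detector
#' per channel, numbered with zero-padded ids so lexicographic order equals
#' numeric order.
#'
#' @param n_long,n_short channel counts.
#' @param wavelengths wavelengths in nm.
#' @return an \code{fnirs_montage}.
#' @export
default_montage <- function(n_long = 121, n_short = 8,
                            wavelengths = c(760, 850)) {
  n <- n_long + n_short
  idx <- sprintf("%03d", seq_len(n))
  fnirs_montage(channel_id = paste0("S", idx, "-D", idx),
                source_id = paste0("S", idx),
                detector_id = paste0("D", idx),
                rho = c(rep(3, n_long), rep(0.8, n_short)),
                wavelengths = wavelengths)
}

validate_montage_match <- function(a, b) {
  same <- identical(a$channel_id, b$channel_id) &&
    identical(attr(a, "wavelengths"), attr(b, "wavelengths")) &&
    isTRUE(all.equal(a$rho, b$rho))
  if (!same)
    abort_nirsisc("recordings disagree on montage or wavelength set",
                  "nirsisc_validation")
  invisible(TRUE)
}
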
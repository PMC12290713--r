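#' Hybrid spline/wavelet motion-artifact correction
#'
#' Two-stage correction applied per channel and wavelength to optical
#' density. Stage 1 (spline): artifact segments are detected where a
#' sliding-window standard deviation exceeds \code{sd_thresh} times a robust
#' channel baseline (the median windowed SD); within each detected segment a
#' smoothing-spline fit is subtracted and the segment re-anchored to the
#' level of the preceding clean data, with subsequent segments shifted to
#' remove residual baseline steps. Stage 2 (wavelet): a 4-tap Daubechies
#' decomposition per channel; detail coefficients outside
#' median +/- \code{iqr_mult} * IQR at each level are zeroed and the signal
#' reconstructed. Output dimensions equal input dimensions.
#'
#' @param od an \code{od_series}.
#' @param spline_params list with \code{window_s} (s) and \code{sd_thresh}.
#' @param wavelet_params list with \code{levels} and \code{iqr_mult}.
#' @return corrected \code{od_series}.
#' @export
correct_motion_hybrid <- function(od,
                                  spline_params = list(window_s = 1,
                                                       sd_thresh = 3),
                                  wavelet_params = list(levels = 4,
                                                        iqr_mult = 4)) {
  x <- od$od
  nT <- dim(x)[3]
  w <- max(4L, round(spline_params$window_s * od$fs))
  if (w > nT)
    abort_nirsisc("sliding window longer than the series", "nirsisc_parameter")
  for (ch in seq_len(dim(x)[1])) {
    for (wl in seq_len(dim(x)[2])) {
      v <- x[ch, wl, ]
      v <- spline_correct(v, w, spline_params$sd_thresh)
      v <- wavelet_despike(v, wavelet_params$levels, wavelet_params$iqr_mult)
      x[ch, wl, ] <- v
    }
  }
  od_series(x, od$fs, od$montage,
            provenance = c(od$provenance,
                           list(motion_correction = list(
                             spline = spline_params, wavelet = wavelet_params))))
}

# Sliding-window SD (centered, width w) for artifact detection.
moving_sd <- function(v, w) {
  n <- length(v)
  cs <- c(0, cumsum(v)); cs2 <- c(0, cumsum(v^2))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(lo + w - 1, n)
  lo <- pmax(hi - w + 1, 1)
  m <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  sqrt(pmax((s2 - s^2 / m) / (m - 1), 0))
}

spline_correct <- function(v, w, thresh) {
  n <- length(v)
  ms <- moving_sd(v, w)
  # robust channel baseline: MAD-scaled sd of the first differences. This
  # tracks the fast (sample-to-sample) variation of the channel and is
  # insensitive to slow drift, spikes and baseline steps, so clean signal
  # never trips the threshold while artifacts exceed it by construction.
  base <- stats::mad(diff(v)) / sqrt(2)
  if (base == 0) base <- stats::sd(v)
  if (base == 0) return(v)
  bad <- ms > thresh * base
  if (!any(bad)) return(v)
  # dilate the artifact mask by half a window so segment edges are covered
  half <- w %/% 2
  mask <- rep(FALSE, n)
  for (i in which(bad)) mask[max(1, i - half):min(n, i + half)] <- TRUE
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  aruns <- which(runs$values)
  aw <- max(4L, w)
  # pass 1: remove genuine baseline steps across artifact runs. The step is
  # the difference of clean medians just after vs just before the run,
  # re-anchored only when it exceeds the natural signal change over the
  # same lag (MAD of lagged differences), so spikes on sloping signal do
  # not trigger spurious shifts.
  out <- v
  for (r in aruns) {
    pre <- max(1, starts[r] - aw):(starts[r] - 1)
    post <- (ends[r] + 1):min(n, ends[r] + aw)
    if (starts[r] == 1 || ends[r] == n) next
    step <- stats::median(out[post]) - stats::median(out[pre])
    g <- ends[r] - starts[r] + aw
    lagdiff <- v[(1 + g):n] - v[1:(n - g)]
    scale <- stats::mad(lagdiff)
    if (scale > 0 && abs(step) > thresh * scale)
      out[(ends[r] + 1):n] <- out[(ends[r] + 1):n] - step
  }
  # pass 2: repair artifact-segment content on the step-corrected series:
  # short runs are bridged by linear interpolation; longer runs keep the
  # residual around a flexible smoothing-spline fit of the artifact
  # trajectory, re-connected linearly between the clean boundary levels.
  for (r in aruns) {
    seg <- starts[r]:ends[r]
    lo <- starts[r] - 1; hi <- ends[r] + 1
    lo_val <- if (lo >= 1) out[lo] else out[hi]
    hi_val <- if (hi <= n) out[hi] else out[lo]
    bridge <- seq(lo_val, hi_val, length.out = length(seg) + 2)[-c(1, length(seg) + 2)]
    if (length(seg) > 3 * w) {
      y <- out[seg]
      fit <- stats::smooth.spline(seq_along(y), y, spar = 0.3, cv = FALSE)
      out[seg] <- (y - stats::fitted(fit)) + bridge
    } else {
      out[seg] <- bridge
    }
  }
  out
}
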
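#' Leave-one-out inter-subject correlation matrix
#'
#' For every participant, channel and chromophore, computes the Pearson
#' correlation between that participant's time series and the average
#' series of all remaining participants, Fisher-transforms it (with
#' clipping at \eqn{\pm(1 - clip)}), and averages the HbO and HbR z values
#' per channel. Unequal series lengths are truncated to the common minimum
#' before averaging. Zero-variance series yield an ISC of 0 with a warning.
#'
#' @param cohort_hb list of \code{\link{hb_series}}, one per participant
#'   (same channel set and order).
#' @param condition optional condition label stored on the result.
#' @param fisher_clip clipping constant for the Fisher transform.
#' @return matrix of class \code{isc_matrix} (participants x channels) with
#'   attributes \code{condition}, \code{participants}, \code{channels}.
#' @export
loo_isc <- function(cohort_hb, condition = NULL, fisher_clip = 1e-7) {
  n <- length(cohort_hb)
  if (n < 3)
    abort_nirsisc("need at least 3 participants", "nirsisc_validation")
  nT <- min(vapply(cohort_hb, function(h) ncol(h$hbo), integer(1)))
  chans <- cohort_hb[[1]]$channels
  zsum <- NULL
  had_degenerate <- FALSE
  for (chrom in c("hbo", "hbr")) {
    mats <- lapply(cohort_hb, function(h) h[[chrom]][, seq_len(nT),
                                                     drop = FALSE])
    total <- Reduce(`+`, mats)
    z <- matrix(NA_real_, n, length(chans))
    for (p in seq_len(n)) {
      others <- (total - mats[[p]]) / (n - 1)
      r <- row_cor(mats[[p]], others)
      if (anyNA(r)) { had_degenerate <- TRUE; r[is.na(r)] <- 0 }
      z[p, ] <- fisher_z(r, fisher_clip)
    }
    zsum <- if (is.null(zsum)) z else zsum + z
  }
  if (had_degenerate)
    warning("zero-variance series encountered; ISC recorded as 0")
  vals <- zsum / 2
  dimnames(vals) <- list(names(cohort_hb) %||%
                           paste0("P", seq_len(n)), chans)
  structure(vals, class = c("isc_matrix", "matrix"),
            condition = condition,
            participants = rownames(vals), channels = chans)
}

#' Phase-scrambled surrogate of a hemoglobin series
#'
#' Per channel: Fourier-transforms the series, adds an independent uniform
#' phase to every positive frequency (DC and Nyquist untouched), mirrors the
#' rotation for conjugate symmetry, and inverse-transforms. The identical
#' phase draws are applied to HbO and HbR of a channel, preserving their
#' cross-correlation; the amplitude spectrum (hence variance and
#' autocorrelation) of every series is preserved exactly.
#'
#' @param hb an \code{\link{hb_series}} with at least 4 samples.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return phase-scrambled \code{hb_series}.
#' @export
phase_scramble <- function(hb, seed = NULL) {
  nT <- ncol(hb$hbo)
  if (nT < 4) abort_nirsisc("series too short to scramble", "nirsisc_validation")
  doit <- function() {
    nch <- nrow(hb$hbo)
    rot <- matrix(1 + 0i, nT, nch)
    h <- floor((nT - 1) / 2)
    if (h >= 1) {
      phi <- matrix(stats::runif(h * nch, 0, 2 * pi), h, nch)
      rot[2:(h + 1), ] <- exp(1i * phi)
      rot[nT:(nT - h + 1), ] <- exp(-1i * phi)
    }
    scr <- function(m) {
      sp <- stats::mvfft(t(m)) * rot
      out <- t(Re(stats::mvfft(sp, inverse = TRUE) / nT))
      rownames(out) <- rownames(m)
      out
    }
    hb_series(scr(hb$hbo), scr(hb$hbr), hb$fs, hb$channels,
              provenance = c(hb$provenance, list("phase_scramble")))
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

# Scramble every participant of a cohort independently (one RNG stream).
scramble_cohort <- function(cohort_hb) lapply(cohort_hb, phase_scramble)

#' Surrogate ISC matrices from phase-scrambled cohorts
#'
#' Each surrogate scrambles every participant independently (fresh phase
#' draws per iteration) and recomputes the leave-one-out ISC matrix.
#'
#' @param cohort_hb list of \code{hb_series} per participant.
#' @param n_surrogates number of surrogates.
#' @param seed integer seed.
#' @param fisher_clip Fisher clipping constant.
#' @return list of \code{isc_matrix}.
#' @export
isc_surrogates <- function(cohort_hb, n_surrogates = 1000, seed = 1L,
                           fisher_clip = 1e-7) {
  fc <- fast_cohort(cohort_hb)
  with_seed(seed, {
    lapply(seq_len(n_surrogates), function(b)
      isc_from_cov(cohort_cov(scramble_fast(fc)), NULL, fisher_clip))
  })
}

col_tstat <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- (colSums(m^2) - n * mu^2) / (n - 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / n)
  t <- mu / se
  t[se == 0] <- ifelse(mu[se == 0] > 0, Inf, ifelse(mu[se == 0] < 0, -Inf, 0))
  t
}

channel_stats <- function(t_obs, null_max, alpha, dof, contrast, channels) {
  p <- vapply(t_obs, function(tt) mean(null_max >= tt), numeric(1))
  out <- data.frame(channel = channels, t = t_obs, p_corrected = p,
                    significant = p < alpha, row.names = NULL)
  structure(out, class = c("channel_stats", "data.frame"),
            dof = dof, null_max = null_max, alpha = alpha,
            contrast = contrast)
}

#' Group-level significance with max-statistic correction
#'
#' A one-sample, one-tailed (positive) t statistic per channel across
#' participants; the same statistic is computed on every surrogate ISC
#' matrix and the maximum across channels recorded per surrogate. The
#' corrected p for a channel is the proportion of surrogate maxima at or
#' above its observed t — the max-statistic method, which controls the
#' family-wise error rate across channels.
#'
#' @param isc observed \code{isc_matrix}.
#' @param surrogate_iscs nonempty list of surrogate \code{isc_matrix}.
#' @param alpha significance level.
#' @return \code{channel_stats} data frame (channel, t, corrected p,
#'   significant flag) with attributes \code{dof}, \code{null_max}.
#' @export
group_significance <- function(isc, surrogate_iscs, alpha = 0.05) {
  if (nrow(isc) < 2)
    abort_nirsisc("need at least 2 participants", "nirsisc_statistical")
  if (!length(surrogate_iscs))
    abort_nirsisc("surrogate list must be nonempty", "nirsisc_validation")
  t_obs <- col_tstat(isc)
  null_max <- vapply(surrogate_iscs, function(s) max(col_tstat(s)),
                     numeric(1))
  channel_stats(t_obs, null_max, alpha, dof = nrow(isc) - 1L,
                contrast = attr(isc, "condition") %||% "condition",
                channels = colnames(isc))
}

#' Intact > Scrambled contrast with max-statistic correction
#'
#' Subtracts the Scrambled-condition ISC matrix from the Intact matrix per
#' participant and channel, then runs the identical one-tailed max-t
#' procedure on surrogate difference matrices.
#'
#' @param isc_intact,isc_scrambled observed \code{isc_matrix} objects with
#'   matching participant and channel order.
#' @param surrogate_pairs list of \code{list(intact =, scrambled =)}
#'   surrogate matrix pairs.
#' @param alpha significance level.
#' @return \code{channel_stats} for the Intact > Scrambled contrast.
#' @export
condition_contrast <- function(isc_intact, isc_scrambled, surrogate_pairs,
                               alpha = 0.05) {
  if (!identical(dim(isc_intact), dim(isc_scrambled)) ||
      !identical(colnames(isc_intact), colnames(isc_scrambled)) ||
      !identical(rownames(isc_intact), rownames(isc_scrambled)))
    abort_nirsisc("Intact and Scrambled matrices must match in order",
                  "nirsisc_validation")
  d <- unclass(isc_intact) - unclass(isc_scrambled)
  t_obs <- col_tstat(d)
  null_max <- vapply(surrogate_pairs, function(pr)
    max(col_tstat(unclass(pr$intact) - unclass(pr$scrambled))), numeric(1))
  channel_stats(t_obs, null_max, alpha, dof = nrow(d) - 1L,
                contrast = "Intact>Scrambled", channels = colnames(d))
}

#' Leave-one-out masks for reproducibility analyses
#'
#' For every left-out participant, recomputes the ISC matrices, surrogate
#' nulls, per-condition group significance and the Intact > Scrambled
#' contrast on the remaining participants only, and records the significant
#' channel sets. The left-out participant's data never enter their own
#' masks (no double dipping).
#'
#' @param cohort_hb list with elements \code{intact} and \code{scrambled},
#'   each a named list of \code{hb_series} per participant (same names).
#' @param config an \code{\link{analysis_config}} (surrogate count, alpha,
#'   seed).
#' @return list of class \code{loo_masks}: per participant a list with
#'   \code{left_out} and channel vectors \code{intact}, \code{scrambled},
#'   \code{contrast}.
#' @export
build_loo_masks <- function(cohort_hb, config = analysis_config()) {
  pts <- names(cohort_hb$intact)
  if (length(pts) < 4)
    abort_nirsisc("need at least 4 participants", "nirsisc_validation")
  if (!identical(pts, names(cohort_hb$scrambled)))
    abort_nirsisc("intact and scrambled participant sets differ",
                  "nirsisc_validation")
  B <- config$n_surrogates
  n <- length(pts)
  fc_i <- fast_cohort(cohort_hb$intact)
  fc_s <- fast_cohort(cohort_hb$scrambled)
  cc_i <- cohort_cov(fc_i)
  cc_s <- cohort_cov(fc_s)
  obs <- lapply(seq_len(n), function(p)
    list(isc_i = isc_from_cov(cc_i, p, config$fisher_clip),
         isc_s = isc_from_cov(cc_s, p, config$fisher_clip)))
  # one scrambled cohort per iteration serves every LOO dataset (each
  # dataset still sees B independent surrogates)
  null_i <- null_s <- null_c <- matrix(NA_real_, B, n)
  with_seed(derive_seed(config$seed, 131L), {
    for (b in seq_len(B)) {
      sc_i <- cohort_cov(scramble_fast(fc_i))
      sc_s <- cohort_cov(scramble_fast(fc_s))
      for (p in seq_len(n)) {
        zi <- isc_from_cov(sc_i, p, config$fisher_clip)
        zs <- isc_from_cov(sc_s, p, config$fisher_clip)
        null_i[b, p] <- max(col_tstat(zi))
        null_s[b, p] <- max(col_tstat(zs))
        null_c[b, p] <- max(col_tstat(unclass(zi) - unclass(zs)))
      }
    }
  })
  masks <- lapply(seq_len(n), function(p) {
    t_i <- col_tstat(obs[[p]]$isc_i)
    t_s <- col_tstat(obs[[p]]$isc_s)
    t_c <- col_tstat(unclass(obs[[p]]$isc_i) - unclass(obs[[p]]$isc_s))
    chans <- colnames(obs[[p]]$isc_i)
    sig <- function(t_obs, nm) chans[vapply(t_obs, function(tt)
      mean(nm >= tt), numeric(1)) < config$alpha]
    list(left_out = pts[p],
         intact = sig(t_i, null_i[, p]),
         scrambled = sig(t_s, null_s[, p]),
         contrast = sig(t_c, null_c[, p]))
  })
  names(masks) <- pts
  structure(masks, class = "loo_masks")
}
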
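#' Group-average a list of hemoglobin series
#'
#' Element-wise mean across participants, truncated to the common minimum
#' length.
#'
#' @param hb_list list of \code{\link{hb_series}}.
#' @return an \code{hb_series}.
#' @export
group_average_hb <- function(hb_list) {
  nT <- min(vapply(hb_list, function(h) ncol(h$hbo), integer(1)))
  avg <- function(field) Reduce(`+`, lapply(hb_list, function(h)
    h[[field]][, seq_len(nT), drop = FALSE])) / length(hb_list)
  hb_series(avg("hbo"), avg("hbr"), hb_list[[1]]$fs,
            hb_list[[1]]$channels,
            provenance = list(sprintf("group_average(n=%d)", length(hb_list))))
}

#' Resample hemoglobin series to the suspense-rating grid
#'
#' Reduces each channel series to one value per rating by averaging all
#' samples inside each rating interval (anti-aliasing by construction;
#' point decimation is available via \code{method = "decimate"}).
#'
#' @param hb an \code{\link{hb_series}} (typically the group average).
#' @param ratings a \code{suspense_ratings} object (fields \code{times} in
#'   seconds and \code{values}).
#' @param method \code{"average"} (default) or \code{"decimate"}.
#' @return list of class \code{resampled_hb} with matrices \code{hbo},
#'   \code{hbr} (channels x n_ratings) and the rating times.
#' @export
resample_to_ratings <- function(hb, ratings, method = c("average",
                                                        "decimate")) {
  method <- match.arg(method)
  nT <- ncol(hb$hbo)
  dur <- nT / hb$fs
  times <- ratings$times
  if (max(times) > dur + 1 / hb$fs)
    abort_nirsisc("ratings extend beyond the recording", "nirsisc_validation")
  half <- (ratings$interval_s %||% stats::median(diff(times))) / 2
  one <- function(m) {
    out <- matrix(NA_real_, nrow(m), length(times),
                  dimnames = list(rownames(m), NULL))
    for (k in seq_along(times)) {
      if (method == "average") {
        # window centered on the rating time, so averaging introduces no lag
        lo <- max(1L, floor((times[k] - half) * hb$fs) + 1L)
        hi <- min(nT, max(lo, round((times[k] + half) * hb$fs)))
        out[, k] <- rowMeans(m[, lo:hi, drop = FALSE])
      } else {
        out[, k] <- m[, min(nT, max(1L, round(times[k] * hb$fs)))]
      }
    }
    out
  }
  structure(list(hbo = one(hb$hbo), hbr = one(hb$hbr),
                 times = times, channels = hb$channels),
            class = "resampled_hb")
}

#' Suspense GLM with Scrambled-condition nuisance regressor
#'
#' Per channel and chromophore, ordinary least squares of the resampled
#' Intact group-average series on an intercept, the z-scored suspense
#' ratings and the z-scored same-channel Scrambled group-average series
#' (nuisance control for dynamics correlated with the ratings by chance).
#' The suspense beta's t statistic is tested two-sided and
#' Benjamini-Hochberg FDR is applied across all channel x chromophore
#' tests.
#'
#' @param hb_intact_group,hb_scrambled_group \code{resampled_hb} objects
#'   (see \code{\link{resample_to_ratings}}); the Scrambled series is
#'   truncated/aligned from time zero to the Intact length.
#' @param ratings a \code{suspense_ratings}.
#' @param alpha FDR level.
#' @return data frame of class \code{suspense_glm_result}: channel,
#'   chromophore, beta, t, p, q, dof, significant.
#' @export
suspense_glm <- function(hb_intact_group, hb_scrambled_group, ratings,
                         alpha = 0.05) {
  nK <- ncol(hb_intact_group$hbo)
  if (ncol(hb_scrambled_group$hbo) < nK)
    abort_nirsisc("Scrambled series shorter than the Intact rating grid",
                  "nirsisc_validation")
  s <- as.numeric(scale(ratings$values[seq_len(nK)]))
  rows <- list()
  for (chrom in c("hbo", "hbr")) {
    yi <- hb_intact_group[[chrom]]
    ns <- hb_scrambled_group[[chrom]][, seq_len(nK), drop = FALSE]
    for (ch in seq_len(nrow(yi))) {
      y <- yi[ch, ]
      nuis <- as.numeric(scale(ns[ch, ]))
      X <- cbind(intercept = 1, suspense = s, nuisance = nuis)
      dof <- nK - ncol(X)
      row <- data.frame(channel = hb_intact_group$channels[ch],
                        chromophore = c(hbo = "HbO", hbr = "HbR")[[chrom]],
                        beta = NA_real_, t = NA_real_, p = NA_real_,
                        dof = dof)
      if (kappa(X, exact = TRUE) > 1e6) {
        rows[[length(rows) + 1]] <- row
        next
      }
      fit <- stats::lm.fit(X, y)
      sigma2 <- sum(fit$residuals^2) / dof
      XtXinv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(sigma2 * XtXinv[2, 2])
      row$beta <- fit$coefficients["suspense"]
      row$t <- row$beta / se
      row$p <- 2 * stats::pt(-abs(row$t), dof)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$q) & out$q < alpha
  rownames(out) <- NULL
  structure(out, class = c("suspense_glm_result", "data.frame"),
            alpha = alpha)
}
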
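#' Normalized dot product between a participant and the group
#'
#' The single-participant consistency score
#' \deqn{\frac{1}{n}\sum_{i=1}^{n} a_i g_i}
#' over the \eqn{n} channels of a mask, where \eqn{a} is the left-out
#' participant's ISC vector and \eqn{g} the group-averaged ISC vector of
#' their leave-one-out dataset. Normalizing by the mask size makes scores
#' comparable across participants with different masks; the sign is
#' preserved so systematically inverted ISC patterns score negatively.
#'
#' @param a named ISC vector of the left-out participant.
#' @param g named group-mean ISC vector.
#' @param mask character vector of channel ids (or a mask list with a
#'   channel vector element).
#' @return scalar score.
#' @examples
#' a <- c(ch1 = 0.2, ch2 = 0.1, ch3 = -0.1)
#' g <- c(ch1 = 0.3, ch2 = 0.2, ch3 = 0.1)
#' normalized_dot_product(a, g, names(a))  # 0.02333...
#' @export
normalized_dot_product <- function(a, g, mask) {
  ch <- if (is.list(mask)) mask$contrast %||% mask$channels else mask
  if (!length(ch))
    abort_nirsisc("mask is empty", "nirsisc_validation")
  if (!all(ch %in% names(a)) || !all(ch %in% names(g)))
    abort_nirsisc("ISC vectors do not cover the mask channels",
                  "nirsisc_validation")
  mean(a[ch] * g[ch])
}

# Scores for every participant of one condition against the Intact LOO
# group mean, on the Intact>Scrambled LOO masks.
cohort_ndp_scores <- function(isc_scored, loo_group_means, masks) {
  pts <- rownames(isc_scored)
  vapply(seq_along(pts), function(p) {
    ch <- masks[[p]]$contrast
    if (!length(ch)) return(NA_real_)
    normalized_dot_product(isc_scored[p, ], loo_group_means[[p]], ch)
  }, numeric(1))
}

#' Single-participant consistency analysis
#'
#' For every participant: the normalized dot product between their Intact
#' ISC vector and the group-averaged Intact ISC vector of their
#' leave-one-out dataset, restricted to that dataset's Intact > Scrambled
#' mask. A surrogate null is built by phase-scrambling the whole cohort
#' (left-out participant included) per iteration and recomputing the score
#' with the original-data mask held fixed; the one-sided p counts null
#' scores at or above the actual one (add-one estimator). Benjamini-
#' Hochberg FDR is applied across participants. Scrambled-condition scores
#' against the same Intact references are returned for validation.
#'
#' Participants with an empty contrast mask are marked indeterminate (NA
#' scores, excluded from the FDR step).
#'
#' @param cohort_hb list with \code{intact} and \code{scrambled} named
#'   lists of \code{hb_series}.
#' @param masks \code{loo_masks} from \code{\link{build_loo_masks}}.
#' @param config an \code{\link{analysis_config}}.
#' @return data frame of class \code{consistency_result}: participant,
#'   score, score_scrambled, n_mask, p, q, significant; the null score
#'   matrix is attached as attribute \code{null_scores}.
#' @export
consistency_analysis <- function(cohort_hb, masks,
                                 config = analysis_config()) {
  pts <- names(cohort_hb$intact)
  if (!identical(pts, names(masks)))
    abort_nirsisc("masks must cover every participant", "nirsisc_validation")
  n <- length(pts)
  fc_i <- fast_cohort(cohort_hb$intact)
  cc_i <- cohort_cov(fc_i)
  isc_int <- isc_from_cov(cc_i, NULL, config$fisher_clip)
  isc_scr <- loo_isc(cohort_hb$scrambled, "Scrambled", config$fisher_clip)
  gmeans <- lapply(seq_len(n), function(p)
    colMeans(isc_from_cov(cc_i, p, config$fisher_clip)))
  score_int <- cohort_ndp_scores(isc_int, gmeans, masks)
  score_scr <- cohort_ndp_scores(isc_scr, gmeans, masks)
  B <- config$n_surrogates
  null_scores <- with_seed(derive_seed(config$seed, 547L), {
    t(vapply(seq_len(B), function(b) {
      cb <- cohort_cov(scramble_fast(fc_i))
      isc_b <- isc_from_cov(cb, NULL, config$fisher_clip)
      gm_b <- lapply(seq_len(n), function(p)
        colMeans(isc_from_cov(cb, p, config$fisher_clip)))
      cohort_ndp_scores(isc_b, gm_b, masks)
    }, numeric(n)))
  })
  p_unc <- vapply(seq_len(n), function(p) {
    if (is.na(score_int[p])) return(NA_real_)
    (1 + sum(null_scores[, p] >= score_int[p])) / (B + 1)
  }, numeric(1))
  q <- rep(NA_real_, n)
  ok <- !is.na(p_unc)
  q[ok] <- stats::p.adjust(p_unc[ok], method = "BH")
  out <- data.frame(participant = pts, score = score_int,
                    score_scrambled = score_scr,
                    n_mask = vapply(masks, function(m)
                      length(m$contrast), integer(1)),
                    p = p_unc, q = q,
                    significant = !is.na(q) & q < config$alpha,
                    row.names = NULL)
  structure(out, class = c("consistency_result", "data.frame"),
            null_scores = null_scores)
}

#' Validate consistency scores: Intact vs Scrambled
#'
#' Paired t test on the per-participant difference between Intact and
#' Scrambled normalized dot products (two-sided, df = n - 1).
#'
#' @param scores_intact,scores_scrambled equal-length per-participant score
#'   vectors.
#' @return list with \code{t}, \code{dof}, \code{p},
#'   \code{mean_intact}, \code{mean_scrambled}.
#' @export
consistency_validation <- function(scores_intact, scores_scrambled) {
  ok <- !is.na(scores_intact) & !is.na(scores_scrambled)
  x <- scores_intact[ok]; y <- scores_scrambled[ok]
  if (length(x) < 3)
    abort_nirsisc("need at least 3 paired scores", "nirsisc_statistical")
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  if (!is.finite(t)) t <- 0
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, dof = n - 1L, p = p,
       mean_intact = mean(x), mean_scrambled = mean(y))
}
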
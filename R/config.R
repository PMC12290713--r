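#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the acquisition and analysis settings the pipeline was designed around:
#' a 0.005-0.20 Hz Butterworth band-pass (order 3, applied forward-backward),
#' 1000 phase-scrambled surrogates, 1000 label permutations, alpha = 0.05.
#'
#' @param low_cut,high_cut band-pass edges in Hz.
#' @param filter_order Butterworth order (one pass; zero-phase filtering
#'   doubles the effective order).
#' @param n_surrogates number of phase-scrambled surrogates for null
#'   distributions.
#' @param n_permutations number of label permutations for decoding tests.
#' @param alpha significance level.
#' @param fisher_clip correlations are clipped to +/-(1 - fisher_clip)
#'   before atanh.
#' @param motion list of hybrid motion-correction settings: \code{window_s}
#'   sliding-window length (s), \code{sd_thresh} threshold on the windowed
#'   SD as a multiple of its robust channel baseline, \code{wavelet_levels}
#'   decomposition depth, \code{iqr_mult} IQR multiple for coefficient
#'   rejection. The windowed SD is compared against the MAD-scaled SD of
#'   the whole channel, and the wavelet IQR multiple (default 4) is set so
#'   an artifact-free Gaussian-process signal passes through essentially
#'   unchanged while spikes and baseline shifts remain far outside both
#'   rejection envelopes (see the methods vignette).
#' @param short_quality list: \code{band} (Hz) searched for the cardiac
#'   peak, \code{prominence_mult} required peak height as a multiple of the
#'   median in-band power, \code{segments} Welch segments.
#' @param classifiers character vector of registry names used by the
#'   decoder (NULL = full registry).
#' @param search_budget hyperparameter evaluations per classifier.
#' @param permutation_budget search budget reused during permutation runs
#'   (reduced tuning is standard practice and logged in provenance).
#' @param cv_folds cross-validation folds for tuning.
#' @param seed master seed; per-stage streams are derived by fixed offsets.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(low_cut = 0.005, high_cut = 0.20,
                            filter_order = 3,
                            n_surrogates = 1000, n_permutations = 1000,
                            alpha = 0.05, fisher_clip = 1e-7,
                            motion = list(window_s = 1, sd_thresh = 3,
                                          wavelet_levels = 4, iqr_mult = 4),
                            short_quality = list(band = c(0.5, 2.0),
                                                 prominence_mult = 3,
                                                 segments = 8),
                            classifiers = NULL,
                            search_budget = 25,
                            permutation_budget = NULL,
                            cv_folds = 3,
                            seed = 1L) {
  if (n_surrogates < 1 || n_permutations < 0)
    abort_nirsisc("surrogate count must be >= 1 and permutation count >= 0",
                  "nirsisc_parameter")
  if (low_cut <= 0 || high_cut <= low_cut)
    abort_nirsisc("need 0 < low_cut < high_cut", "nirsisc_parameter")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 filter_order = filter_order,
                 n_surrogates = as.integer(n_surrogates),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, fisher_clip = fisher_clip,
                 motion = motion, short_quality = short_quality,
                 classifiers = classifiers,
                 search_budget = as.integer(search_budget),
                 permutation_budget =
                   as.integer(permutation_budget %||% search_budget),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write a configuration as YAML
#' @param path file path.
#' @param config an \code{analysis_config}.
#' @return \code{read_config} returns an \code{analysis_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
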
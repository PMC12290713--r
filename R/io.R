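#' Write / load a recording in the plain-text fixture format
#'
#' The fixture format stores one recording as two files in a directory:
#' \itemize{
#'   \item \code{<id>_meta.json} — participant id, age, condition,
#'     stimulus, sampling rate, wavelengths (ascending) and the montage
#'     table (channel_id, source_id, detector_id, rho);
#'   \item \code{<id>_intensity.csv} — one row per time sample, one column
#'     per channel-wavelength pair named \code{<channel>@<wavelength>},
#'     written with 17 significant digits so the round trip is exact to
#'     full double precision.
#' }
#'
#' @param recording a \code{\link{raw_recording}}.
#' @param dir output directory (created if needed).
#' @return (invisibly) the meta-file path.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sprintf("%s_%s_%s", recording$participant_id, recording$stimulus,
                recording$condition)
  mont <- recording$montage
  wl <- attr(mont, "wavelengths")
  meta <- list(participant_id = recording$participant_id,
               age = recording$age, condition = recording$condition,
               stimulus = recording$stimulus, fs = recording$fs,
               wavelengths = wl,
               montage = as.data.frame(mont[, c("channel_id", "source_id",
                                                "detector_id", "rho")]))
  meta_path <- file.path(dir, paste0(id, "_meta.json"))
  jsonlite::write_json(meta, meta_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  d <- dim(recording$intensity)
  cols <- as.vector(outer(mont$channel_id, wl,
                          function(a, b) paste0(a, "@", b)))
  flat <- matrix(NA_real_, d[3], d[1] * d[2])
  k <- 0
  for (w in seq_len(d[2])) for (ch in seq_len(d[1])) {
    k <- k + 1
    flat[, k] <- recording$intensity[ch, w, ]
  }
  txt <- apply(flat, 2, function(v) sprintf("%.17g", v))
  utils::write.table(rbind(cols, txt), file.path(dir, paste0(id, "_intensity.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(meta_path)
}

#' @rdname write_recording
#' @param path path to a \code{*_meta.json} fixture file.
#' @param format currently only \code{"fixture"}.
#' @return \code{load_recording} returns a \code{\link{raw_recording}}.
#' @export
load_recording <- function(path, format = "fixture") {
  format <- match.arg(format, "fixture")
  if (!file.exists(path))
    abort_nirsisc(sprintf("no such file: %s", path), "nirsisc_io")
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (req in c("fs", "wavelengths", "montage", "participant_id"))
    if (is.null(meta[[req]]))
      abort_nirsisc(sprintf("fixture lacks required field '%s'", req),
                    "nirsisc_format")
  mont <- fnirs_montage(meta$montage$channel_id, meta$montage$source_id,
                        meta$montage$detector_id, meta$montage$rho,
                        meta$wavelengths)
  csv <- sub("_meta\\.json$", "_intensity.csv", path)
  if (!file.exists(csv))
    abort_nirsisc(sprintf("missing intensity file: %s", csv), "nirsisc_io")
  tab <- utils::read.csv(csv, check.names = FALSE)
  wl <- attr(mont, "wavelengths")
  nT <- nrow(tab)
  intens <- array(NA_real_, c(nrow(mont), length(wl), nT))
  for (w in seq_along(wl)) for (ch in seq_len(nrow(mont))) {
    col <- paste0(mont$channel_id[ch], "@", wl[w])
    if (!col %in% names(tab))
      abort_nirsisc(sprintf("intensity column missing: %s", col),
                    "nirsisc_format")
    intens[ch, w, ] <- tab[[col]]
  }
  raw_recording(meta$participant_id, meta$age, meta$condition,
                meta$stimulus, meta$fs, intens, mont)
}

results_tables <- function(results) {
  if (inherits(results, "isc_matrix")) {
    m <- unclass(results)
    list(type = "isc_matrix",
         tables = list(isc = data.frame(
           participant = rep(rownames(m), times = ncol(m)),
           channel = rep(colnames(m), each = nrow(m)),
           isc_z = as.vector(m))),
         extra = list(condition = attr(results, "condition")))
  } else if (inherits(results, "channel_stats")) {
    list(type = "channel_stats",
         tables = list(channel_stats = as.data.frame(results)),
         extra = list(dof = attr(results, "dof"),
                      alpha = attr(results, "alpha"),
                      contrast = attr(results, "contrast"),
                      null_max = attr(results, "null_max")))
  } else if (inherits(results, "consistency_result")) {
    list(type = "consistency_result",
         tables = list(consistency = as.data.frame(results)), extra = list())
  } else if (inherits(results, "decoding_result")) {
    conf <- as.data.frame(as.table(results$confusion))
    names(conf) <- c("actual", "predicted", "count")
    list(type = "decoding_result",
         tables = list(confusion = conf),
         extra = list(balanced_accuracy = results$balanced_accuracy,
                      recall = results$recall,
                      precision = results$precision,
                      p_balanced_accuracy = results$p_balanced_accuracy,
                      p_recall = results$p_recall,
                      p_precision = results$p_precision))
  } else if (inherits(results, "suspense_glm_result")) {
    list(type = "suspense_glm_result",
         tables = list(suspense_glm = as.data.frame(results)), extra = list())
  } else {
    abort_nirsisc("unknown results type", "nirsisc_validation")
  }
}

#' Save stage results with a reproducibility manifest
#'
#' Writes each result table as TSV (17 significant digits) plus a JSON
#' manifest recording the result type, the RNG seed and configuration used
#' (when supplied) and an MD5 hash of the configuration, so a run can be
#' reproduced bit-for-bit.
#'
#' @param results an \code{isc_matrix}, \code{channel_stats},
#'   \code{consistency_result}, \code{decoding_result} or
#'   \code{suspense_glm_result}.
#' @param path output directory.
#' @param config optional \code{\link{analysis_config}} to record.
#' @param seed optional seed to record.
#' @return (invisibly) manifest list with element \code{files}.
#' @export
save_results <- function(results, path, config = NULL, seed = NULL) {
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    abort_nirsisc(sprintf("cannot create directory: %s", path), "nirsisc_io")
  rt <- results_tables(results)
  files <- character(0)
  for (nm in names(rt$tables)) {
    f <- file.path(path, paste0(nm, ".tsv"))
    tab <- rt$tables[[nm]]
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  cfg_hash <- NULL
  if (!is.null(config)) {
    tmp <- tempfile()
    jsonlite::write_json(unclass(config), tmp, digits = NA,
                         auto_unbox = TRUE)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  manifest <- list(type = rt$type, files = basename(files),
                   seed = seed %||% (if (!is.null(config)) config$seed),
                   config = if (!is.null(config)) unclass(config),
                   config_md5 = cfg_hash,
                   extra = rt$extra)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(dir = path)))
}

#' Load results written by \code{\link{save_results}}
#'
#' Reconstructs the saved object (an \code{isc_matrix} returns as matrix;
#' tabular results return as data frames with manifest metadata attached).
#'
#' @param path directory containing \code{manifest.json}.
#' @return the reconstructed results object.
#' @export
load_results <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  tabs <- lapply(mf$files, function(f)
    utils::read.delim(file.path(path, f)))
  names(tabs) <- sub("\\.tsv$", "", mf$files)
  if (mf$type == "isc_matrix") {
    df <- tabs$isc
    pts <- unique(df$participant); chs <- unique(df$channel)
    m <- matrix(df$isc_z, length(pts), length(chs),
                dimnames = list(pts, chs))
    structure(m, class = c("isc_matrix", "matrix"),
              condition = mf$extra$condition,
              participants = pts, channels = chs)
  } else {
    out <- if (length(tabs) == 1L) tabs[[1]] else tabs
    attr(out, "manifest") <- mf
    out
  }
}

#' Write a whole synthetic cohort as fixtures
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory.
#' @return (invisibly) vector of written meta-file paths.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- character(0)
  for (pp in names(cohort$recordings))
    for (cond in names(cohort$recordings[[pp]]))
      paths <- c(paths, write_recording(cohort$recordings[[pp]][[cond]], dir))
  invisible(paths)
}
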
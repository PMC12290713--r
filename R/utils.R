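#' @keywords internal
"_PACKAGE"

# Row-wise Pearson correlation between two matrices of matched shape
# (rows = series). Zero-variance rows yield NA.
row_cor <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  num <- rowSums(ca * cb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Fisher z with clipping: r is clipped to +/- (1 - clip) before atanh so the
# transform stays finite at |r| = 1 (documented ceiling atanh(1 - 1e-7)).
fisher_z <- function(r, clip = 1e-7) {
  atanh(pmin(pmax(r, -(1 - clip)), 1 - clip))
}

# Deterministic per-stage seed streams: one master seed spawns substreams by
# fixed offsets, kept below .Machine$integer.max.
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 1103L + offset * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_nirsisc <- function(msg, class) {
  stop(structure(class = c(class, "nirsisc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
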
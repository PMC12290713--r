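# Fast internal machinery for surrogate loops.
#
# All leave-one-out ISC quantities are Pearson correlations between one
# participant's series and the (scaled) sum of other participants' series,
# so every LOO-subset ISC matrix can be assembled from the pairwise
# row-wise covariance tensor C[q, r, ch] = <centered q, centered r> in O(1)
# arithmetic per cell. One tensor therefore serves the full-cohort ISC, all
# n leave-one-subset ISCs and their group means — the workhorse for
# surrogate and permutation loops. Equivalence with the direct
# implementation (loo_isc) is property-tested.

# Compact cohort representation: per chromophore a list of ch x T matrices,
# truncated to the common length.
fast_cohort <- function(hb_list) {
  nT <- min(vapply(hb_list, function(h) ncol(h$hbo), integer(1)))
  trim <- function(m) if (ncol(m) == nT) m else m[, seq_len(nT), drop = FALSE]
  list(hbo = lapply(hb_list, function(h) trim(h$hbo)),
       hbr = lapply(hb_list, function(h) trim(h$hbr)),
       nT = nT, channels = hb_list[[1]]$channels,
       names = names(hb_list) %||% paste0("P", seq_along(hb_list)),
       fs = hb_list[[1]]$fs)
}

# Pairwise row-wise covariance tensors per chromophore:
# C (n x n x ch), U[q, ch] = sum_r C[q, r, ch], Tt[ch] = sum_qr C[q, r, ch].
cohort_cov <- function(fc) {
  out <- list()
  n <- length(fc$hbo)
  nch <- length(fc$channels)
  for (chrom in c("hbo", "hbr")) {
    cm <- lapply(fc[[chrom]], function(m) m - rowMeans(m))
    C <- array(0, c(n, n, nch))
    for (q in seq_len(n)) {
      C[q, q, ] <- rowSums(cm[[q]]^2)
      if (q < n) for (r in (q + 1):n) {
        v <- rowSums(cm[[q]] * cm[[r]])
        C[q, r, ] <- v
        C[r, q, ] <- v
      }
    }
    U <- apply(C, c(1, 3), sum)
    Tt <- colSums(U)
    out[[chrom]] <- list(C = C, U = U, Tt = Tt)
  }
  out$n <- n
  out$channels <- fc$channels
  out$names <- fc$names
  out
}

# Chromophore-averaged Fisher-z LOO ISC matrix for the cohort minus
# `exclude` (NULL = full cohort), computed from the covariance tensors.
isc_from_cov <- function(cc, exclude = NULL, clip = 1e-7) {
  keep <- setdiff(seq_len(cc$n), exclude)
  zsum <- 0
  for (chrom in c("hbo", "hbr")) {
    C <- cc[[chrom]]$C; U <- cc[[chrom]]$U; Tt <- cc[[chrom]]$Tt
    excl_u <- if (length(exclude)) U[exclude, ] else 0
    excl_cc <- if (length(exclude)) C[exclude, exclude, ] else 0
    St <- Tt - 2 * excl_u + excl_cc          # sum_{r,s in subset} C_rs
    z <- matrix(NA_real_, length(keep), length(cc$channels))
    for (i in seq_along(keep)) {
      q <- keep[i]
      cqp <- if (length(exclude)) C[q, exclude, ] else 0
      num <- U[q, ] - cqp - C[q, q, ]        # <q, sum of others in subset>
      oth <- St - 2 * (U[q, ] - cqp) + C[q, q, ]
      den <- sqrt(C[q, q, ] * pmax(oth, 0))
      r <- ifelse(den > 0, num / den, 0)
      z[i, ] <- fisher_z(r, clip)
    }
    zsum <- zsum + z
  }
  vals <- zsum / 2
  dimnames(vals) <- list(cc$names[keep], cc$channels)
  structure(vals, class = c("isc_matrix", "matrix"),
            participants = rownames(vals), channels = cc$channels)
}

# Batched phase scrambling of a fast cohort: one forward/inverse mvfft pair
# per chromophore, identical phase draws for HbO and HbR of each channel.
scramble_fast <- function(fc) {
  nT <- fc$nT
  n <- length(fc$hbo)
  nch <- length(fc$channels)
  X_hbo <- do.call(cbind, lapply(fc$hbo, t))
  X_hbr <- do.call(cbind, lapply(fc$hbr, t))
  rot <- matrix(1 + 0i, nT, n * nch)
  h <- floor((nT - 1) / 2)
  if (h >= 1) {
    phi <- matrix(stats::runif(h * n * nch, 0, 2 * pi), h, n * nch)
    rot[2:(h + 1), ] <- exp(1i * phi)
    rot[nT:(nT - h + 1), ] <- exp(-1i * phi)
  }
  scr <- function(X) Re(stats::mvfft(stats::mvfft(X) * rot,
                                     inverse = TRUE)) / nT
  Y_hbo <- scr(X_hbo); Y_hbr <- scr(X_hbr)
  out <- fc
  for (q in seq_len(n)) {
    cols <- ((q - 1) * nch + 1):(q * nch)
    m1 <- t(Y_hbo[, cols, drop = FALSE])
    m2 <- t(Y_hbr[, cols, drop = FALSE])
    rownames(m1) <- rownames(m2) <- fc$channels
    out$hbo[[q]] <- m1
    out$hbr[[q]] <- m2
  }
  out
}
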
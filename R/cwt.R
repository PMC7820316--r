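# Continuous wavelet transform (db7) and scalogram descriptors -----------

#' Default CWT scale grid
#'
#' 48 logarithmically spaced, integer-rounded dilations over `[8, 128]`
#' samples (duplicates removed).  At 1200 Hz this spans db7 pseudo-
#' frequencies of roughly 6.5-103 Hz, covering the evoked response's energy
#' band while keeping the dilated wavelet support (about `13 * a` samples)
#' commensurate with the 600-sample record.
#'
#' @param n number of requested scales.
#' @param range scale range `c(min, max)` in samples.
#' @return increasing integer vector of scales.
#' @export
cwt_default_scales <- function(n = 48, range = c(8, 128)) {
  unique(round(exp(seq(log(range[1]), log(range[2]), length.out = n))))
}

# Smallest 5-smooth FFT length >= need (falls back to the next power of
# two for very long transforms).
good_fft_length <- function(need) {
  cand <- sort(unique(as.vector(outer(2^(5:14), c(1, 9 / 8, 5 / 4, 3 / 2)))))
  ok <- cand[cand >= need]
  as.integer(if (length(ok)) ok[1] else 2^ceiling(log2(need)))
}

# Sampled kernels w_a[k] = psi(k / a) / sqrt(a), k = 0..floor(13 a), and
# the centre offset of each dilated support.  Cached per scale grid.
cwt_kernels <- function(scales) {
  if (any(scales <= 0)) stop("scales must be positive")
  key <- paste0("k_", paste(scales, collapse = "_"))
  if (!is.null(.mfvepris_cache[[key]])) return(.mfvepris_cache[[key]])
  kernels <- lapply(scales, function(a) db7_psi((0:floor(13 * a)) / a) / sqrt(a))
  centers <- as.integer(round(13 * scales / 2))
  out <- list(kernels = kernels, centers = centers)
  .mfvepris_cache[[key]] <- out
  out
}

# Per-scale transform lengths for records of n samples.  Only the n
# centre-aligned lags b - C are ever read, so L >= n + max(C, K - C)
# keeps every circular alias of a read lag outside the kernel-signal
# overlap — about half the full linear-correlation length at coarse
# scales.
cwt_fft_lengths <- function(n, kk) {
  K <- lengths(kk$kernels)
  C <- kk$centers
  mapply(function(K, C) good_fft_length(n + max(C, K - C)), K, C)
}

#' Continuous wavelet transform modulus (db7)
#'
#' Computes `|T(a, b)|` where
#' `T(a, b) = 1/sqrt(a) * sum_t x[t] psi((t - b') / a)` is the discrete
#' cross-correlation of the zero-padded waveform with the dilated,
#' tabulated db7 wavelet.  The translation axis is aligned to the centre of
#' the dilated wavelet support (the Matlab-style convention), so `b` reads
#' as the time, in ms on the record's own time base, at which the wavelet
#' is centred.
#'
#' @param x numeric waveform (one record, typically 600 samples).
#' @param scales positive dilations in samples; see [cwt_default_scales()].
#' @param fs sampling rate in Hz.
#' @param method `"fft"` (FFT-accelerated, default) or `"direct"` (plain
#'   double-loop summation; slow, used as a self-check).
#' @return object of class `cwt_result`: list with `modulus`
#'   (scales x samples matrix), `scales`, `times_ms`, `fs`.
#' @export
cwt_modulus <- function(x, scales = cwt_default_scales(), fs = 1200,
                        method = c("fft", "direct")) {
  method <- match.arg(method)
  if (any(scales <= 0)) stop("scales must be positive")
  if (!all(is.finite(x))) stop("non-finite waveform")
  n <- length(x)
  kk <- cwt_kernels(scales)
  if (method == "fft") {
    cube <- cwt_batch_cpp(matrix(x, ncol = 1), kk$kernels, kk$centers,
                          cwt_fft_lengths(n, kk))
    modulus <- matrix(cube[, seq_len(n), 1], nrow = length(scales))
  } else {
    modulus <- matrix(0, length(scales), n)
    for (s in seq_along(scales)) {
      w <- kk$kernels[[s]]
      C <- kk$centers[s]
      for (b in seq_len(n)) {
        k <- seq_along(w) - 1L
        t_idx <- (b - 1L) - C + k        # 0-based sample positions
        ok <- t_idx >= 0 & t_idx < n
        modulus[s, b] <- abs(sum(x[t_idx[ok] + 1L] * w[ok]))
      }
    }
  }
  structure(list(modulus = modulus, scales = scales,
                 times_ms = (seq_len(n) - 1) / fs * 1000, fs = fs),
            class = "cwt_result")
}

# Batched CWT modulus for the 60 best-channel waveforms of one eye.
# X: samples x waveforms matrix.  Returns a (scales x samples x waveforms)
# array.
cwt_modulus_batch <- function(X, scales = cwt_default_scales()) {
  kk <- cwt_kernels(scales)
  cwt_batch_cpp(X, kk$kernels, kk$centers, cwt_fft_lengths(nrow(X), kk))
}

# Modulus-maximum location per waveform (no cube materialisation):
# data.frame with scale index, sample index, max value per waveform.
cwt_argmax_batch <- function(X, scales = cwt_default_scales()) {
  kk <- cwt_kernels(scales)
  am <- cwt_argmax_cpp(X, kk$kernels, kk$centers,
                       cwt_fft_lengths(nrow(X), kk))
  data.frame(scale_idx = as.integer(am[1, ]), b_idx = as.integer(am[2, ]),
             max = am[3, ])
}

#' Translation of the scalogram modulus maximum
#'
#' `b_max`: the translation, in ms, at which the absolute maximum of
#' `|T(a, b)|` appears.  Ties are broken by the smallest translation, then
#' the smallest scale.
#'
#' @param result a [cwt_modulus()] result.
#' @return translation in ms.
#' @export
bmax <- function(result) {
  M <- result$modulus
  mx <- max(M)
  if (mx == 0) stop("all-zero modulus: b_max undefined")
  hits <- which(M == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  result$times_ms[hits[1, 2]]
}

#' Count of prominent scalogram local maxima
#'
#' `N_max`: the number of strict 2-D local maxima of `|T(a, b)|`
#' (8-neighbourhood; equal-valued plateaus merged into one and rejected if
#' they leak into non-maximal cells) whose value strictly exceeds
#' `max|T| * threshold`.
#'
#' @param result a [cwt_modulus()] result.
#' @param threshold relative height threshold (default 1/3).
#' @return integer count; 0 for an all-zero modulus.
#' @export
nmax <- function(result, threshold = 1 / 3) {
  M <- result$modulus
  mx <- max(M)
  if (mx == 0) return(0L)
  count_local_maxima(M, mx * threshold)
}

# Strict-8-neighbourhood local maxima above `cut` with plateau merging.
count_local_maxima <- function(M, cut) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(-Inf, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- M
  nb_max <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb_max <- pmax(nb_max, P[2:(nr + 1) + di, 2:(nc + 1) + dj])
  }
  cand <- M >= nb_max & M > cut
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  # merge equal-valued adjacent candidates; reject plateaus touching an
  # equal-valued non-candidate cell (a shoulder, not a maximum)
  candpad <- matrix(FALSE, nr + 2, nc + 2)
  candpad[2:(nr + 1), 2:(nc + 1)] <- cand
  comp <- matrix(0L, nr, nc)
  n_comp <- 0L
  n_ok <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (comp[i, j] != 0L) next
    n_comp <- n_comp + 1L
    ok <- TRUE
    stack <- list(c(i, j))
    comp[i, j] <- n_comp
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cur[1]; cj <- cur[2]
      v <- M[ci, cj]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- ci + di; nj <- cj + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (M[ni, nj] == v) {
          if (!cand[ni, nj]) ok <- FALSE
          else if (comp[ni, nj] == 0L) {
            comp[ni, nj] <- n_comp
            stack[[length(stack) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
    if (ok) n_ok <- n_ok + 1L
  }
  n_ok
}

#' Eye-level scalogram descriptors
#'
#' For each sector, computes the CWT modulus of the best channel and
#' extracts `b_max` and `N_max`; returns the means over the 60 sectors.
#' Sectors with an identically zero modulus are excluded from the means
#' with a warning.
#'
#' @param record an [mfvep_record()].
#' @param windows a [window_spec()] (for best-channel selection).
#' @param scales CWT scale grid.
#' @param best optional precomputed best-channel vector (length 60).
#' @param compute_nmax set `FALSE` to skip the local-maxima count.
#' @param per_sector also return the per-sector vectors.
#' @return list with `bmax_mean` (ms), `nmax_mean`, and, if requested,
#'   `bmax_sector`, `nmax_sector`.
#' @export
eye_cwt_features <- function(record, windows = window_spec(),
                             scales = cwt_default_scales(), best = NULL,
                             compute_nmax = TRUE, per_sector = FALSE) {
  if (is.null(best)) best <- best_channels(record, windows)
  n <- dim(record$data)[3]
  X <- vapply(seq_len(60), function(s) record$data[s, best[s], ],
              numeric(n))                       # samples x 60
  times_ms <- (seq_len(n) - 1) / record$fs * 1000
  bm <- rep(NA_real_, 60)
  nm <- rep(NA_real_, 60)
  if (!compute_nmax) {
    am <- cwt_argmax_batch(X, scales)
    zero <- am$max == 0
    if (any(zero))
      warning("sector(s) ", paste(which(zero), collapse = ", "),
              " have an all-zero scalogram; excluded")
    bm[!zero] <- times_ms[am$b_idx[!zero]]
  } else {
    cube <- cwt_modulus_batch(X, scales)
    for (s in seq_len(60)) {
      M <- cube[, , s]
      mx <- max(M)
      if (mx == 0) {
        warning("sector ", s, " has an all-zero scalogram; excluded")
        next
      }
      hits <- which(M == mx, arr.ind = TRUE)
      hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
      bm[s] <- times_ms[hits[1, 2]]
      nm[s] <- count_local_maxima(M, mx / 3)
    }
  }
  out <- list(bmax_mean = mean(bm, na.rm = TRUE),
              nmax_mean = if (compute_nmax) mean(nm, na.rm = TRUE) else NA_real_)
  if (per_sector) {
    out$bmax_sector <- bm
    out$nmax_sector <- nm
  }
  out
}
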
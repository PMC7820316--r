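# Daubechies-7 wavelet support -------------------------------------------
#
# The scalogram descriptors use the real Daubechies wavelet with 7 vanishing
# moments (db7, 14-tap filter, support [0, 13]).  No installed package
# tabulates the db7 wavelet function for a continuous transform, so it is
# reconstructed here from the standard orthonormal filter bank with the
# cascade algorithm.

# Reconstruction low-pass filter h (sums to sqrt(2)) and its quadrature
# mirror g; standard published db7 coefficients.
.db7_rec_lo <- c(
   0.07785205408500918,   0.39653931948191730,  0.72913209084623510,
   0.46978228740519310,  -0.14390600392856498, -0.22403618499387498,
   0.07130921926683026,   0.08061260915108308, -0.03802993693501441,
  -0.01657454163066688,   0.01255099855609984,  0.00042957797292136650,
  -0.00180164070404749080, 0.00035371379997452024)

.db7_rec_hi <- c(
   0.00035371379997452024, 0.00180164070404749080, 0.00042957797292136650,
  -0.01255099855609984,  -0.01657454163066688,  0.03802993693501441,
   0.08061260915108308,  -0.07130921926683026, -0.22403618499387498,
   0.14390600392856498,   0.46978228740519310, -0.72913209084623510,
   0.39653931948191730,  -0.07785205408500918)

# Full linear convolution via FFT (used only at build time of the table).
.conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  fa <- stats::fft(c(a, numeric(n - length(a))))
  fb <- stats::fft(c(b, numeric(n - length(b))))
  Re(stats::fft(fa * fb, inverse = TRUE)) / n
}

#' Tabulate the db7 wavelet function
#'
#' Runs the cascade algorithm on the db7 filter bank: starting from the
#' high-pass reconstruction filter, the approximation is repeatedly upsampled
#' and convolved with the low-pass filter.  After `level` iterations the
#' result approximates psi on a dyadic grid of step `2^-level` over the
#' support `[0, 13]`.
#'
#' @param level number of cascade iterations (grid step `2^-level`).
#' @return list with `step` (grid spacing) and `values`; `values[i]`
#'   approximates `psi(i * step)`.
#' @keywords internal
db7_wavefun <- function(level = 10L) {
  key <- paste0("db7_", level)
  if (!is.null(.mfvepris_cache[[key]])) return(.mfvepris_cache[[key]])
  v <- .db7_rec_hi
  if (level > 1L) for (j in 2:level) {
    up <- numeric(2L * length(v) - 1L)
    up[seq(1L, length(up), 2L)] <- v
    v <- .conv_full(up, .db7_rec_lo)
  }
  out <- list(step = 2^-level, values = v * 2^(level / 2))
  .mfvepris_cache[[key]] <- out
  out
}

#' Evaluate the db7 wavelet function
#'
#' Linear interpolation into the cascade table; zero outside the support
#' `[0, 13]`.
#'
#' @param t numeric vector of evaluation points.
#' @param level cascade refinement level.
#' @return numeric vector `psi(t)`.
#' @keywords internal
db7_psi <- function(t, level = 10L) {
  tab <- db7_wavefun(level)
  nv <- length(tab$values)
  i <- t / tab$step
  i0 <- floor(i)
  fr <- i - i0
  at <- function(k) ifelse(k >= 1 & k <= nv, tab$values[pmin(pmax(k, 1L), nv)], 0)
  out <- (1 - fr) * at(i0) + fr * at(i0 + 1)
  out[t < 0 | t > 13] <- 0
  out
}
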
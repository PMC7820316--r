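# Preprocessing: channel derivation, FFT band-pass, window extraction ----

#' mfVEP recording container
#'
#' One eye's multifocal VEP ensemble: 60 stimulus sectors x 6 channels x
#' 600 samples recorded at 1200 Hz (500 ms per record), amplitudes in
#' arbitrary microvolt-like units.  Channels 1-3 are the recorded bipolar
#' channels, 4-6 the derived pairwise differences (see [derive_channels()]).
#'
#' @param data numeric array with dim `c(60, 6, 600)`; all values finite.
#' @param fs sampling rate in Hz (must be 1200).
#' @param patient_id,eye optional metadata (eye is `"OD"` or `"OS"`).
#' @return object of class `mfvep_record`.
#' @export
mfvep_record <- function(data, fs = 1200, patient_id = NA_character_,
                         eye = NA_character_) {
  if (!is.array(data) || !identical(dim(data), c(60L, 6L, 600L)))
    stop("`data` must be a 60 x 6 x 600 array")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (fs != 1200) stop("`fs` must be 1200 Hz")
  structure(list(data = data, fs = fs,
                 meta = list(patient_id = patient_id, eye = eye)),
            class = "mfvep_record")
}

#' @export
print.mfvep_record <- function(x, ...) {
  cat("<mfvep_record>", x$meta$patient_id, x$meta$eye, "-",
      "60 sectors x 6 channels x 600 samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Analysis window specification
#'
#' The signal window (default 45-150 ms) contains the evoked response; the
#' noise window (325-430 ms) contains essentially noise.  Windows are
#' half-open `[lo, hi)` in milliseconds and must be disjoint and inside the
#' 500 ms record.
#'
#' @param signal,noise numeric length-2 vectors, `c(lo, hi)` in ms.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(signal = c(45, 150), noise = c(325, 430)) {
  chk <- function(w, nm) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > 500)
      stop("`", nm, "` must be an increasing interval within [0, 500) ms")
  }
  chk(signal, "signal"); chk(noise, "noise")
  if (max(signal[1], noise[1]) < min(signal[2], noise[2]))
    stop("signal and noise windows must be disjoint")
  structure(list(signal = signal, noise = noise), class = "window_spec")
}

#' Derive the three difference channels
#'
#' From the three recorded bipolar channels A, B, C, appends the pairwise
#' differences, the standard multichannel-mfVEP construction, giving the
#' fixed channel order A, B, C, A-B, B-C, A-C.
#'
#' @param recorded numeric matrix with 3 rows (channels) and one column per
#'   sample.
#' @return numeric matrix with 6 rows in the order above.
#' @export
derive_channels <- function(recorded) {
  if (!is.matrix(recorded) || nrow(recorded) != 3)
    stop("`recorded` must be a matrix with exactly 3 channel rows")
  rbind(recorded,
        recorded[1, ] - recorded[2, ],
        recorded[2, ] - recorded[3, ],
        recorded[1, ] - recorded[3, ])
}

#' Zero-phase FFT brick-wall band-pass filter
#'
#' Transforms the waveform, zeroes every frequency bin with `|f| < lo` or
#' `|f| > hi` (including DC), and inverse-transforms.  This is the filter
#' named in the recording protocol (digital pass-band 1-35 Hz via the fast
#' Fourier transform); it is idempotent and exactly energy-preserving in
#' band.
#'
#' @param x numeric vector, or a matrix whose columns are waveforms.
#' @param lo,hi band edges in Hz (`lo < hi < fs/2`).
#' @param fs sampling rate in Hz.
#' @return filtered waveform(s), same shape as `x`.
#' @export
bandpass_fft <- function(x, lo = 1, hi = 35, fs = 1200) {
  if (!all(is.finite(x))) stop("`x` contains non-finite values")
  if (!(lo < hi && hi < fs / 2)) stop("need lo < hi < fs/2")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  f <- (seq_len(n) - 1) * fs / n
  f <- ifelse(f > fs / 2, f - fs, f)           # signed bin frequencies
  keep <- abs(f) >= lo & abs(f) <= hi
  X <- stats::mvfft(xm)
  X[!keep, ] <- 0
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Extract a time window from a waveform
#'
#' Half-open window `[lo, hi)` ms mapped to 0-based sample indices
#' `[round(lo * fs / 1000), round(hi * fs / 1000))`; at 1200 Hz both default
#' analysis windows contain exactly 126 samples.
#'
#' @param x numeric waveform.
#' @param window length-2 numeric, `c(lo, hi)` in ms.
#' @param fs sampling rate in Hz.
#' @return the samples falling in the window.
#' @export
extract_window <- function(x, window, fs = 1200) {
  n <- length(x)
  i0 <- round(window[1] * fs / 1000)
  i1 <- round(window[2] * fs / 1000)
  if (i1 <= i0) stop("empty window")
  if (i0 < 0 || i1 > n) stop("window outside the record")
  x[(i0 + 1):i1]
}
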
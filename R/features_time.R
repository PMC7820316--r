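# Time-domain features: windowed SNR, best channel, normative latency ----

#' Root mean square amplitude
#'
#' @param x non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0) stop("empty segment")
  sqrt(mean(x^2))
}

# Mean noise-window RMS per channel (length-6), the SNR denominator: for
# each channel, the average over all 60 sectors of the RMS in the noise
# window of that channel.  scope = "all-channels" pools all 360 waveforms
# into one denominator instead.
noise_floor <- function(record, windows = window_spec(),
                        scope = c("per-channel", "all-channels")) {
  scope <- match.arg(scope)
  fs <- record$fs
  i0 <- round(windows$noise[1] * fs / 1000) + 1
  i1 <- round(windows$noise[2] * fs / 1000)
  seg <- record$data[, , i0:i1, drop = FALSE]
  r <- sqrt(apply(seg^2, c(1, 2), mean))     # 60 x 6 noise RMS
  if (scope == "per-channel") colMeans(r) else rep(mean(r), 6)
}

# 60 x 6 matrix of sector SNR values for one eye.
snr_matrix <- function(record, windows = window_spec(),
                       scope = c("per-channel", "all-channels")) {
  scope <- match.arg(scope)
  fs <- record$fs
  i0 <- round(windows$signal[1] * fs / 1000) + 1
  i1 <- round(windows$signal[2] * fs / 1000)
  seg <- record$data[, , i0:i1, drop = FALSE]
  num <- sqrt(apply(seg^2, c(1, 2), mean))   # 60 x 6 signal RMS
  den <- noise_floor(record, windows, scope)
  if (any(den == 0)) stop("degenerate recording: zero noise floor")
  sweep(num, 2, den, "/")
}

#' Sector signal-to-noise ratio
#'
#' SNR of one sector/channel: the RMS amplitude in the signal window divided
#' by the mean noise-window RMS of the same channel over all 60 sectors of
#' the eye (the per-channel noise floor).
#'
#' @param record an [mfvep_record()].
#' @param sector sector index, 1-60.
#' @param channel channel index, 1-6.
#' @param windows a [window_spec()].
#' @param scope denominator scope: `"per-channel"` (default; 60 noise RMS
#'   values of that channel) or `"all-channels"` (all 360 waveforms).
#' @return dimensionless SNR (V/V).
#' @export
sector_snr <- function(record, sector, channel, windows = window_spec(),
                       scope = c("per-channel", "all-channels")) {
  snr_matrix(record, windows, scope)[sector, channel]
}

#' Best channel of a sector
#'
#' The channel with the highest sector SNR; ties go to the lowest channel
#' index.
#'
#' @inheritParams sector_snr
#' @return channel index in 1-6.
#' @export
best_channel <- function(record, sector, windows = window_spec()) {
  which.max(snr_matrix(record, windows)[sector, ])
}

# Best channel for every sector at once (length-60 integer vector).
best_channels <- function(record, windows = window_spec()) {
  apply(snr_matrix(record, windows), 1, which.max)
}

#' Eye-level SNR
#'
#' Mean over the 60 sectors of the sector SNR at each sector's best channel.
#'
#' @inheritParams sector_snr
#' @return dimensionless eye SNR.
#' @export
eye_snr <- function(record, windows = window_spec()) {
  m <- snr_matrix(record, windows)
  mean(apply(m, 1, max))
}

#' Sector latency against a normative template
#'
#' Lag (ms, positive = subject delayed) maximising the normalised
#' (Pearson) cross-correlation between a waveform and the normative
#' template, searched over integer-sample lags in `[-max_lag, +max_lag]`.
#' Correlations are computed on the overlapping segment at each lag; ties
#' are broken by the smallest `|lag|`, then negative before positive.
#'
#' @param x waveform (full filtered record, 600 samples).
#' @param template normative template of the same length.
#' @param max_lag maximum absolute lag in ms.
#' @param fs sampling rate in Hz.
#' @return latency in ms.
#' @export
sector_latency <- function(x, template, max_lag = 50, fs = 1200) {
  n <- length(x)
  if (length(template) != n) stop("waveform and template lengths differ")
  if (stats::sd(x) == 0 || stats::sd(template) == 0)
    stop("zero-variance input: latency undefined")
  kmax <- floor(max_lag * fs / 1000)
  if (kmax >= n) stop("max_lag exceeds the record")
  lags <- (-kmax):kmax
  r <- vapply(lags, function(k) {
    if (k >= 0) a <- x[(k + 1):n] else a <- x[1:(n + k)]
    if (k >= 0) b <- template[1:(n - k)] else b <- template[(1 - k):n]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  # tie-break: max r, then smallest |lag|, then negative lag first
  ord <- order(-r, abs(lags), lags)
  lags[ord[1]] / fs * 1000
}

#' Eye-level latency
#'
#' Mean over the 60 sectors of the best-channel sector latency against the
#' corresponding normative-database template.
#'
#' @param record an [mfvep_record()].
#' @param normdb a [normative_db()].
#' @param windows a [window_spec()] (used for best-channel selection).
#' @param max_lag maximum absolute lag in ms.
#' @return mean latency in ms.
#' @export
eye_latency <- function(record, normdb, windows = window_spec(),
                        max_lag = 50) {
  if (nrow(normdb$templates) != dim(record$data)[1])
    stop("record and normative database sector counts differ")
  bc <- best_channels(record, windows)
  lat <- vapply(seq_len(60), function(s) {
    sector_latency(record$data[s, bc[s], ], normdb$templates[s, ],
                   max_lag = max_lag, fs = record$fs)
  }, numeric(1))
  mean(lat)
}

#' Extract all per-eye features
#'
#' Runs best-channel selection once, then computes the eye-level SNR,
#' normative latency, and the scalogram descriptors (mean `b_max`, mean
#' `N_max`) for one eye.
#'
#' @inheritParams eye_latency
#' @param scales CWT scale grid, see [cwt_default_scales()].
#' @param compute_latency,compute_nmax set `FALSE` to skip those features.
#' @return object of class `eye_features`: a list with `snr`, `latency_ms`,
#'   `bmax_ms`, `nmax`, per-sector vectors, and the eye metadata.
#' @export
eye_features <- function(record, normdb = NULL, windows = window_spec(),
                         scales = cwt_default_scales(), max_lag = 50,
                         compute_latency = !is.null(normdb),
                         compute_nmax = TRUE) {
  m <- snr_matrix(record, windows)
  bc <- apply(m, 1, which.max)
  snr_sector <- m[cbind(seq_len(60), bc)]
  lat_sector <- rep(NA_real_, 60)
  if (compute_latency) {
    if (is.null(normdb)) stop("latency requested but no normative database")
    lat_sector <- vapply(seq_len(60), function(s) {
      sector_latency(record$data[s, bc[s], ], normdb$templates[s, ],
                     max_lag = max_lag, fs = record$fs)
    }, numeric(1))
  }
  cwt <- eye_cwt_features(record, windows, scales = scales,
                          best = bc, compute_nmax = compute_nmax,
                          per_sector = TRUE)
  structure(list(
    snr = mean(snr_sector),
    latency_ms = if (compute_latency) mean(lat_sector) else NA_real_,
    bmax_ms = cwt$bmax_mean,
    nmax = cwt$nmax_mean,
    per_sector = data.frame(sector = seq_len(60), best_channel = bc,
                            snr = snr_sector, latency_ms = lat_sector,
                            bmax_ms = cwt$bmax_sector,
                            nmax = cwt$nmax_sector),
    meta = record$meta
  ), class = "eye_features")
}
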
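# Shared fixtures, built in code.

# A record with every value zero except what `fill` writes into the
# 60 x 6 x 600 array.
blank_record <- function(fill = NULL) {
  data <- array(0, c(60, 6, 600))
  if (!is.function(fill)) fill <- function(d) d
  mfvep_record(fill(data), patient_id = "T01", eye = "OD")
}

# Sample index ranges of the default windows at 1200 Hz (1-based).
sig_idx <- 55:180
noi_idx <- 391:516

# A fabricated eye_features object (for aggregation tests).
fake_eye <- function(snr, lat, bm, nm, pid = "T01", eye = "OD") {
  structure(list(snr = snr, latency_ms = lat, bmax_ms = bm, nmax = nm,
                 per_sector = NULL,
                 meta = list(patient_id = pid, eye = eye)),
            class = "eye_features")
}

# Fast generator settings used where a full eye is needed but the exact
# preset does not matter.
quick_config <- function(...) generator_config(...)

quick_preset <- function(label = "non_converter", snr = 4.07, bm = 139.03,
                         dispersion = 1, amplitude = 0.95, peak = 110) {
  p <- group_preset(label, target_eye_snr = snr, target_bmax = bm,
                    dispersion_factor = dispersion)
  p$amplitude_scale <- amplitude
  p$peak_time <- peak
  p
}
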
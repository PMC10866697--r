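#' Spectral band powers and RMS amplitude of a waveform segment
#'
#' Summarises a sampled waveform (one phoneme's worth of audio) as the mean
#' periodogram power within ten geometrically spaced frequency bands from
#' 200 to 5,000 Hz, plus the root-mean-square amplitude. A rectangular
#' window is used; bands with no periodogram ordinate get power 0.
#'
#' @param segment Numeric waveform samples (length >= 2).
#' @param rate Sampling rate in Hz; must exceed 10 kHz so the 5 kHz band
#'   edge is below Nyquist.
#' @param n_bands Number of log-spaced bands (default 10).
#' @param f_lo,f_hi Band range in Hz.
#' @return List with `band_power` (length `n_bands`, non-negative),
#'   `band_edges` (length `n_bands + 1`) and `rms`.
#' @export
band_powers_from_waveform <- function(segment, rate, n_bands = 10,
                                      f_lo = 200, f_hi = 5000) {
  assert_that(length(segment) >= 2, "segment must have at least 2 samples",
              class = "phonopop_short_segment")
  assert_that(rate > 2 * f_hi, "sampling rate too low for the 5 kHz band edge",
              class = "phonopop_short_segment")
  n <- length(segment)
  sp <- Mod(stats::fft(segment))^2 / n
  freq <- (seq_len(n) - 1) * rate / n
  half <- freq <= rate / 2
  sp <- sp[half]; freq <- freq[half]

  edges <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands + 1))
  band_power <- vapply(seq_len(n_bands), function(b) {
    in_band <- freq >= edges[b] & freq < edges[b + 1]
    if (!any(in_band)) 0 else mean(sp[in_band])
  }, numeric(1))

  list(band_power = band_power, band_edges = edges,
       rms = sqrt(mean(segment^2)))
}
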
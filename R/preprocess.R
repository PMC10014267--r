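# FIR filtering, referencing, and epoch rejection.

# Linear-phase FIR applied with group-delay compensation (zero-phase
# overall for the symmetric designs used here). FFT-based convolution.
fir_apply <- function(data, h) {
  ntaps <- length(h)
  gd <- (ntaps - 1) / 2
  if (abs(gd - round(gd)) > 0)
    stopf("FIR kernel must have odd length (even order) for exact delay compensation")
  gd <- as.integer(round(gd))
  nt <- ncol(data)
  nfft <- stats::nextn(nt + ntaps - 1, 2)
  H <- stats::fft(c(h, rep(0, nfft - ntaps)))
  out <- matrix(0, nrow(data), nt)
  for (ch in seq_len(nrow(data))) {
    X <- stats::fft(c(data[ch, ], rep(0, nfft - nt)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    out[ch, ] <- y[(gd + 1):(gd + nt)]
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed linear-phase FIR band-pass (default 1-200 Hz, order
#' 7500 at 512 Hz) applied per channel with group-delay compensation, so
#' the net response is zero-phase. The DC component is removed.
#'
#' @param rec an `eeg_recording`.
#' @param lo_hz,hi_hz band edges, Hz; `hi_hz` must be below Nyquist.
#' @param order filter order (number of taps minus one, even). Must be
#'   long enough that the Hamming transition band (about `3.3 * rate /
#'   order` Hz) fits below `lo_hz`.
#' @return the filtered recording.
#' @export
bandpass_fir <- function(rec, lo_hz = 1, hi_hz = 200, order = 7500) {
  nyq <- rec$rate / 2
  if (hi_hz >= nyq) stopf("hi_hz (%g) must be < Nyquist (%g)", hi_hz, nyq)
  if (lo_hz <= 0 || lo_hz >= hi_hz) stopf("need 0 < lo_hz < hi_hz")
  min_order <- ceiling(3.3 * rec$rate / lo_hz)
  if (order < min_order)
    stopf("order %d too short for a %g Hz low edge at %g Hz; need >= %d",
          order, lo_hz, rec$rate, min_order)
  if (order %% 2 == 1) stopf("order must be even")
  h <- signal::fir1(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  data <- rec$data - rowMeans(rec$data)
  rec$data <- fir_apply(data, h)
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Zero-phase FIR notch filter for mains noise
#'
#' Hamming-windowed band-stop FIR (default 50 Hz, order 3302) with
#' group-delay compensation. The stop band spans `mains_hz +/- bw_hz`;
#' neighbouring frequencies (45/55 Hz for the defaults) are preserved.
#'
#' @param rec an `eeg_recording`.
#' @param mains_hz mains frequency, Hz.
#' @param order filter order (even).
#' @param bw_hz half-width of the stop band, Hz.
#' @return the filtered recording.
#' @export
notch_fir <- function(rec, mains_hz = 50, order = 3302, bw_hz = 2) {
  nyq <- rec$rate / 2
  if (mains_hz + bw_hz >= nyq) stopf("notch band exceeds Nyquist")
  min_order <- ceiling(3.3 * rec$rate / bw_hz)
  if (order < min_order)
    stopf("order %d too short for a %g Hz stop band at %g Hz; need >= %d",
          order, bw_hz, rec$rate, min_order)
  if (order %% 2 == 1) stopf("order must be even")
  h <- signal::fir1(order, c(mains_hz - bw_hz, mains_hz + bw_hz) / nyq,
                    type = "stop")
  rec$data <- fir_apply(rec$data, h)
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, the
#' referencing used for source imaging. Refuses to re-reference twice.
#'
#' @param rec an `eeg_recording` with `reference == "raw"`.
#' @return the re-referenced recording (`reference = "common_average"`).
#' @export
common_average <- function(rec) {
  if (rec$reference != "raw")
    stopf("recording is already referenced (%s)", rec$reference)
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "common_average"
  rec
}

#' Reject artifactual stride epochs
#'
#' Drops epochs containing any sample exceeding `amplitude_uv` in absolute
#' value, or any channel whose peak-to-peak range is below `flatline_uv`
#' (dead channel / saturated amplifier), on any channel. These reproducible
#' rules stand in for the visual inspection used on clinical recordings.
#'
#' @param epochs a `gait_epochs` set.
#' @param amplitude_uv absolute amplitude threshold, microvolts.
#' @param flatline_uv peak-to-peak flatline threshold, microvolts.
#' @return the surviving `gait_epochs`; errors if none survive.
#' @export
reject_epochs <- function(epochs, amplitude_uv = 200, flatline_uv = 0.5) {
  stopifnot(inherits(epochs, "gait_epochs"))
  keep <- vapply(epochs$epochs, function(e) {
    pp <- apply(e, 1, function(x) diff(range(x)))
    max(abs(e)) <= amplitude_uv && all(pp >= flatline_uv)
  }, TRUE)
  if (!any(keep)) stopf("all %d epochs rejected", length(keep))
  message(sprintf("reject_epochs: %d of %d epochs survive",
                  sum(keep), length(keep)))
  subset_gait_epochs(epochs, which(keep))
}
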
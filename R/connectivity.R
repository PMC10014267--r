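# Scalp connectivity: time-frequency decomposition, phase-locking value,
# imaginary coherency, spherical-spline interpolation and the
# original-vs-interpolated PLV difference used as the cerebellar-signal
# evidence construct.

#' Morlet time-frequency decomposition on consecutive 2-s epochs
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_len_s` seconds and computes one complex Morlet coefficient per
#' channel, frequency and epoch at the epoch-center sample (the phase/
#' amplitude estimate each epoch contributes to PLV and ImCoh). The
#' wavelet has `n_cycles` cycles (Gaussian sd `n_cycles / (2 pi f)` s) and
#' unit energy; it is truncated at the epoch edges.
#'
#' @param rec an `eeg_recording`, or a channels x samples matrix plus
#'   `rate`.
#' @param freqs frequency grid, Hz; default 20 log-spaced bins over
#'   2-45 Hz (below the mains notch).
#' @param epoch_len_s epoch length, seconds (default 2).
#' @param n_cycles Morlet cycles (default 7).
#' @param rate sampling rate when `rec` is a plain matrix.
#' @return object of class `tfd_result`: `coeffs` (channels x freqs x
#'   epochs, complex), `freqs`, `epoch_len_s`, `channel_names`.
#' @export
tfd <- function(rec, freqs = default_freq_grid(), epoch_len_s = 2,
                n_cycles = 7, rate = NULL) {
  if (inherits(rec, "eeg_recording")) {
    data <- rec$data; rate <- rec$rate; chn <- rec$channel_names
  } else {
    data <- as.matrix(rec)
    if (is.null(rate)) stopf("rate required for matrix input")
    chn <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  if (min(freqs) * epoch_len_s < 2)
    stopf("lowest frequency %.3g Hz unresolvable in %g s epochs (need >= 2 cycles)",
          min(freqs), epoch_len_s)
  L <- as.integer(round(epoch_len_s * rate))
  nE <- floor(ncol(data) / L)
  if (nE < 1) stopf("recording shorter than one epoch")
  nC <- nrow(data); nF <- length(freqs)
  tau <- ((seq_len(L) - 1) - (L - 1) / 2) / rate     # time from epoch center
  W <- vapply(freqs, function(f) {
    sdt <- n_cycles / (2 * pi * f)
    w <- exp(2i * pi * f * tau) * exp(-tau^2 / (2 * sdt^2))
    w / sqrt(sum(Mod(w)^2))
  }, complex(L))                                     # L x nF
  coeffs <- array(complex(1), c(nC, nF, nE))
  for (e in seq_len(nE)) {
    seg <- data[, ((e - 1) * L + 1):(e * L), drop = FALSE]
    coeffs[, , e] <- seg %*% Conj(W)
  }
  dimnames(coeffs) <- list(chn, NULL, NULL)
  structure(list(coeffs = coeffs, freqs = freqs, epoch_len_s = epoch_len_s,
                 n_cycles = n_cycles, channel_names = chn),
            class = "tfd_result")
}

#' Default connectivity frequency grid: 20 log-spaced bins over 2-45 Hz
#' @export
default_freq_grid <- function() exp(seq(log(2), log(45), length.out = 20))

check_nonzero_coeffs <- function(tfdres) {
  if (any(Mod(tfdres$coeffs) == 0))
    stopf("zero spectral amplitude in at least one channel/frequency/epoch")
}

ref_other_index <- function(tfdres, ref_channels, others = NULL) {
  chn <- tfdres$channel_names
  ri <- match(ref_channels, chn)
  if (anyNA(ri)) stopf("reference channel(s) not found: %s",
                       paste(ref_channels[is.na(ri)], collapse = ", "))
  oi <- if (is.null(others)) seq_along(chn) else match(others, chn)
  list(ri = ri, oi = oi, chn = chn)
}

#' Phase-locking value between reference and other channels
#'
#' `PLV(a, b, f) = |mean over epochs of exp(i (phi_a - phi_b))|`, the
#' across-epoch consistency of the phase difference; 1 means a perfectly
#' consistent (not necessarily zero) lag.
#'
#' @param tfdres a `tfd_result` with >= 2 epochs.
#' @param ref_channels reference channels (default O1/O2, the occipital
#'   cerebellar proxies).
#' @param others channels to pair with; default all.
#' @return object of class `plv_matrix`: `plv` (refs x others x freqs in
#'   [0,1]), `n_epochs`.
#' @export
plv <- function(tfdres, ref_channels = c("O1", "O2"), others = NULL) {
  ix <- ref_other_index(tfdres, ref_channels, others)
  nE <- dim(tfdres$coeffs)[3]
  if (nE < 2) stopf("PLV needs >= 2 epochs (degenerate at 1)")
  check_nonzero_coeffs(tfdres)
  z <- tfdres$coeffs / Mod(tfdres$coeffs)            # unit phasors
  out <- array(0, c(length(ix$ri), length(ix$oi), length(tfdres$freqs)),
               dimnames = list(ix$chn[ix$ri], ix$chn[ix$oi], NULL))
  for (a in seq_along(ix$ri)) {
    za <- z[ix$ri[a], , , drop = FALSE]              # 1 x F x E
    for (b in seq_along(ix$oi)) {
      zb <- z[ix$oi[b], , , drop = FALSE]
      out[a, b, ] <- Mod(apply(za * Conj(zb), 2, mean))
    }
  }
  structure(list(plv = out, freqs = tfdres$freqs, n_epochs = nE,
                 ref_channels = ix$chn[ix$ri], others = ix$chn[ix$oi]),
            class = "plv_matrix")
}

#' Imaginary part of coherency
#'
#' `ImCoh(a, b, f) = Im(S_ab / sqrt(S_aa S_bb))` with cross- and
#' auto-spectra averaged over epochs. Insensitive to instantaneous
#' (zero-lag) mixtures of a common source -- the volume-conduction
#' robustness that motivates its use for gait-induced connectivity.
#'
#' @inheritParams plv
#' @return object of class `imcoh_matrix`: `imcoh` (refs x others x freqs
#'   in [-1,1]).
#' @export
imcoh <- function(tfdres, ref_channels = c("O1", "O2"), others = NULL) {
  ix <- ref_other_index(tfdres, ref_channels, others)
  nE <- dim(tfdres$coeffs)[3]
  if (nE < 2) stopf("ImCoh needs >= 2 epochs")
  C <- tfdres$coeffs
  auto <- apply(Mod(C)^2, c(1, 2), mean)             # channels x freqs
  if (any(auto == 0)) stopf("zero auto-spectrum")
  out <- array(0, c(length(ix$ri), length(ix$oi), length(tfdres$freqs)),
               dimnames = list(ix$chn[ix$ri], ix$chn[ix$oi], NULL))
  for (a in seq_along(ix$ri)) {
    for (b in seq_along(ix$oi)) {
      S_ab <- apply(C[ix$ri[a], , , drop = FALSE] *
                      Conj(C[ix$oi[b], , , drop = FALSE]), 2, mean)
      out[a, b, ] <- Im(S_ab / sqrt(auto[ix$ri[a], ] * auto[ix$oi[b], ]))
    }
  }
  structure(list(imcoh = out, freqs = tfdres$freqs, n_epochs = nE,
                 ref_channels = ix$chn[ix$ri], others = ix$chn[ix$oi]),
            class = "imcoh_matrix")
}

# Perrin g-function: truncated Legendre series
ssi_g <- function(x, m = 4, n_terms = 7) {
  leg <- legendre_table(x, n_terms)
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n^m * (n + 1)^m)
  (leg$P %*% w) / (4 * pi)
}

#' Spherical spline interpolation of target channels
#'
#' Perrin-style spherical spline: electrodes are projected onto the unit
#' sphere, spline coefficients are fit on the M non-target electrodes
#' (order-`m` Legendre series truncated at `n_terms` terms, Tikhonov
#' regularized solve), and the spline is evaluated at the target electrode
#' positions. The interpolated targets carry exactly the part of the
#' target signal explained by the scalp field of the other electrodes.
#'
#' @param rec an `eeg_recording` with a montage.
#' @param targets channels to interpolate (default O1/O2).
#' @param m spline order (default 4).
#' @param n_terms Legendre truncation (default 7).
#' @param reg Tikhonov regularization on the g-matrix solve.
#' @return matrix `length(targets)` x samples of interpolated signals,
#'   rownames = targets.
#' @export
spherical_spline_interpolate <- function(rec, targets = c("O1", "O2"),
                                         m = 4, n_terms = 7, reg = 1e-8) {
  if (is.null(rec$montage)) stopf("montage required for spline interpolation")
  pos <- montage_matrix(rec)
  ti <- match(targets, rec$channel_names)
  if (anyNA(ti)) stopf("target channel(s) not found: %s",
                       paste(targets[is.na(ti)], collapse = ", "))
  si <- setdiff(seq_len(nrow(pos)), ti)
  if (length(si) < 4) stopf("need >= 4 non-target channels, have %d", length(si))
  cosang <- pos[si, ] %*% t(pos[si, ])
  G <- matrix(ssi_g(pmin(pmax(cosang, -1), 1), m, n_terms),
              length(si), length(si))
  if (rcond(G + reg * diag(length(si))) < 1e-15)
    stopf("degenerate montage: spline system is singular")
  A <- rbind(cbind(G + reg * diag(length(si)), 1),
             c(rep(1, length(si)), 0))
  rhs <- rbind(rec$data[si, , drop = FALSE], 0)
  sol <- solve(A, rhs)                               # (M+1) x T
  cost <- pos[ti, , drop = FALSE] %*% t(pos[si, , drop = FALSE])
  Gt <- matrix(ssi_g(pmin(pmax(cost, -1), 1), m, n_terms),
               length(ti), length(si))
  out <- Gt %*% sol[seq_along(si), , drop = FALSE] +
    matrix(sol[length(si) + 1, ], length(ti), ncol(rec$data), byrow = TRUE)
  rownames(out) <- targets
  out
}

#' PLV difference between original and spline-interpolated targets
#'
#' Computes the phase-locking of the original target channels (default
#' O1/O2) with every channel (near and distant pairs, including the other
#' target), then replaces the targets with their spherical-spline
#' interpolation from the remaining electrodes and recomputes;
#' `dplv = PLV(original) - PLV(interpolated)`. A positive difference at a
#' pair/frequency indicates phase-locking in the original signal that the
#' scalp field of the other electrodes cannot explain -- the signature of
#' a locally generated (putatively cerebellar) source under the occipital
#' electrodes. The target-target pair carries most of that evidence.
#'
#' @param rec an `eeg_recording` with montage.
#' @param targets target channels (default O1/O2).
#' @param freqs,epoch_len_s,n_cycles TFD parameters, see [tfd()].
#' @param m,n_terms,reg spline parameters, see
#'   [spherical_spline_interpolate()].
#' @param others channels to pair the targets with (default all).
#' @return object of class `plv_difference`: `dplv` (targets x others x
#'   freqs), plus the two constituent `plv_matrix` objects.
#' @export
plv_difference <- function(rec, targets = c("O1", "O2"),
                           freqs = default_freq_grid(), epoch_len_s = 2,
                           n_cycles = 7, m = 4, n_terms = 7, reg = 1e-8,
                           others = rec$channel_names) {
  tf1 <- tfd(rec, freqs, epoch_len_s, n_cycles)
  p1 <- plv(tf1, targets, others)
  interp <- spherical_spline_interpolate(rec, targets, m, n_terms, reg)
  rec2 <- rec
  rec2$data[match(targets, rec$channel_names), ] <- interp
  tf2 <- tfd(rec2, freqs, epoch_len_s, n_cycles)
  p2 <- plv(tf2, targets, others)
  structure(list(dplv = p1$plv - p2$plv, freqs = freqs,
                 original = p1, interpolated = p2,
                 targets = targets, others = others),
            class = "plv_difference")
}
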
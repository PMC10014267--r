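#' Define a synthetic gait-EEG scenario
#'
#' The scenario holds the acquisition and ground-truth parameters for the
#' generator: stride count and timing statistics, planted sources, sensor
#' noise, mains contamination and the RNG seed. Defaults emulate a 20-min
#' treadmill walk recorded at 512 Hz: 500 strides of 1.1 s with 5%
#' duration jitter, and a per-epoch scalp SNR of 0.5 so that planted
#' sources are invisible in single strides and only epoch averaging
#' recovers them.
#'
#' @param n_epochs number of strides (>= 1).
#' @param stride_s mean stride duration, seconds.
#' @param stride_jitter_frac sd of stride duration as a fraction of
#'   `stride_s`.
#' @param lhs_frac mean position of the left heel strike within the
#'   stride (fraction of stride duration).
#' @param lhs_jitter_frac sd of the LHS position (fraction of stride).
#' @param rate sampling rate, Hz.
#' @param sources list of [planted_source()] objects.
#' @param snr per-epoch scalp SNR (signal RMS over active samples divided
#'   by noise sd); used to derive `noise_sd` when that is `NULL`.
#' @param noise_sd white sensor-noise sd in microvolts, or `NULL` to derive
#'   from `snr`.
#' @param line_hz mains frequency, Hz (0 disables).
#' @param line_amp_uv mains amplitude, microvolts.
#' @param blink_rate_hz rate of eye-blink-like frontal transients, per
#'   second (0 disables). When > 0 the simulated recording carries an EOG
#'   channel.
#' @param blink_amp_uv blink amplitude at the frontal-most channels.
#' @param start_s time of the first right heel strike, seconds. The
#'   default leaves room for the 1-s pre-stride baseline window of the
#'   first stride.
#' @param seed RNG seed; a fixed seed gives bit-reproducible output
#'   (R's default Mersenne-Twister generator).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_epochs = 500, stride_s = 1.1,
                         stride_jitter_frac = 0.05, lhs_frac = 0.5,
                         lhs_jitter_frac = 0.02, rate = 512,
                         sources = list(), snr = 0.5, noise_sd = NULL,
                         line_hz = 50, line_amp_uv = 20,
                         blink_rate_hz = 0, blink_amp_uv = 120,
                         start_s = 2, seed = 1) {
  stopifnot(n_epochs >= 1, stride_s > 0, rate > 0, stride_jitter_frac >= 0,
            lhs_frac > 0, lhs_frac < 1)
  if (length(sources) && !all(vapply(sources, inherits, TRUE, "planted_source")))
    stopf("sources must be a list of planted_source objects")
  structure(list(n_epochs = as.integer(n_epochs), stride_s = stride_s,
                 stride_jitter_frac = stride_jitter_frac,
                 lhs_frac = lhs_frac, lhs_jitter_frac = lhs_jitter_frac,
                 rate = rate, sources = sources, snr = snr,
                 noise_sd = noise_sd, line_hz = line_hz,
                 line_amp_uv = line_amp_uv, blink_rate_hz = blink_rate_hz,
                 blink_amp_uv = blink_amp_uv, start_s = start_s,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Define a planted dipolar source
#'
#' Ground truth for the recovery tests: a single source-space vertex whose
#' activity is gated to a subset of the gait-cycle quartiles (0-25, 25-50,
#' 50-75, 75-100% of the warped cycle). Gating uses a raised-cosine on/off
#' ramp spanning 10% of the quartile width, so that adjacent active
#' quartiles join seamlessly and step-gating spectral splatter does not
#' confound the filtering stages.
#'
#' @param vertex_id index into the source space.
#' @param active_quartiles subset of `c("Q1","Q2","Q3","Q4")`.
#' @param amplitude dipole moment, arbitrary positive scale.
#' @param waveform `"gaussian_burst"` (Gaussian-enveloped oscillation
#'   centered in the active span) or `"sinusoid"` (sustained oscillation).
#' @param freq_hz oscillation frequency, Hz.
#' @param phase_lag_s temporal lag of the oscillation, seconds.
#' @return object of class `planted_source`.
#' @export
planted_source <- function(vertex_id, active_quartiles = c("Q2", "Q3"),
                           amplitude = 1,
                           waveform = c("gaussian_burst", "sinusoid"),
                           freq_hz = 10, phase_lag_s = 0) {
  waveform <- match.arg(waveform)
  stopifnot(amplitude > 0, vertex_id >= 1)
  bad <- setdiff(active_quartiles, c("Q1", "Q2", "Q3", "Q4"))
  if (length(bad)) stopf("unknown quartile(s): %s", paste(bad, collapse = ", "))
  structure(list(vertex_id = as.integer(vertex_id),
                 active_quartiles = active_quartiles,
                 amplitude = amplitude, waveform = waveform,
                 freq_hz = freq_hz, phase_lag_s = phase_lag_s),
            class = "planted_source")
}

#' Simulate a heel-strike event stream
#'
#' Produces `n_epochs + 1` right heel strikes with jittered stride
#' durations and one left heel strike near mid-stride per stride, the
#' structure an inertial-sensor trigger would deliver.
#'
#' @param scenario a [sim_scenario()].
#' @return an `event_stream` with alternating RHS/LHS.
#' @export
simulate_gait_events <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(derive_seed(scenario$seed, "events"), {
    n <- scenario$n_epochs
    dur <- scenario$stride_s *
      pmax(0.2, 1 + stats::rnorm(n, sd = scenario$stride_jitter_frac))
    rhs <- scenario$start_s + c(0, cumsum(dur))
    frac <- pmin(0.9, pmax(0.1, scenario$lhs_frac +
                             stats::rnorm(n, sd = scenario$lhs_jitter_frac)))
    lhs <- rhs[seq_len(n)] + frac * dur
    tt <- c(rhs, lhs)
    ll <- c(rep("RHS", n + 1), rep("LHS", n))
    o <- order(tt)
    event_stream(tt[o], ll[o],
                 source = "simulated inertial-sensor trigger")
  })
}

# Phase (0-100) of times within one stride given its landmarks; piecewise
# linear with the LHS pinned to 50%.
stride_phase <- function(t, rhs0, lhs, rhs1) {
  ifelse(t <= lhs,
         50 * (t - rhs0) / (lhs - rhs0),
         50 + 50 * (t - lhs) / (rhs1 - lhs))
}

# Raised-cosine quartile gate evaluated on phase values (0-100). Ramps
# span `ramp` percent on each side of each active quartile; gates of
# adjacent active quartiles sum to one across the shared edge.
quartile_gate <- function(phase, quartiles, ramp = 2.5) {
  edges <- list(Q1 = c(0, 25), Q2 = c(25, 50), Q3 = c(50, 75), Q4 = c(75, 100))
  env <- numeric(length(phase))
  for (q in quartiles) {
    e <- edges[[q]]
    up <- pmin(1, pmax(0, (phase - (e[1] - ramp)) / (2 * ramp)))
    dn <- pmin(1, pmax(0, ((e[2] + ramp) - phase) / (2 * ramp)))
    # linear ramps remapped through the raised cosine 0.5*(1 - cos(pi u))
    env <- env + (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * dn))
  }
  # edge-most quartiles: clamp phase 0/100 to fully-on inside their span
  pmin(env, 1)
}

# Source time course for one planted source over the recording
source_timecourse <- function(src, times, events) {
  rhs <- events$time_s[events$label == "RHS"]
  lhs <- events$time_s[events$label == "LHS"]
  s <- numeric(length(times))
  for (i in seq_len(length(rhs) - 1)) {
    r0 <- rhs[i]; r1 <- rhs[i + 1]
    il <- lhs[lhs > r0 & lhs < r1]
    if (length(il) != 1) next
    sel <- which(times >= r0 & times < r1)
    if (!length(sel)) next
    ph <- stride_phase(times[sel], r0, il, r1)
    env <- quartile_gate(ph, src$active_quartiles)
    osc <- sin(2 * pi * src$freq_hz * (times[sel] - r0 - src$phase_lag_s))
    if (src$waveform == "gaussian_burst") {
      spans <- range(quartile_span(src$active_quartiles))
      tq <- r0 + (r1 - r0) * spans / 100
      mid <- mean(tq); sdv <- diff(tq) / 6
      env <- env * exp(-0.5 * ((times[sel] - mid) / sdv)^2)
    }
    s[sel] <- src$amplitude * env * osc
  }
  s
}

quartile_span <- function(quartiles) {
  edges <- c(Q1 = 0, Q2 = 25, Q3 = 50, Q4 = 75)
  lo <- min(edges[quartiles]); hi <- max(edges[quartiles]) + 25
  c(lo, hi)
}

#' Forward-simulate scalp EEG from planted sources
#'
#' Scalp data are the lead-field projection of the planted-source time
#' courses plus white sensor noise and a mains sinusoid with
#' channel-specific gains (so it survives common-average referencing, as
#' real line noise does). Source activity is gated to each stride's active
#' quartiles through that stride's own heel-strike landmarks. With
#' `blink_rate_hz > 0`, frontal-weighted eye-blink transients are added
#' and returned on a synchronous EOG channel.
#'
#' @param scenario a [sim_scenario()].
#' @param fwd a `forward_model` built on the source space the scenario's
#'   `vertex_id`s index.
#' @param events an `event_stream`; default [simulate_gait_events()] of
#'   the scenario.
#' @return an `eeg_recording` (reference `"raw"`, montage attached, EOG in
#'   `$eog` when blinks are enabled).
#' @export
simulate_eeg <- function(scenario, fwd, events = simulate_gait_events(scenario)) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(fwd, "forward_model"))
  nV <- ncol(fwd$leadfield)
  for (src in scenario$sources)
    if (src$vertex_id > nV)
      stopf("vertex_id %d outside source space (%d vertices)",
            src$vertex_id, nV)
  rate <- scenario$rate
  t_end <- max(events$time_s, scenario$start_s) + 1.0
  nt <- as.integer(ceiling(t_end * rate))
  times <- (seq_len(nt) - 1) / rate
  nC <- nrow(fwd$leadfield)
  signal <- matrix(0, nC, nt)
  active <- rep(FALSE, nt)
  for (src in scenario$sources) {
    s <- source_timecourse(src, times, events)
    signal <- signal + fwd$leadfield[, src$vertex_id] %o% s
    active <- active | (s != 0)
  }
  with_seed(derive_seed(scenario$seed, "eeg"), {
    noise_sd <- scenario$noise_sd
    if (is.null(noise_sd)) {
      rms <- if (any(active)) sqrt(mean(signal[, active]^2)) else 0
      noise_sd <- if (rms > 0) rms / scenario$snr else 1
    }
    data <- signal
    if (noise_sd > 0)
      data <- data + matrix(stats::rnorm(nC * nt, sd = noise_sd), nC, nt)
    if (scenario$line_hz > 0 && scenario$line_amp_uv > 0) {
      gains <- stats::runif(nC, 0.5, 1.5) * scenario$line_amp_uv
      phi <- stats::runif(1, 0, 2 * pi)
      data <- data + gains %o% sin(2 * pi * scenario$line_hz * times + phi)
    }
    eog <- NULL
    if (scenario$blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, scenario$blink_rate_hz * t_end)
      bt <- sort(stats::runif(n_blinks, 0, t_end))
      blink <- numeric(nt)
      for (b in bt) blink <- blink + exp(-0.5 * ((times - b) / 0.15)^2)
      topo <- pmax(0, fwd$montage$x)^2
      topo <- topo / max(topo)
      data <- data + (scenario$blink_amp_uv * topo) %o% blink
      eog <- scenario$blink_amp_uv * blink +
        stats::rnorm(nt, sd = max(noise_sd, 1))
    }
    eeg_recording(data, rate, fwd$channel_names, montage = fwd$montage,
                  reference = "raw", eog = eog)
  })
}

#' Simulate a two-group, two-timepoint clinical outcomes table
#'
#' Draws per-subject baseline scores per measure from Gaussian
#' distributions on each scale's natural range, applies group-specific
#' post-training shifts, adds test-retest noise and rounds to the nearest
#' scale unit (ordinal-ish scores).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effects named list: measure -> c(NMT = shift, nonNMT = shift)
#'   added at TPOST. Measures not listed get zero shift.
#' @param seed RNG seed.
#' @param retest_sd test-retest noise sd as a fraction of the measure's
#'   between-subject sd.
#' @return a `clinical_table`.
#' @export
simulate_clinical <- function(n_per_group, effects = list(), seed = 1,
                              retest_sd = 0.5) {
  stopifnot(n_per_group >= 2)
  base <- list(FGA = c(15, 4), UPDRS = c(40, 10), BBS = c(42, 6),
               FES = c(30, 8), TENMWT = c(16, 4), TUG = c(14, 4),
               GQI = c(60, 10))
  with_seed(derive_seed(seed, "clinical"), {
    rows <- list()
    for (g in CLINICAL_GROUPS) {
      ids <- sprintf("%s%02d", ifelse(g == "NMT", "N", "C"),
                     seq_len(n_per_group))
      for (m in CLINICAL_MEASURES) {
        mu <- base[[m]][1]; sdv <- base[[m]][2]
        pre <- stats::rnorm(n_per_group, mu, sdv)
        shift <- 0
        if (!is.null(effects[[m]]) && !is.na(effects[[m]][g]))
          shift <- unname(effects[[m]][g])
        post <- pre + shift + stats::rnorm(n_per_group, 0, retest_sd * sdv)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = rep(ids, 2), group = g,
          timepoint = rep(c("TPRE", "TPOST"), each = n_per_group),
          measure = m, value = round(c(pre, post)),
          stringsAsFactors = FALSE)
      }
    }
    clinical_table(do.call(rbind, rows))
  })
}
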
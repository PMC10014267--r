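# Stride segmentation, gait-phase time-warping, quartile views.

#' Gait epoch container
#' @noRd
gait_epochs <- function(epochs, landmarks, rate, baseline, channel_names) {
  stopifnot(length(epochs) == nrow(landmarks),
            length(baseline) == length(epochs))
  if (nrow(landmarks) &&
      !all(landmarks[, 1] < landmarks[, 2] & landmarks[, 2] < landmarks[, 3]))
    stopf("landmarks must satisfy t_RHS0 < t_LHS < t_RHS1")
  structure(list(epochs = epochs, landmarks = landmarks, rate = rate,
                 baseline = baseline, channel_names = channel_names),
            class = "gait_epochs")
}

#' @export
print.gait_epochs <- function(x, ...) {
  cat(sprintf("<gait_epochs> %d strides x %d channels @ %g Hz, 1-s baselines\n",
              length(x$epochs), length(x$channel_names), x$rate))
  invisible(x)
}

#' Number of epochs in a gait epoch set
#' @param x a `gait_epochs` or `warped_epochs` object.
#' @export
n_epochs <- function(x) {
  if (inherits(x, "gait_epochs")) length(x$epochs)
  else if (inherits(x, "warped_epochs")) dim(x$epochs)[3]
  else stopf("not an epoch container")
}

subset_gait_epochs <- function(x, idx) {
  gait_epochs(x$epochs[idx], x$landmarks[idx, , drop = FALSE], x$rate,
              x$baseline[idx], x$channel_names)
}

#' Segment continuous EEG into full strides
#'
#' One epoch per consecutive right-heel-strike pair containing exactly one
#' interior left heel strike, plus a 1-s pre-stride baseline segment.
#' Strides outside the duration bounds, missing their LHS, or overlapping
#' the recording edges (including the baseline window) are dropped.
#'
#' @param rec an `eeg_recording`.
#' @param events an `event_stream` with at least two RHS events.
#' @param stride_bounds_s admissible stride durations, seconds; the default
#'   (0.5, 2.5) excludes freezing episodes and sensor dropouts.
#' @return a `gait_epochs` object.
#' @export
extract_strides <- function(rec, events, stride_bounds_s = c(0.5, 2.5)) {
  rhs <- events$time_s[events$label == "RHS"]
  lhs <- events$time_s[events$label == "LHS"]
  if (length(rhs) < 2) stopf("need at least two RHS events, got %d", length(rhs))
  rate <- rec$rate
  nt <- n_samples(rec)
  epochs <- list(); baselines <- list(); lm <- NULL
  n_nolhs <- 0L
  for (i in seq_len(length(rhs) - 1)) {
    r0 <- rhs[i]; r1 <- rhs[i + 1]
    dur <- r1 - r0
    if (dur < stride_bounds_s[1] || dur > stride_bounds_s[2]) next
    il <- lhs[lhs > r0 & lhs < r1]
    if (length(il) != 1) { n_nolhs <- n_nolhs + 1L; next }
    i0 <- floor(r0 * rate) + 1
    i1 <- floor(r1 * rate)
    ib <- i0 - round(rate)
    if (ib < 1 || i1 > nt || i0 > i1) next   # overlaps a recording edge
    epochs[[length(epochs) + 1]] <- rec$data[, i0:i1, drop = FALSE]
    baselines[[length(baselines) + 1]] <- rec$data[, ib:(i0 - 1), drop = FALSE]
    lm <- rbind(lm, c(r0, il, r1))
  }
  if (n_nolhs > 0)
    warnf("%d stride(s) dropped: no single interior LHS", n_nolhs)
  if (!length(epochs)) stopf("no valid strides")
  colnames(lm) <- c("t_RHS0", "t_LHS", "t_RHS1")
  gait_epochs(epochs, lm, rate, baselines, rec$channel_names)
}

#' Time-warp stride epochs onto a common gait-phase axis
#'
#' Each stride is mapped by the two-segment piecewise-linear warp
#' [RHS0, LHS] -> [0, 50]% and [LHS, RHS1] -> [50, 100]% and resampled at
#' `G` uniform phase points `100*(j-1)/G`, j = 1..G (phase 100% is the
#' next cycle's 0%). Phases 0 and 50 fall exactly on grid points; the warp
#' pins the three heel strikes to 0, 50 and 100% by construction.
#'
#' @param epochs a `gait_epochs` set.
#' @param G phase-grid size (>= 8, divisible by 4). Default 200 (0.5%
#'   phase resolution).
#' @param method interpolation onto the phase grid: `"linear"`
#'   (vectorized, default) or `"spline"` (cubic).
#' @return object of class `warped_epochs`: `epochs` (channels x G x
#'   n_epochs array), `phase` (percent), `G`, `quartile_edges`,
#'   `landmarks`, `rate`, `channel_names`.
#' @export
time_warp <- function(epochs, G = 200, method = c("linear", "spline")) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "gait_epochs"))
  if (G < 8) stopf("G must be >= 8, got %d", G)
  if (G %% 4 != 0) stopf("G must be divisible by 4, got %d", G)
  n <- n_epochs(epochs)
  nc <- length(epochs$channel_names)
  rate <- epochs$rate
  phase <- 100 * (seq_len(G) - 1) / G
  out <- array(0, c(nc, G, n))
  for (e in seq_len(n)) {
    lmk <- epochs$landmarks[e, ]
    tt <- ifelse(phase <= 50,
                 lmk[1] + (phase / 50) * (lmk[2] - lmk[1]),
                 lmk[2] + ((phase - 50) / 50) * (lmk[3] - lmk[2]))
    E <- epochs$epochs[[e]]
    t0 <- (floor(lmk[1] * rate)) / rate           # time of first sample
    s <- (tt - t0) * rate + 1                     # fractional sample index
    s <- pmin(pmax(s, 1), ncol(E))
    if (method == "linear") {
      i0 <- pmin(floor(s), ncol(E) - 1)
      w <- s - i0
      out[, , e] <- E[, i0, drop = FALSE] * rep(1 - w, each = nc) +
        E[, i0 + 1, drop = FALSE] * rep(w, each = nc)
    } else {
      xi <- seq_len(ncol(E))
      for (ch in seq_len(nc))
        out[ch, , e] <- stats::spline(xi, E[ch, ], xout = s)$y
    }
  }
  dimnames(out) <- list(epochs$channel_names, NULL, NULL)
  structure(list(epochs = out, phase = phase, G = G,
                 quartile_edges = c(0, 25, 50, 75, 100),
                 landmarks = epochs$landmarks, rate = rate,
                 channel_names = epochs$channel_names),
            class = "warped_epochs")
}

#' @export
print.warped_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<warped_epochs> %d channels x %d phase points x %d strides\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Gait-cycle quartile views of a warped epoch set
#'
#' Splits the phase grid into the four gait quartiles with half-open bins
#' [0,25), [25,50), [50,75), [75,100), so every grid point belongs to
#' exactly one quartile and the four slices partition the grid.
#'
#' @param w a `warped_epochs` set (or anything with a `phase` vector).
#' @return named list `Q1`..`Q4` of phase-grid index vectors.
#' @export
quartile_slices <- function(w) {
  phase <- w$phase
  list(Q1 = which(phase >= 0 & phase < 25),
       Q2 = which(phase >= 25 & phase < 50),
       Q3 = which(phase >= 50 & phase < 75),
       Q4 = which(phase >= 75 & phase < 100))
}
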
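# Infomax ICA and artifact-component rejection.

#' Natural-gradient Infomax ICA
#'
#' Classic Infomax with the logistic nonlinearity: the data are centered,
#' whitened by PCA (eigenvalues below `rank_tol` times the largest are
#' dropped, which handles the rank deficiency of common-average-referenced
#' data), and the square unmixing matrix is learnt by natural-gradient
#' ascent on randomly ordered sample blocks with learning-rate annealing.
#' Convergence is declared when the relative weight change drops below
#' `tol`. With a fixed seed the decomposition is deterministic.
#'
#' Separation is only guaranteed for (at most one) non-Gaussian sources;
#' on Gaussian-only data the algorithm still converges but the rotation is
#' arbitrary.
#'
#' @param rec an `eeg_recording` (high-pass filtered data assumed).
#' @param n_components number of components; default = effective data rank
#'   (at most the channel count).
#' @param seed RNG seed for block shuffling.
#' @param max_iter maximum number of passes over the data.
#' @param tol convergence tolerance on the relative weight change.
#' @param lrate initial learning rate.
#' @param anneal per-iteration learning-rate cooling factor (applied after
#'   a 10-iteration burn-in, on top of the angle-triggered annealing).
#' @param rank_tol relative eigenvalue cutoff for the whitening step.
#' @return object of class `ica_decomposition`: `unmixing` (components x
#'   channels), `mixing` (channels x components, its pseudo-inverse),
#'   `component_scores` (filled by [reject_components()]), `rejected`
#'   (empty), plus the channel means removed before whitening.
#' @export
infomax_ica <- function(rec, n_components = NULL, seed = 1, max_iter = 1500,
                        tol = 1e-6, lrate = NULL, anneal = 0.99,
                        rank_tol = 1e-9) {
  X <- rec$data
  nc <- nrow(X); nt <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  ev <- eigen(tcrossprod(Xc) / nt, symmetric = TRUE)
  rank <- sum(ev$values > rank_tol * ev$values[1])
  k <- min(n_components %||% rank, rank, nc)
  if (k < 1) stopf("data has rank 0")
  E <- ev$vectors[, seq_len(k), drop = FALSE]
  d <- ev$values[seq_len(k)]
  wh <- diag(1 / sqrt(d), k) %*% t(E)          # k x nc whitening
  dewh <- E %*% diag(sqrt(d), k)               # nc x k
  Z <- wh %*% Xc                               # whitened
  if (is.null(lrate)) lrate <- 0.01 / log(k^2 + 1)
  block <- max(8L, min(nt, as.integer(ceiling(min(5 * sqrt(nt), 0.3 * nt)))))
  W <- diag(k)
  I <- diag(k)
  old_dW <- NULL
  wchange <- Inf
  converged <- FALSE
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      perm <- sample.int(nt)
      W0 <- W
      for (b in seq(1, nt - block + 1, by = block)) {
        idx <- perm[b:(b + block - 1)]
        u <- W %*% Z[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        dW <- lrate * (I + (1 - 2 * y) %*% t(u) / block) %*% W
        W <- W + dW
        if (max(abs(W)) > 1e8) stopf("ICA diverged; lower lrate")
      }
      dWi <- W - W0
      wchange <- sqrt(sum(dWi^2)) / sqrt(sum(W0^2))
      if (!is.null(old_dW)) {
        denom <- sqrt(sum(dWi^2) * sum(old_dW^2))
        ang <- if (denom > 0) sum(dWi * old_dW) / denom else 1
        if (ang < cos(60 * pi / 180)) lrate <- lrate * 0.9
      }
      # slow geometric cooling after a burn-in: the stochastic block noise
      # floor scales with lrate, so this guarantees the weight change
      # eventually drops below tol without stalling early learning
      if (iter > 10) lrate <- lrate * anneal
      old_dW <- dWi
      if (wchange < tol) { converged <- TRUE; break }
    }
  })
  if (!converged)
    stopf("Infomax did not converge in %d iterations (last relative weight change %.3g)",
          max_iter, wchange)
  unmixing <- W %*% wh
  mixing <- dewh %*% solve(W)
  rownames(mixing) <- rec$channel_names
  colnames(unmixing) <- rec$channel_names
  structure(list(unmixing = unmixing, mixing = mixing,
                 component_scores = NULL, rejected = integer(0),
                 center = mu, n_components = k),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d channels, %d rejected\n",
              nrow(x$unmixing), ncol(x$unmixing), length(x$rejected)))
  invisible(x)
}

#' Score and reject artifact components, reconstruct the EEG
#'
#' Components whose absolute correlation with the EOG exceeds
#' `eog_corr` or whose low-frequency power ratio (power below `lf_hz`
#' over power above) exceeds `lf_ratio` are zeroed; the recording is
#' reconstructed from the remaining components. With no EOG only the
#' low-frequency criterion applies.
#'
#' @param ica an `ica_decomposition`.
#' @param rec the `eeg_recording` it was fit on.
#' @param eog EOG signal (defaults to `rec$eog`), or `NULL`.
#' @param thresholds list with `eog_corr` (default 0.7) and `lf_ratio`
#'   (default 3); `Inf` disables a criterion.
#' @param lf_hz boundary of the "low-frequency" band, Hz.
#' @return the reconstructed `eeg_recording`; the decomposition with
#'   filled `component_scores` and `rejected` is attached as attribute
#'   `"ica"`. Errors if every component would be rejected.
#' @export
reject_components <- function(ica, rec, eog = rec$eog,
                              thresholds = list(eog_corr = 0.7, lf_ratio = 3),
                              lf_hz = 4) {
  comps <- ica$unmixing %*% (rec$data - ica$center)
  k <- nrow(comps)
  eogc <- rep(NA_real_, k)
  if (!is.null(eog))
    eogc <- abs(apply(comps, 1, stats::cor, y = as.numeric(eog)))
  lfr <- apply(comps, 1, function(x) {
    p <- Mod(stats::fft(x))^2
    nf <- length(x)
    freqs <- (seq_len(nf) - 1) / nf * rec$rate
    half <- freqs <= rec$rate / 2
    lo <- p[half & freqs < lf_hz]; hi <- p[half & freqs >= lf_hz]
    if (!length(hi) || sum(hi) == 0) return(Inf)
    mean(lo) / mean(hi)
  })
  rej <- which((!is.na(eogc) & eogc > (thresholds$eog_corr %||% Inf)) |
                 lfr > (thresholds$lf_ratio %||% Inf))
  if (length(rej) == k) stopf("all %d components rejected", k)
  keep <- setdiff(seq_len(k), rej)
  rec$data <- ica$mixing[, keep, drop = FALSE] %*%
    comps[keep, , drop = FALSE] + ica$center
  rownames(rec$data) <- rec$channel_names
  ica$component_scores <- data.frame(component = seq_len(k),
                                     eog_corr = eogc, lf_ratio = lfr)
  ica$rejected <- rej
  attr(rec, "ica") <- ica
  rec
}

#' Amari index of a permutation-scale recovery matrix
#'
#' Scores how close `P = unmixing %*% true_mixing` is to a scaled
#' permutation; 0 means perfect source recovery.
#'
#' @param P square matrix.
#' @return the Amari index in [0, 2 (k - 1) / k...]; below 0.05 is
#'   conventionally "recovered".
#' @export
amari_index <- function(P) {
  P <- abs(P)
  k <- nrow(P)
  rowterm <- sum(rowSums(P) / apply(P, 1, max) - 1)
  colterm <- sum(colSums(P) / apply(P, 2, max) - 1)
  (rowterm + colterm) / (2 * k * (k - 1))
}
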
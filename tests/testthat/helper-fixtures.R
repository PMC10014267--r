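# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_space <- function() fixture("space_small", function()
  build_source_space(n_cortex = 120, n_cerebellum = 40, seed = 1))

small_fwd <- function() fixture("fwd_small", function()
  leadfield_sphere(small_space(), montage_1020()))

# white-noise recording with the standard montage
white_rec <- function(secs = 4, rate = 256, seed = 1, sd = 1) {
  mont <- montage_1020()
  nt <- secs * rate
  with_seed(seed, {
    eeg_recording(matrix(stats::rnorm(19 * nt, sd = sd), 19,
                         dimnames = list(mont$name, NULL)),
                  rate, mont$name, montage = mont)
  })
}

# two-channel recording carrying the same signal, for filter tests
two_chan <- function(x, rate) {
  eeg_recording(rbind(a = x, b = x), rate, c("a", "b"))
}

with_seed <- gaitsource:::with_seed

# independent step-up BH oracle
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# brute-force paired max-t sign-flip threshold over all 2^S patterns
perm_thr_brute <- function(D, alpha = 0.05) {
  S <- nrow(D)
  tfun <- function(d) {
    m <- colMeans(d); s <- apply(d, 2, stats::sd)
    m / (s / sqrt(nrow(d)))
  }
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), S)))
  mx <- apply(g, 1, function(s) max(abs(tfun(D * s))))
  stats::quantile(mx, 1 - alpha, type = 1, names = FALSE)
}

# continuous signal whose value is a pure function of gait phase
phase_locked_signal <- function(events, nt, rate, fn) {
  t <- (seq_len(nt) - 1) / rate
  rhs <- events$time_s[events$label == "RHS"]
  lhs <- events$time_s[events$label == "LHS"]
  x <- numeric(nt)
  for (i in seq_len(length(rhs) - 1)) {
    sel <- which(t >= rhs[i] & t < rhs[i + 1])
    il <- lhs[lhs > rhs[i] & lhs < rhs[i + 1]]
    if (length(il) != 1) next
    ph <- gaitsource:::stride_phase(t[sel], rhs[i], il, rhs[i + 1])
    x[sel] <- fn(ph)
  }
  x
}
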
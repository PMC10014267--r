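rate <- 256

test_that("Morlet TFD peaks at the stimulus frequency and is linear", {
  t <- (0:(20 * 2 * rate - 1)) / rate
  x <- sin(2 * pi * 10 * t)
  tf <- tfd(rbind(a = x, b = 2 * x), freqs = c(4, 10, 25), rate = rate)
  expect_identical(dim(tf$coeffs), c(2L, 3L, 20L))
  for (e in seq_len(20))
    expect_identical(which.max(Mod(tf$coeffs[1, , e])), 2L)
  # linearity: doubled amplitude doubles magnitude, phase unchanged
  expect_equal(Mod(tf$coeffs[2, , ]), 2 * Mod(tf$coeffs[1, , ]),
               tolerance = 1e-12)
  expect_equal(Arg(tf$coeffs[2, , ]), Arg(tf$coeffs[1, , ]), tolerance = 1e-9)
})

test_that("a chirp's ridge frequency increases monotonically", {
  t <- (0:(40 * 2 * rate - 1)) / rate
  T <- max(t)
  x <- sin(2 * pi * (5 * t + (15 / (2 * T)) * t^2))   # 5 -> 20 Hz
  tf <- tfd(rbind(a = x), freqs = seq(4, 24, by = 1), rate = rate)
  ridge <- apply(Mod(tf$coeffs[1, , ]), 2, which.max)
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[40] - ridge[1], 10)
})

test_that("unresolvable low frequencies are refused", {
  x <- rnorm(10 * 2 * rate)
  expect_error(tfd(rbind(a = x), freqs = c(0.5, 10), rate = rate),
               "unresolvable")
})

test_that("PLV is 1 for identical signals and any constant lag", {
  t <- (0:(30 * 2 * rate - 1)) / rate
  x <- sin(2 * pi * 10 * t + 2 * pi * rep(runif(30), each = 2 * rate))
  tf <- tfd(rbind(a = x, b = x), freqs = c(10), rate = rate)
  expect_equal(plv(tf, "a", "b")$plv[1, 1, 1], 1, tolerance = 1e-12)

  lag <- 1 / (8 * 10)       # pi/4 at 10 Hz
  sh <- round(lag * rate)
  y <- c(rep(0, sh), x[1:(length(x) - sh)])
  tf2 <- tfd(rbind(a = x, b = y), freqs = c(10), rate = rate)
  expect_equal(plv(tf2, "a", "b")$plv[1, 1, 1], 1, tolerance = 1e-3)
  expect_error(plv(tfd(rbind(a = x[1:(2 * rate)], b = x[1:(2 * rate)]),
                       freqs = 10, rate = rate), "a", "b"), ">= 2 epochs")
})

test_that("null PLV matches the Monte-Carlo mean of random phasors", {
  K <- 40
  with_seed(31, {
    # brute-force oracle: |mean of K unit phasors| over many replicates
    oracle <- mean(replicate(3000, Mod(mean(exp(2i * pi * runif(K))))))
    # package path: independent white noise on both channels
    reps <- replicate(60, {
      X <- matrix(rnorm(2 * K * 2 * rate), 2)
      rownames(X) <- c("a", "b")
      plv(tfd(X, freqs = c(8), rate = rate), "a", "b")$plv[1, 1, 1]
    })
    expect_lt(abs(mean(reps) - oracle) / oracle, 0.05)
  })
})

test_that("ImCoh vanishes for zero-lag mixtures and flags real lags", {
  with_seed(32, {
    s <- rnorm(50 * 2 * rate)
    tf <- tfd(rbind(a = 3.2 * s, b = -1.4 * s), freqs = c(5, 12), rate = rate)
    ic <- imcoh(tf, c("a", "b"))
    expect_lt(max(abs(ic$imcoh[1, 2, ])), 1e-8)     # a-b pair
    expect_identical(max(abs(ic$imcoh[1, 1, ])), 0) # self pair

    # quarter-cycle lag at 10 Hz: |ImCoh| ~ coherence ~ 1
    t <- (0:(50 * 2 * rate - 1)) / rate
    x <- sin(2 * pi * 10 * t + 2 * pi * rep(runif(50), each = 2 * rate))
    sh <- round(rate / (4 * 10))
    y <- c(rep(0, sh), x[1:(length(x) - sh)])
    tf2 <- tfd(rbind(a = x, b = y), freqs = c(10), rate = rate)
    ic2 <- imcoh(tf2, c("a", "b"))
    expect_gt(abs(ic2$imcoh[1, 2, 1]), 0.95)
    # antisymmetry
    expect_equal(ic2$imcoh[1, 2, 1], -ic2$imcoh[2, 1, 1], tolerance = 1e-12)
  })
})

test_that("PLV and ImCoh respect their bounds on random inputs", {
  with_seed(33, {
    for (i in 1:5) {
      X <- matrix(rnorm(19 * 10 * 2 * rate, sd = runif(1, 0.1, 10)), 19)
      rownames(X) <- montage_1020()$name
      tf <- tfd(X, freqs = c(3, 9, 21), rate = rate)
      p <- plv(tf)$plv
      expect_true(all(p >= 0 & p <= 1 + 1e-12))
      ic <- imcoh(tf)$imcoh
      expect_true(all(abs(ic) <= 1 + 1e-12))
    }
  })
})

test_that("spherical splines reproduce constants and low-order fields", {
  mont <- montage_1020()
  nt <- 50
  mk <- function(vals) {
    eeg_recording(vals %o% rep(1, nt) + 0, rate, mont$name, montage = mont)
  }
  out <- spherical_spline_interpolate(mk(rep(5, 19)))
  expect_lt(max(abs(out - 5)), 1e-10)

  # order-1 spherical harmonic field, analytic values at O1/O2
  pos <- as.matrix(mont[, c("x", "y", "z")])
  field <- 2 * pos[, 3] + pos[, 1]
  out1 <- spherical_spline_interpolate(mk(field))
  truth <- field[match(c("O1", "O2"), mont$name)]
  expect_lt(max(abs(out1[, 1] - truth)) / max(abs(truth)), 0.02)

  # linearity in the data
  f2 <- pos[, 2] - 0.5 * pos[, 3]
  o_a <- spherical_spline_interpolate(mk(field))
  o_b <- spherical_spline_interpolate(mk(f2))
  o_ab <- spherical_spline_interpolate(mk(2 * field + 3 * f2))
  expect_equal(o_ab, 2 * o_a + 3 * o_b, tolerance = 1e-9)

  # interpolating at a position occupied by a source electrode returns it
  mont2 <- mont
  mont2[mont2$name == "O1", c("x", "y", "z")] <-
    mont2[mont2$name == "Pz", c("x", "y", "z")]
  rec2 <- eeg_recording(field %o% rep(1, nt), rate, mont$name, montage = mont2)
  out2 <- spherical_spline_interpolate(rec2, targets = "O1")
  expect_equal(unname(out2[1, 1]), unname(field[mont$name == "Pz"]),
               tolerance = 1e-4)
})

test_that("PLV difference separates volume conduction from local sources", {
  mont <- montage_1020()
  sp <- small_space()
  fwd <- small_fwd()
  K <- 150
  nt <- K * 2 * rate
  t <- (0:(nt - 1)) / rate
  with_seed(34, {
    ci <- sample(which(sp$surface == "cortex"), 8)
    X <- fwd$leadfield[, ci] %*% matrix(rnorm(8 * nt), 8) * 5
    dimnames(X) <- list(fwd$channel_names, NULL)
    o12 <- match(c("O1", "O2"), rownames(X))

    # null: targets are exactly the interpolable cortical field + sensor noise
    rec0 <- eeg_recording(X + matrix(rnorm(19 * nt, sd = 0.02 * sd(X)), 19),
                          rate, fwd$channel_names, montage = mont)
    interp <- spherical_spline_interpolate(rec0)
    X0 <- rec0$data
    X0[o12, ] <- interp + matrix(rnorm(2 * nt, sd = 0.02 * sd(X)), 2)
    d0 <- plv_difference(eeg_recording(X0, rate, fwd$channel_names,
                                       montage = mont),
                         freqs = exp(seq(log(4), log(30), length.out = 8)))
    expect_lt(max(abs(d0$dplv)), 0.05)

    # planted independent lagged oscillation on O1/O2 only
    f0 <- 10; ph <- 2 * pi * rep(runif(K), each = 2 * rate)
    a <- 2 * sd(X)
    X1 <- X
    X1[o12[1], ] <- X1[o12[1], ] + a * sin(2 * pi * f0 * t + ph)
    X1[o12[2], ] <- X1[o12[2], ] + a * sin(2 * pi * f0 * (t - 0.02) + ph)
    d1 <- plv_difference(eeg_recording(X1, rate, fwd$channel_names,
                                       montage = mont),
                         freqs = exp(seq(log(4), log(30), length.out = 8)))
    fi <- which.min(abs(d1$freqs - f0))
    expect_gt(d1$dplv["O1", "O2", fi], 0.1)
  })
})

test_that("zero signal errors out rather than returning silent zeros", {
  mont <- montage_1020()
  rec <- eeg_recording(matrix(0, 19, 4 * rate,
                              dimnames = list(mont$name, NULL)),
                       rate, mont$name, montage = mont)
  expect_error(plv_difference(rec, freqs = c(10)), "zero")
})
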
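rate <- 512
tt <- (0:(12 * rate - 1)) / rate
mid <- (4 * rate):(8 * rate)   # away from filter edge effects

test_that("band-pass preserves the passband and kills drift and DC", {
  r100 <- bandpass_fir(two_chan(sin(2 * pi * 100 * tt), rate), 1, 200, 7500)
  expect_lt(abs(max(abs(r100$data[1, mid])) - 1), 0.01)

  rdrift <- bandpass_fir(two_chan(sin(2 * pi * 0.1 * tt), rate), 1, 200, 7500)
  expect_lt(20 * log10(max(abs(rdrift$data[1, mid]))), -40)

  roff <- bandpass_fir(two_chan(sin(2 * pi * 20 * tt) + 7, rate), 1, 200, 7500)
  expect_lt(abs(mean(roff$data[1, mid])), 1e-3)
})

test_that("band-pass is zero-phase: impulse response is symmetric in place", {
  x <- numeric(length(tt)); x[6 * rate] <- 1
  h <- bandpass_fir(two_chan(x, rate), 1, 200, 7500)$data[1, ]
  pk <- which.max(abs(h))
  expect_equal(pk, 6 * rate)
  win <- 1500
  # symmetric about the input sample (the DC-removal leaves a ~1e-8 floor)
  expect_lt(max(abs(h[(pk - win):(pk + win)] - rev(h[(pk - win):(pk + win)]))),
            1e-6)
})

test_that("filter order must accommodate the transition band", {
  rec <- two_chan(sin(2 * pi * 10 * tt), rate)
  expect_error(bandpass_fir(rec, 1, 200, 500), "need >= 1690")
  expect_error(bandpass_fir(rec, 1, 300, 7500), "Nyquist")
})

test_that("notch removes mains and preserves the neighbourhood", {
  r50 <- notch_fir(two_chan(sin(2 * pi * 50 * tt), rate), 50, 3302)
  expect_lt(max(abs(r50$data[1, mid])), 0.01)
  for (f in c(45, 55)) {
    rf <- notch_fir(two_chan(sin(2 * pi * f * tt), rate), 50, 3302)
    expect_lt(abs(max(abs(rf$data[1, mid])) - 1), 0.05)
  }
  r10 <- notch_fir(two_chan(sin(2 * pi * 10 * tt), rate), 50, 3302)
  expect_lt(abs(max(abs(r10$data[1, mid])) - 1), 0.01)
})

test_that("simulated mains is pushed below the noise floor by the notch", {
  fwd <- small_fwd()
  sc <- sim_scenario(n_epochs = 6, rate = 512, noise_sd = 1, line_hz = 50,
                     line_amp_uv = 30, seed = 8)
  rec <- simulate_eeg(sc, fwd)
  spec_at <- function(r, f) {
    x <- r$data[1, ]
    Mod(sum(x * exp(-2i * pi * f * (seq_along(x) - 1) / r$rate))) / length(x)
  }
  before <- spec_at(rec, 50)
  after <- spec_at(notch_fir(rec, 50, 3302), 50)
  floor_est <- spec_at(rec, 40)
  expect_gt(before, 30 * floor_est)
  expect_lt(after, 3 * floor_est)
})

test_that("filtering is linear to numerical precision", {
  x <- sin(2 * pi * 5 * tt); y <- sin(2 * pi * 37 * tt + 1)
  fy <- function(v) bandpass_fir(two_chan(v, rate), 1, 200, 2000)$data[1, ]
  expect_equal(fy(2 * x + 3 * y), 2 * fy(x) + 3 * fy(y), tolerance = 1e-10)
})

test_that("common average zeroes the channel mean exactly once", {
  rec <- white_rec(secs = 1, rate = 256, seed = 6)
  car <- common_average(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-12)
  expect_identical(car$reference, "common_average")
  expect_error(common_average(car), "already referenced")

  # a common offset on all channels is removed, nothing else changes
  rec2 <- rec; rec2$data <- rec$data + 100
  car2 <- common_average(rec2)
  expect_equal(car2$data, car$data, tolerance = 1e-12)
})

test_that("epoch rejection drops spikes and flatlines, order-invariantly", {
  fwd <- small_fwd()
  sc <- sim_scenario(n_epochs = 12, rate = 128, noise_sd = 5, line_hz = 0,
                     seed = 10)
  ev <- simulate_gait_events(sc)
  rec <- simulate_eeg(sc, fwd, ev)
  ge <- extract_strides(rec, ev)
  ge$epochs[[2]][3, 10] <- 500     # spike
  ge$epochs[[5]][1, ] <- 0.01      # flat channel
  suppressMessages(kept <- reject_epochs(ge, 200, 0.5))
  expect_identical(n_epochs(kept), n_epochs(ge) - 2L)
  suppressMessages(all_kept <- reject_epochs(ge, Inf, 0))
  expect_identical(n_epochs(all_kept), n_epochs(ge))

  # permuting epoch order permutes, never changes, the survivor set
  perm <- sample(n_epochs(ge))
  gep <- gaitsource:::subset_gait_epochs(ge, perm)
  suppressMessages(keptp <- reject_epochs(gep, 200, 0.5))
  expect_setequal(keptp$landmarks[, 1], kept$landmarks[, 1])
  expect_error(suppressMessages(reject_epochs(ge, 0.0001, 0)), "all 12 epochs")
})

test_that("preprocessing a noiseless rank-1 simulation preserves rank 1", {
  fwd <- small_fwd()
  src <- planted_source(20, c("Q2", "Q3"), waveform = "sinusoid", freq_hz = 12)
  sc <- sim_scenario(n_epochs = 6, rate = 512, sources = list(src),
                     noise_sd = 0, line_hz = 0, seed = 2)
  rec <- simulate_eeg(sc, fwd)
  out <- notch_fir(bandpass_fir(rec, 1, 200, 7500), 50, 3302)
  sv <- svd(out$data)$d
  expect_lt(sv[2], 1e-6 * sv[1])
})
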
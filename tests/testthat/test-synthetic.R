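test_that("zero-jitter gait events follow the closed form", {
  sc <- sim_scenario(n_epochs = 10, stride_s = 1.1, stride_jitter_frac = 0,
                     lhs_jitter_frac = 0, start_s = 0, seed = 1)
  ev <- simulate_gait_events(sc)
  rhs <- ev$time_s[ev$label == "RHS"]
  lhs <- ev$time_s[ev$label == "LHS"]
  expect_length(rhs, 11)
  expect_equal(rhs, seq(0, 11, by = 1.1), tolerance = 1e-12)
  expect_equal(lhs, seq(0.55, 10.45, by = 1.1), tolerance = 1e-12)
})

test_that("event simulation is deterministic and matches its nominal jitter", {
  sc <- sim_scenario(n_epochs = 500, stride_s = 1.1, stride_jitter_frac = 0.05,
                     seed = 42)
  ev1 <- simulate_gait_events(sc)
  ev2 <- simulate_gait_events(sc)
  expect_identical(ev1, ev2)
  dur <- diff(ev1$time_s[ev1$label == "RHS"])
  expect_lt(abs(sd(dur) - 0.05 * 1.1) / (0.05 * 1.1), 0.2)
  expect_lt(abs(mean(dur) - 1.1), 0.02)
})

test_that("noiseless simulation is zero without sources and rank-1 with one", {
  fwd <- small_fwd()
  sc0 <- sim_scenario(n_epochs = 5, rate = 128, noise_sd = 0, line_hz = 0,
                      seed = 1)
  rec0 <- simulate_eeg(sc0, fwd)
  expect_true(all(rec0$data == 0))

  src <- planted_source(7, c("Q2", "Q3"), waveform = "sinusoid", freq_hz = 6)
  sc1 <- sim_scenario(n_epochs = 5, rate = 128, sources = list(src),
                      noise_sd = 0, line_hz = 0, seed = 1)
  rec1 <- simulate_eeg(sc1, fwd)
  sv <- svd(rec1$data)$d
  expect_lt(sv[2], 1e-10 * sv[1])
  # every channel is an exact scalar multiple of the lead-field column
  expect_equal(unname(rec1$data / fwd$leadfield[, 7]),
               matrix(rec1$data[1, ] / fwd$leadfield[1, 7], 19,
                      ncol(rec1$data), byrow = TRUE),
               tolerance = 1e-9)
})

test_that("forward simulation is linear in the source amplitude", {
  fwd <- small_fwd()
  mk <- function(a) {
    src <- planted_source(12, "Q2", amplitude = a, waveform = "sinusoid")
    sc <- sim_scenario(n_epochs = 4, rate = 128, sources = list(src),
                       noise_sd = 0, line_hz = 0, seed = 5)
    simulate_eeg(sc, fwd)$data
  }
  expect_equal(mk(3), 3 * mk(1), tolerance = 1e-12)
})

test_that("a cerebellar Q2/Q3 source raises posterior scalp power in Q2+Q3", {
  space <- small_space()
  fwd <- small_fwd()
  cb <- which(space$surface == "cerebellum")
  src <- planted_source(cb[5], c("Q2", "Q3"), waveform = "sinusoid",
                        freq_hz = 10)
  sc <- sim_scenario(n_epochs = 30, rate = 256, sources = list(src),
                     noise_sd = 0, line_hz = 0, seed = 9)
  ev <- simulate_gait_events(sc)
  rec <- simulate_eeg(sc, fwd, ev)
  w <- time_warp(extract_strides(rec, ev), 200)
  sl <- quartile_slices(w)
  post <- match(c("O1", "O2", "T5", "T6"), rec$channel_names)
  pw <- vapply(sl, function(idx) mean(w$epochs[post, idx, ]^2), 0)
  expect_gt(pw["Q2"] + pw["Q3"], 5 * (pw["Q1"] + pw["Q4"]))
})

test_that("vertex ids outside the source space are rejected", {
  fwd <- small_fwd()
  src <- planted_source(10000, "Q1")
  sc <- sim_scenario(n_epochs = 2, rate = 128, sources = list(src), seed = 1)
  expect_error(simulate_eeg(sc, fwd), "outside source space")
})

test_that("simulated clinical tables are reproducible and calibrated", {
  t1 <- simulate_clinical(10, seed = 3)
  t2 <- simulate_clinical(10, seed = 3)
  expect_identical(t1, t2)

  # zero effects: between-group Mann-Whitney on deltas has ~5% type-I rate
  deltas_of <- function(tab, m = "FGA") {
    d <- as.data.frame(tab)
    d <- d[d$measure == m, ]
    pre <- d[d$timepoint == "TPRE", ]
    post <- d[d$timepoint == "TPOST", ]
    post <- post[match(pre$subject_id, post$subject_id), ]
    split(post$value - pre$value, pre$group)
  }
  nrep <- 400
  rej <- vapply(seq_len(nrep), function(i) {
    dl <- deltas_of(simulate_clinical(12, seed = 1000 + i))
    suppressWarnings(stats::wilcox.test(dl$NMT, dl$nonNMT,
                                        exact = FALSE)$p.value) < 0.05
  }, TRUE)
  ci <- 1.96 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), ci + 0.01)

  # a large NMT-only shift is detected in > 95% of replicates
  hits <- vapply(seq_len(100), function(i) {
    tab <- simulate_clinical(12, effects = list(FGA = c(NMT = 8, nonNMT = 0)),
                             seed = 2000 + i)
    dl <- deltas_of(tab)
    suppressWarnings(stats::wilcox.test(dl$NMT, dl$nonNMT,
                                        exact = FALSE)$p.value) < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
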
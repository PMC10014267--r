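test_that("wMNE with zero depth weighting reduces to classical MNE", {
  fwd <- small_fwd()
  inv <- make_inverse(fwd, "wMNE", reg_lambda = 0.1, depth_gamma = 0)
  L <- fwd$leadfield
  A <- tcrossprod(L)
  lam2 <- 0.1^2 * mean(diag(A))
  kernel <- t(L) %*% MASS::ginv(A + lam2 * diag(nrow(L)))
  expect_lt(max(abs(inv$kernel - kernel)), 1e-10 * max(abs(kernel)))
})

test_that("eLORETA localizes every vertex exactly; wMNE misses deep ones", {
  sp <- small_space()
  fwd <- small_fwd()
  inv <- make_inverse(fwd, "eLORETA", reg_lambda = 1e-8)
  est <- abs(inv$kernel %*% fwd$leadfield)
  hit <- max.col(t(est), ties.method = "first")
  expect_identical(sum(hit != seq_len(ncol(est))), 0L)

  invw <- make_inverse(fwd, "wMNE", reg_lambda = 1e-8)
  hitw <- max.col(t(abs(invw$kernel %*% fwd$leadfield)), ties.method = "first")
  cb <- which(sp$surface == "cerebellum")
  expect_gt(sum(hitw[cb] != cb), 0)
})

test_that("inverse kernels are scale-covariant in the lead field", {
  fwd <- small_fwd()
  fwd2 <- fwd; fwd2$leadfield <- 10 * fwd$leadfield
  for (m in c("wMNE", "eLORETA")) {
    k1 <- make_inverse(fwd, m, reg_lambda = 0.05)$kernel
    k2 <- make_inverse(fwd2, m, reg_lambda = 0.05)$kernel
    expect_equal(k2, k1 / 10, tolerance = 1e-8)
  }
})

test_that("apply_inverse is linear, channel-checked, and exact on rank-1 data", {
  fwd <- small_fwd()
  inv <- make_inverse(fwd, "eLORETA", reg_lambda = 1e-6)
  x <- matrix(rnorm(19 * 40), 19, dimnames = list(fwd$channel_names, NULL))
  expect_equal(apply_inverse(inv, 3 * x), 3 * apply_inverse(inv, x),
               tolerance = 1e-12)
  expect_true(all(apply_inverse(inv, 0 * x) == 0))
  bad <- x; rownames(bad) <- rev(rownames(x))
  expect_error(apply_inverse(inv, bad), "channel order")

  # noiseless planted source: estimated time course at the true vertex
  # correlates > 0.99 with the planted waveform
  src <- planted_source(25, c("Q2", "Q3"), waveform = "sinusoid", freq_hz = 8)
  sc <- sim_scenario(n_epochs = 8, rate = 256, sources = list(src),
                     noise_sd = 0, line_hz = 0, seed = 3)
  ev <- simulate_gait_events(sc)
  rec <- simulate_eeg(sc, fwd, ev)
  w <- time_warp(extract_strides(rec, ev), 200)
  s <- apply_inverse(inv, w)
  planted <- w$epochs[1, , 1] / fwd$leadfield[1, 25]  # source waveform
  expect_gt(abs(cor(s[25, , 1], planted)), 0.99)
})

test_that("z-score maps match the closed-form shifted-baseline expectation", {
  V <- 20; n <- 400; S <- 30; G <- 40
  with_seed(8, {
    base_mu <- matrix(rnorm(V * n, mean = 10, sd = 1), V, n)
    baseline <- array(rep(base_mu, each = 1), c(V, 1, n))[, rep(1, S), , drop = FALSE]
    act_mu <- matrix(rnorm(V * n, mean = 12, sd = 1), V, n)   # +2 sd shift
    active <- array(rep(act_mu, each = 1), c(V, 1, n))[, rep(1, G), , drop = FALSE]
    zm <- zscore_maps(active, baseline, summary = "signed")
    expect_equal(mean(zm$z), 2 * sqrt(n), tolerance = 0.1)
    # "sd" convention: z ~ 2, independent of n
    zm2 <- zscore_maps(active, baseline, convention = "sd", summary = "signed")
    expect_equal(mean(zm2$z), 2, tolerance = 0.1)

    # identical distributions: z centered on zero
    act0 <- array(rep(matrix(rnorm(V * n, 10, 1), V, n), each = 1),
                  c(V, 1, n))[, rep(1, G), , drop = FALSE]
    z0 <- zscore_maps(act0, baseline, summary = "signed")
    expect_lt(abs(mean(z0$z)), 0.5)
    expect_lt(mean(abs(z0$z)) , 3)
  })
})

test_that("z-score maps of pure noise are centered near zero", {
  V <- 500; n <- 500; S <- 40; G <- 40
  with_seed(17, {
    active <- array(rnorm(V * G * n), c(V, G, n))
    baseline <- array(rnorm(V * S * n), c(V, S, n))
    zm <- zscore_maps(active, baseline, convention = "sd")
    expect_lt(mean(abs(rowMeans(zm$z))), 0.1)
    zsem <- zscore_maps(active, baseline, convention = "sem")
    expect_lt(abs(mean(zsem$z)), 0.5)   # unbiased; spread grows with n
    expect_error(zscore_maps(active, baseline * 0 + 1), "zero baseline sd")
  })
})

test_that("a planted cerebellar Q2/Q3 source peaks in Q2 or Q3", {
  sp <- small_space()
  fwd <- small_fwd()
  cb <- which(sp$surface == "cerebellum")
  src <- planted_source(cb[7], c("Q2", "Q3"), waveform = "sinusoid",
                        freq_hz = 10)
  sc <- sim_scenario(n_epochs = 300, rate = 128, sources = list(src),
                     snr = 0.5, line_hz = 0, seed = 23)
  ev <- simulate_gait_events(sc)
  rec <- common_average(simulate_eeg(sc, fwd, ev))
  ge <- extract_strides(rec, ev)
  w <- time_warp(ge, 40)
  inv <- make_inverse(fwd, "eLORETA", reg_lambda = 0.05)
  s <- apply_inverse(inv, w, vertices = cb)
  b <- baseline_source_means(inv, ge$baseline, vertices = cb)
  zm <- zscore_maps(s, b, phase = w$phase)
  expect_true(which.max(colMeans(zm$z)) %in% c(2, 3))
})

test_that("paired t-maps match the textbook formula and its symmetries", {
  A <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  expect_true(all(paired_t_maps(A, A) == 0))

  B <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  t1 <- paired_t_maps(A, B)
  # hand-computed paired t at one voxel
  d <- A[, 2, 3] - B[, 2, 3]
  expect_equal(t1[2, 3], mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  # antisymmetry
  expect_equal(paired_t_maps(B, A), -t1, tolerance = 1e-12)
  expect_error(paired_t_maps(A[1, , , drop = FALSE], B[1, , , drop = FALSE]),
               ">= 2 subjects")
})

test_that("ROI time courses pick the planted vertex and break ties low", {
  sp <- small_space()
  fwd <- small_fwd()
  par_l <- which(sp$region == "parietal_L")
  v0 <- par_l[3]
  src <- planted_source(v0, c("Q1", "Q2", "Q3", "Q4"), waveform = "sinusoid",
                        freq_hz = 6)
  sc <- sim_scenario(n_epochs = 6, rate = 256, sources = list(src),
                     noise_sd = 0, line_hz = 0, seed = 4)
  ev <- simulate_gait_events(sc)
  rec <- simulate_eeg(sc, fwd, ev)
  w <- time_warp(extract_strides(rec, ev), 200)
  inv <- make_inverse(fwd, "eLORETA", reg_lambda = 1e-8)
  s <- apply_inverse(inv, w)
  avg <- apply(abs(s), c(1, 2), mean)
  roi <- roi_timecourse(avg, sp)
  expect_identical(unname(roi$vertex_chosen["parietal_L"]), v0)
  # all-zero data: lowest vertex index per ROI
  roi0 <- roi_timecourse(avg * 0, sp)
  expect_identical(unname(roi0$vertex_chosen["parietal_L"]), par_l[1])
  expect_error(roi_timecourse(avg, sp, regions = "thalamus"), "empty ROI")
})
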
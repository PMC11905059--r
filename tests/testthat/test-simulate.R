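test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_channels = 30, n_shanks = 4), "divisible")
  expect_error(simulation_config(pre_s = 0), "strictly positive")
  expect_error(simulation_config(orientations = c(0, 45, 45)), "distinct")
  expect_error(coupling_spec("PAC", "H", "theta", 0.5), "below")
  expect_error(coupling_spec("PAC", "theta", "H", 0.8,
                             stimulus_gain = c(LG = 2, CG = 1)), "\\[0, 1\\]")
  expect_error(coupling_spec("PAC", "theta", "zeta", 0.5), "unknown band")
  expect_error(
    simulation_config(coupling_specs = list(coupling_spec(
      "PAC", "theta", "H", 0.5, stimulus_gain = c(XX = 1)))),
    "stimulus_gain")
})

test_that("the same seed and config reproduce the session exactly", {
  cfg <- quick_config(n_trials_per_condition = 1, seed = 77)
  b1 <- generate_session(cfg)
  b2 <- generate_session(cfg)
  expect_identical(b1$signal, b2$signal)
  expect_identical(b1$events, b2$events)
  # and byte-identical on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  for (f in c("signal.f32", "metadata.json", "events.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  b3 <- generate_session(quick_config(n_trials_per_condition = 1, seed = 78))
  expect_false(identical(b1$signal, b3$signal))
})

test_that("event table covers every condition with in-bounds ordered onsets", {
  cfg <- quick_config(n_trials_per_condition = 2, seed = 3)
  b <- generate_session(cfg)
  ev <- b$events
  expect_equal(nrow(ev), 8 * 2 * 2)
  expect_true(all(diff(ev$onset_sample) > 0))
  counts <- table(ev$orientation_deg, ev$stimulus_type)
  expect_true(all(counts == 2))
  fs <- cfg$sampling_rate
  expect_true(all(ev$onset_sample - 0.5 * fs >= 0))
  expect_true(all(ev$onset_sample + 2.5 * fs <= ncol(b$signal)))
})

test_that("1/f background spectral density decreases across bands", {
  cfg <- quick_config(n_trials_per_condition = 1, background_exponent = 1,
                      noise_sd = 0, seed = 9)
  b <- generate_session(cfg)
  x <- b$signal[1, ]
  bands <- canonical_bands()
  # band power per Hz of bandwidth: monotone for any positive 1/f exponent
  # (band-integrated power is not, since bandwidths grow with frequency)
  dens <- vapply(seq_len(nrow(bands)), function(i)
    mean(bandpass_filter(x, bands$label[i], cfg$sampling_rate)^2) /
      (bands$high[i] - bands$low[i]), numeric(1))
  expect_true(all(diff(dens) < 0))
})

test_that("injected PAC is orientation-tuned: preferred beats orthogonal", {
  cfg <- simulation_config(
    n_channels = 4, n_shanks = 1, n_trials_per_condition = 30,
    orientations = c(90, 270), stimulus_types = "LG",
    coupling_specs = list(coupling_spec("PAC", "theta", "H", 0.6,
                                        preferred_orientation = 90,
                                        tuning_width = 45)),
    seed = 21)
  ct <- coupling_table(preprocess_session(generate_session(cfg)))
  th <- ct[ct$kind == "PAC" & ct$low_band == "theta" & ct$high_band == "H", ]
  m <- tapply(th$value, th$orientation_deg, mean)
  expect_gt(m[["90"]], m[["270"]])
})

test_that("estimated PAC increases with injected modulation depth", {
  mean_pac <- vapply(c(0, 0.25, 0.5, 0.75), function(m) {
    specs <- if (m > 0)
      list(coupling_spec("PAC", "theta", "H", m)) else list()
    cfg <- simulation_config(n_channels = 4, n_shanks = 1,
                             n_trials_per_condition = 30,
                             orientations = 0, stimulus_types = "LG",
                             coupling_specs = specs, seed = 31)
    ct <- coupling_table(preprocess_session(generate_session(cfg)))
    th <- ct[ct$kind == "PAC" & ct$low_band == "theta" & ct$high_band == "H", ]
    mean(th$value)
  }, numeric(1))
  expect_true(all(diff(mean_pac) > 0))
})

test_that("without injected coupling, PAC sits inside its shuffle null", {
  cfg <- quick_config(n_trials_per_condition = 3, seed = 55)
  tt <- preprocess_session(generate_session(cfg))
  n_tr <- dim(tt$values)[1]
  bands <- tt$bands$label
  pairs <- band_pairs(tt$bands)
  # analytic signals once per (trial, band)
  amp <- phs <- array(0, c(dim(tt$values)[4], length(bands), n_tr))
  for (tr in seq_len(n_tr)) for (b in seq_along(bands)) {
    a <- analytic_signal(tt$values[tr, b, 1, ])
    amp[, b, tr] <- a$amplitude
    phs[, b, tr] <- a$phase
  }
  set.seed(1)
  n_inside <- 0
  for (i in seq_len(nrow(pairs))) {
    li <- match(pairs$low_band[i], bands)
    hi <- match(pairs$high_band[i], bands)
    M <- pac_cross_trials(phs[, li, ], amp[, hi, ])
    observed <- mean(diag(M))
    off <- M[row(M) != col(M)]
    null_means <- replicate(200, mean(sample(off, n_tr)))
    qs <- stats::quantile(null_means, c(0.025, 0.975))
    if (observed >= qs[1] && observed <= qs[2]) n_inside <- n_inside + 1
  }
  expect_gte(n_inside, ceiling(0.95 * nrow(pairs)))
})

test_that("strong flat-tuned PAC exceeds the 99th percentile of its null", {
  cfg <- simulation_config(
    n_channels = 4, n_shanks = 1, n_trials_per_condition = 16,
    orientations = c(0, 90), stimulus_types = c("LG", "CG"),
    coupling_specs = list(coupling_spec("PAC", "theta", "H", 0.9)),
    seed = 66)
  tt <- preprocess_session(generate_session(cfg))
  n_tr <- dim(tt$values)[1]
  n_time <- dim(tt$values)[4]
  phs <- amp <- matrix(0, n_time, n_tr)
  for (tr in seq_len(n_tr)) {
    phs[, tr] <- analytic_signal(tt$values[tr, 2, 1, ])$phase      # theta
    amp[, tr] <- analytic_signal(tt$values[tr, 7, 1, ])$amplitude  # H
  }
  # trial-shuffle null: phase of one trial against amplitude of another
  M <- pac_cross_trials(phs, amp)
  observed <- diag(M)
  set.seed(2)
  null <- sample(M[row(M) != col(M)], 200)
  thr <- stats::quantile(null, 0.99)
  expect_gte(mean(observed > thr), 0.9)
})

test_that("injected AAC reproduces the target envelope correlation", {
  cfg <- simulation_config(
    n_channels = 4, n_shanks = 1, n_trials_per_condition = 30,
    orientations = 0, stimulus_types = c("LG", "CG"),
    coupling_specs = list(coupling_spec("AAC", "beta", "H", 0.7)),
    seed = 44)
  b <- generate_session(cfg, keep_truth = TRUE)
  truth <- attr(b, "truth")[[1]]
  r <- vapply(truth, function(tr) cor(tr$env_low, tr$env_high), numeric(1))
  expect_lt(abs(mean(r) - 0.7), 0.05)
})
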
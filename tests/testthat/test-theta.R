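test_that("phase extraction matches the closed form of a cosine", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  x <- 50 * cos(2 * pi * 6 * t)
  ph <- extract_phase(x, fs, band = c(4, 7))
  mid <- t > 0.5 & t < 3.5
  # peak at t = 0 -> phase 0; trough at t = 1/12 -> phase 180
  true <- (360 * 6 * t) %% 360
  err <- (ph$phase_deg[mid] - true[mid] + 180) %% 360 - 180
  expect_lt(max(abs(err)), 1)
  # amplitude recovered up to the pass-band gain of the Butterworth filter
  expect_lt(abs(mean(ph$amplitude[mid]) - 50), 2.5)
  expect_error(extract_phase(x[1:100], fs), "2 s")
})

test_that("cycle segmentation counts 6 Hz cycles and excludes weak ones", {
  ss <- small_lfp_session()
  s <- ss$session
  seg <- suppressMessages(segment_cycles(s, s$trials, exclude_amp_pct = 20))
  c1 <- seg$cycles[seg$cycles$cycle >= 1, ]
  per_trial <- table(c1$trial_id)
  ins <- s$trials$trial_id[s$trials$poke_out - s$trials$poke_in >= 1.2]
  # a 1.2 s hold at 6 Hz leaves 5-7 complete cycles after the 100 ms offset
  expect_true(all(per_trial[names(per_trial) %in% ins] %in% 5:7))
  # boundaries strictly increasing, non-overlapping within trial
  for (tid in head(unique(seg$cycles$trial_id), 5)) {
    d <- seg$cycles[seg$cycles$trial_id == tid, ]
    d <- d[order(d$cycle), ]
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$end > d$start))
  }
  seg0 <- suppressMessages(segment_cycles(s, s$trials, exclude_amp_pct = 0))
  expect_length(seg0$excluded_trials, 0)
  expect_gt(length(seg$excluded_trials), 0)
})

test_that("every in-cycle spike maps to exactly one 10-degree bin", {
  ss <- small_lfp_session()
  s <- ss$session
  seg <- suppressMessages(segment_cycles(s, s$trials))
  obs <- seg$cycles[seg$cycles$cycle == 1, ][1:10, ]
  h <- seqmem:::cycle_phase_hists(s, seg, obs)
  for (r in 1:nrow(obs)) {
    for (j in seq_along(h$neuron_ids)) {
      st <- s$neurons[[h$neuron_ids[j]]]
      n_in <- sum(st >= obs$start[r] & st < obs$end[r])
      expect_equal(sum(h$counts[r, j, ]), n_in)
    }
    # occupancy sums to the cycle duration
    expect_lt(abs(sum(h$dur[r, ]) - (obs$end[r] - obs$start[r])), 3e-3)
  }
})

test_that("trough LASSO zeroes silent neurons and decodes odors", {
  cfg <- phase_coded_config(n_neurons = 40, n_sequences = 15)
  ss <- suppressMessages(simulate_session(cfg, seed = 21))
  s <- ss$session
  s$neurons[["mute"]] <- numeric(0)           # add a silent unit
  s$tetrode_of_neuron <- c(s$tetrode_of_neuron, mute = "T1")
  seg <- suppressMessages(segment_cycles(s, s$trials))
  cls <- suppressWarnings(suppressMessages(train_trough_lasso(s, seg, seed = 1)))
  expect_true("mute" %in% cls$zero_neurons)
  tr <- suppressMessages(select_trials(s$trials, in_seq = TRUE, correct = TRUE,
                                       odors = c("B", "C")))
  dec <- decode_phase_sliding(cls, s, seg, tr, cycle_set = 1L)
  pcols <- paste0("p_", cls$classes)
  sums <- rowSums(dec[, pcols])
  expect_equal(unname(sums[is.finite(sums)]),
               rep(1, sum(is.finite(sums))), tolerance = 1e-9)
  # trough decoding recovers the presented odor above chance
  trough <- dec[dec$bin %in% 13:24, ]
  pres <- tr$odor[match(trough$trial_id, tr$trial_id)]
  m <- as.matrix(trough[, pcols])
  p_pres <- m[cbind(seq_len(nrow(trough)), match(pres, cls$classes))]
  expect_gt(mean(p_pres, na.rm = TRUE), 0.3)
})

test_that("role mapping and z-normalization preserve structure", {
  d <- data.frame(trial_id = "t001", cycle = 1, bin = c(5, 18, 30),
                  p_A = c(0.6, 0.2, 0.1), p_B = c(0.2, 0.6, 0.2),
                  p_C = c(0.1, 0.1, 0.6), p_D = c(0.1, 0.1, 0.1))
  trials <- manual_trials(1, odor = "B", position = 2)
  ro <- role_probabilities(d, trials)
  expect_equal(ro$p_past, d$p_A)
  expect_equal(ro$p_present, d$p_B)
  expect_equal(ro$p_future, d$p_C)
  expect_equal(ro$phase, c("descending", "trough", "ascending"))
  # z-normalization preserves within-role rank order
  cc <- cross_cycle_analysis(rbind(
    transform(ro, cycle = 1), transform(ro, cycle = 3),
    transform(ro, cycle = 5), transform(ro, cycle = -2)),
    cycle_set = c(-2, 1, 3, 5))
  ag <- cc$summary
  for (rl in unique(ag$role)) {
    v <- ag[ag$role == rl, ]
    expect_equal(order(v$value), order(v$z))
  }
})

test_that("circular-linear correlation has the documented properties", {
  set.seed(9)
  t <- runif(200)
  # pure precession: phase decreases 2 cycles over the trial
  phi <- (360 - 720 * t + rnorm(200, 0, 10)) %% 360
  r <- circ_lin_cor(phi, t)
  expect_lt(r$p, 0.01)
  expect_lt(r$slope_deg_per_unit, 0)
  # rotational invariance
  r2 <- circ_lin_cor((phi + 133) %% 360, t)
  expect_equal(abs(r$rho), abs(r2$rho), tolerance = 0.05)
  # constant phase: no correlation
  r0 <- circ_lin_cor(rep(90, 100) + rnorm(100, 0, 1), runif(100))
  expect_gt(r0$p, 0.05)
})

test_that("spike-phase precession statistics respect the spike threshold", {
  ss <- small_lfp_session()
  s <- ss$session
  seg <- suppressMessages(segment_cycles(s, s$trials))
  tr <- suppressMessages(select_trials(s$trials, in_seq = TRUE, correct = TRUE,
                                       odors = c("B", "C", "D")))
  pr <- suppressMessages(spike_phase_precession(s, seg, tr, min_spikes = 10))
  expect_true(all(pr$n_spikes >= 10))
  expect_true(all(pr$p >= 0 & pr$p <= 1, na.rm = TRUE))
})
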
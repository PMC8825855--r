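test_that("trial simulation respects task structure", {
  cfg <- sim_config(n_sequences = 30, p_outseq = 0, p_incorrect = 0,
                    p_incorrect_inseq = 0)
  tr <- simulate_trials(cfg, seed = 1)
  expect_true(all(tr$in_seq))
  expect_true(all(tr$correct))
  expect_equal(nrow(tr), 150)  # every sequence completes 5 positions
  expect_true(all(tr$odor[tr$position == 1] == "A"))
  # holds: InSeq correct responses exceed the 1.2 s signal
  expect_true(all(tr$poke_out - tr$poke_in >= 1.2))
  # inter-odor floor
  for (sq in unique(tr$sequence_id)) {
    d <- tr[tr$sequence_id == sq, ]
    if (nrow(d) > 1)
      expect_true(all(d$poke_in[-1] - d$poke_out[-nrow(d)] >= 0.8))
  }
})

test_that("OutSeq substitution rate matches the configured probability", {
  cfg <- sim_config(n_sequences = 400, p_outseq = 0.5, p_incorrect = 0,
                    p_incorrect_inseq = 0)
  tr <- simulate_trials(cfg, seed = 2)
  at2 <- tr[tr$position == 2, ]
  phat <- mean(!at2$in_seq)
  ci <- 3 * sqrt(0.25 / nrow(at2))
  expect_lt(abs(phat - 0.5), ci)
  # incorrect responses terminate the sequence
  cfg2 <- sim_config(n_sequences = 50, p_outseq = 0.4, p_incorrect = 1)
  tr2 <- simulate_trials(cfg2, seed = 3)
  for (sq in unique(tr2$sequence_id)) {
    d <- tr2[tr2$sequence_id == sq, ]
    expect_true(all(d$correct[-nrow(d)]))
  }
})

test_that("with modulations off, spiking is Poisson at the configured baseline", {
  cfg <- sim_config(n_neurons = 8, n_sequences = 6, peak_rate_range = c(0, 0),
                    baseline_range = c(4, 4), pretrial_gain = 0,
                    theta_frac = 0, frac_outcome = 0)
  ss <- suppressMessages(simulate_session(cfg, seed = 5, make_lfp = FALSE))
  s <- ss$session
  t_end <- max(s$trials$poke_out) + 5
  rates <- lengths(s$neurons) / t_end
  # each neuron within 4 sd of the 4 Hz target
  for (r in rates)
    expect_lt(abs(r - 4), 4 * sqrt(4 / t_end))
  # dispersion: per-window counts have variance ~ mean (Fano ~ 1)
  cnt <- window_spike_counts(s, s$trials, "poke_in", c(0, 1.2), bin = 0.1)
  fano <- var(as.numeric(cnt)) / mean(cnt)
  expect_lt(abs(fano - 1), 0.15)
})

test_that("theta-coded neurons fire at their preferred phase", {
  cfg <- sim_config(n_neurons = 10, n_sequences = 10, kappa = 8,
                    theta_frac = 1, pretrial_gain = 0,
                    role_probs = c(past = 0, present = 1, future = 0),
                    baseline_range = c(0.1, 0.1))
  ss <- suppressMessages(simulate_session(cfg, seed = 6, make_lfp = FALSE))
  s <- ss$session
  pars <- ss$truth$params
  j <- which(pars$theta_role == "present")[1]
  trj <- suppressMessages(select_trials(s$trials, odors = pars$pref_odor[j],
                                        correct = TRUE, in_seq = TRUE))
  st <- s$neurons[[pars$neuron_id[j]]]
  ph <- numeric(0)
  for (i in seq_len(nrow(trj))) {
    sp <- st[st >= trj$poke_in[i] & st < trj$poke_out[i]]
    ph <- c(ph, (360 * cfg$theta_freq * sp) %% 360)
  }
  mu <- atan2(mean(sin(ph * pi / 180)), mean(cos(ph * pi / 180))) * 180 / pi
  expect_lt(abs(((mu - 180 + 180) %% 360) - 180), 15)
})

test_that("LFP carries theta and injected ripples raise ripple-band power", {
  ss <- small_lfp_session()
  expect_equal(nrow(ss$truth$swr), 0)  # no SWRs by default
  cfg <- sim_config(n_neurons = 5, n_sequences = 3, swr_rate = 0.1)
  trl <- simulate_trials(cfg, seed = 7)
  lf <- simulate_lfp(cfg, trl, seed = 7)
  expect_gt(nrow(lf$swr_truth), 0)
  ch <- lf$lfp[[lf$roles$ripple_tetrode]]
  bf <- signal::butter(2, c(150, 250) / 500, type = "pass")
  env <- Mod(analytic_signal(signal::filtfilt(bf, ch$samples)))
  z <- (env - mean(env)) / sd(env)
  ev <- lf$swr_truth[1, ]
  i0 <- round(ev$start * 1000); i1 <- round(ev$end * 1000)
  expect_gt(max(z[i0:i1]), 3)
})

test_that("ground truth records tuning and labels without leaking into analyses", {
  ss <- small_session()
  expect_true(all(c("params", "trial_labels", "theta") %in% names(ss$truth)))
  expect_equal(nrow(ss$truth$params), 20)
  expect_setequal(ss$truth$params$neuron_id, names(ss$session$neurons))
})
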
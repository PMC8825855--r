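test_that("PSTH peaks at the firing latency and is scale invariant", {
  trl <- manual_trials(c(10, 20, 30))
  spikes <- as.numeric(outer(c(10, 20, 30), 0.5, `+`))  # one spike at +0.5 s
  s <- manual_session(list(n1 = spikes, n2 = sort(rep(spikes, 3))), trl)
  p <- suppressMessages(build_psth(s, trl, window = c(0, 1.2), smooth_sd_ms = 150))
  peak_bin <- which.max(p$rates["n1", ])
  expect_lt(abs(peak_bin - 500), 2)
  # tripling the rate (n2) leaves the normalized row unchanged
  expect_equal(p$rates["n1", ], p$rates["n2", ], tolerance = 1e-9)
  expect_equal(unname(apply(p$rates, 1, max)), c(1, 1))
  expect_error(build_psth(s, trl[0, ], c(0, 1.2)), "empty")
})

test_that("silent neurons are dropped and flat neurons smooth to near-constant", {
  trl <- manual_trials(c(10, 20))
  set.seed(1)
  flat <- sort(c(runif(600, 10, 11.2), runif(600, 20, 21.2)))
  s <- manual_session(list(n1 = flat, n2 = numeric(0)), trl)
  p <- suppressMessages(build_psth(s, trl, c(0, 1.2), smooth_sd_ms = 150))
  expect_equal(p$dropped, "n2")
  row <- p$raw["n1", ]
  # smoothing a homogeneous train: sd bounded well below the mean
  expect_lt(sd(row[200:1000]) / mean(row[200:1000]), 0.2)
})

test_that("peak sorting is a stable permutation", {
  p <- structure(list(rates = rbind(
    a = c(0, 0, 1, 0), b = c(1, 0, 0, 0), c = c(0, 1, 0, 0),
    d = c(0, 1, 0, 0))), class = "seqmem_psth")
  expect_equal(sort_by_peak(p), c("b", "c", "d", "a"))
  ord <- sort_by_peak(p)
  expect_setequal(ord, rownames(p$rates))
  peaks <- apply(p$rates[ord, ], 1, which.max)
  expect_false(is.unsorted(peaks))
})

test_that("trial PSTH correlations separate same-odor from different-odor pairs", {
  cfg <- sim_config(n_neurons = 30, n_sequences = 16, rho = 0.5,
                    peak_rate_range = c(15, 35))
  ss <- suppressMessages(simulate_session(cfg, seed = 11, make_lfp = FALSE))
  s <- ss$session
  tr <- suppressMessages(select_trials(s$trials, in_seq = TRUE, correct = TRUE))
  res <- suppressMessages(psth_similarity(s, tr, n_per_odor = 10))
  expect_gt(res$mean_same, res$mean_diff)
  expect_lt(res$same_vs_diff_p, 0.05)
  expect_lt(res$anova_p, 0.05)
  # pair table covers all pairs once, r in [-1, 1]
  expect_true(all(abs(res$pairs$r) <= 1 + 1e-12, na.rm = TRUE))
  n <- length(unique(c(res$pairs$trial_i, res$pairs$trial_j)))
  expect_equal(nrow(res$pairs), n * (n - 1) / 2)
  # identical trials correlate exactly when compared to themselves
  v <- res$pairs
  expect_error(psth_similarity(s, tr[tr$odor == "A", ][1, ], n_per_odor = 2),
               ">= 2 trials")
})
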
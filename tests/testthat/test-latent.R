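test_that("window construction yields 16 sub-windows of n_neurons x 10 bins", {
  ss <- small_session()
  s <- ss$session
  tr <- suppressMessages(select_trials(s$trials, correct = TRUE))
  w <- make_windows(s, tr, anchor = "poke_in", offset = 0)
  expect_equal(ncol(w$X), length(s$neurons) * 10)
  expect_equal(max(w$info$subwindow), 16)
  expect_equal(nrow(w$X), nrow(w$trials) * 16)
  # sub-window counts are consistent with window_spike_counts
  cnt <- window_spike_counts(s, w$trials[1, , drop = FALSE], "poke_in",
                             c(0, 0.1), bin = 0.01)
  expect_equal(w$X[1, ], as.numeric(t(matrix(cnt[1, , ], length(s$neurons)))))
  # withdrawal-anchored negative-offset windows drop too-short trials
  w2 <- suppressMessages(make_windows(s, tr, anchor = "poke_out", offset = -0.25))
  expect_lte(nrow(w2$trials), nrow(tr))
})

test_that("the autoencoder reaches near-zero error on a 2-D linear subspace", {
  set.seed(2)
  Z <- matrix(rnorm(400), 200, 2)
  A <- matrix(rnorm(2 * 30), 2, 30)
  X <- pmax(Z %*% A, 0) + 1   # nonnegative count-like data on a thin manifold
  sp <- ae_spec(30, widths = c(32, 16), epochs = 150, lr = 5e-3, batch = 32,
                seed = 4)
  ae <- train_autoencoder(X, sp)
  expect_lt(tail(ae$loss, 1), ae$loss[1])
  expect_lt(tail(ae$loss, 1), 0.35)
  expect_equal(dim(ae$latent), c(200L, 2L))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(3)
  X <- matrix(rpois(100 * 20, 1), 100, 20)
  sp <- ae_spec(20, widths = c(8, 8), epochs = 10, seed = 11)
  a1 <- train_autoencoder(X, sp)
  a2 <- train_autoencoder(X, sp)
  expect_identical(a1$latent, a2$latent)
  expect_identical(a1$loss, a2$loss)
})

test_that("held-out reconstruction error does not blow up (overfit guard)", {
  ss <- small_session()
  s <- ss$session
  tr <- suppressMessages(select_trials(s$trials, correct = TRUE))
  w <- make_windows(s, tr, offset = 0.25)
  n <- nrow(w$X)
  hold <- seq(1, n, by = 10)
  sp <- ae_spec(ncol(w$X), widths = c(32, 16), epochs = 40, seed = 5)
  ae <- train_autoencoder(w$X[-hold, ], sp)
  expect_lt(ae_mse(ae, w$X[hold, , drop = FALSE]),
            2 * ae_mse(ae, w$X[-hold, , drop = FALSE]))
})

test_that("k-NN separability flags separated clouds and honors the tie rule", {
  # two point clouds far apart: 20 trials x 16 points each
  set.seed(6)
  lab <- rep(c("x", "y"), each = 10)
  info <- data.frame(trial_id = rep(sprintf("t%02d", 1:20), each = 16),
                     subwindow = rep(1:16, 20))
  centers <- ifelse(rep(lab, each = 16) == "x", -10, 10)
  latent <- cbind(centers + rnorm(320, 0, 0.5), rnorm(320, 0, 0.5))
  labels <- setNames(lab, sprintf("t%02d", 1:20))
  kn <- knn_separability(latent, info, labels, n_perm = 50, seed = 1)
  expect_equal(kn$accuracy, 1)
  expect_true(kn$significant)
  # label shuffles stay near chance
  expect_lt(mean(kn$chance), 0.8)
})

test_that("centroids on a line give distance proportional to lag", {
  # trials of odors B-E at positions 2-5, centroids equally spaced on a line
  trials <- data.frame(trial_id = sprintf("t%d", 1:8),
                       sequence_id = "s1", position = rep(2:5, 2),
                       odor = rep(c("B", "C", "D", "E"), 2),
                       in_seq = TRUE, poke_in = 1:8, poke_out = (1:8) + 1.2,
                       correct = TRUE, stringsAsFactors = FALSE)
  info <- data.frame(trial_id = rep(trials$trial_id, each = 4),
                     subwindow = rep(1:4, 8))
  pos <- rep(match(trials$odor, c("B", "C", "D", "E")), each = 4)
  latent <- cbind(pos * 2, rep(0, 32))  # singular covariance: Euclidean path
  res <- suppressMessages(cluster_lag_distance(latent, info, trials, "inseq"))
  d <- res$pairs
  m <- tapply(d$distance, d$lag, mean)
  # strictly proportional spacing across lags 1..3 (up to covariance scaling)
  expect_equal(as.numeric(m[c("2", "3")] / m["1"]), c(2, 3), tolerance = 1e-6)
  expect_equal(as.numeric(m["0"]), 0, tolerance = 1e-6)
  expect_gt(res$trend_slope, 0)
})

test_that("the embedding never sees labels (leakage guard)", {
  ss <- small_session()
  s <- ss$session
  tr <- suppressMessages(select_trials(s$trials, correct = TRUE))
  w <- make_windows(s, tr, offset = 0)
  sp <- ae_spec(ncol(w$X), widths = c(16, 8), epochs = 5, seed = 2)
  a1 <- train_autoencoder(w$X, sp)
  shuffled <- w$trials
  shuffled$odor <- sample(shuffled$odor)   # labels changed, inputs unchanged
  a2 <- train_autoencoder(w$X, sp)
  expect_identical(a1$latent, a2$latent)
})
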
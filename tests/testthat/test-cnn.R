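test_that("decoded probability vectors are valid distributions", {
  ss <- small_lfp_session()
  s <- ss$session
  tr <- suppressMessages(select_trials(s$trials, in_seq = TRUE, correct = TRUE,
                                       odors = c("A", "B", "C", "D")))
  cnn <- train_cnn(s, tr, cnn_spec(seed = 2, epochs = 15))
  dw <- decode_windows(cnn, s, tr[1:6, ], starts = c(-0.25, 0, 0.25))
  pcols <- grep("^p_", names(dw$probs))
  expect_equal(unname(rowSums(dw$probs[, pcols])), rep(1, nrow(dw$probs)),
               tolerance = 1e-9)
  expect_true(all(dw$probs$in_sample %in% c(TRUE, FALSE)))
  # training-window trials are flagged in-sample
  expect_true(all(dw$probs$in_sample[dw$probs$trial_id %in% cnn$train_ids]))
})

test_that("training errors on a single class", {
  ss <- small_lfp_session()
  s <- ss$session
  trA <- suppressMessages(select_trials(s$trials, odors = "A"))
  expect_error(train_cnn(s, trA, cnn_spec(seed = 1, epochs = 2)), "2 odor classes")
})

test_that("latent projection is consistent and invariant to duplication", {
  set.seed(4)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), 4, 2, byrow = TRUE)
  lab <- rep(c("A", "B", "C", "D"), each = 30)
  latent <- centers[rep(1:4, each = 30), ] + matrix(rnorm(240, 0, 0.5), 120, 2)
  latent <- cbind(latent, latent %*% matrix(rnorm(4), 2, 2))  # extra dims
  lp <- latent_projection(latent, lab)
  expect_gte(lp$consistency, 0.95)
  # duplicated points project identically
  lp2 <- latent_projection(rbind(latent, latent[1:5, ]),
                           c(lab, lab[1:5]))
  expect_equal(lp2$coords[121:125, ], lp2$coords[1:5, ], tolerance = 1e-9)
})

test_that("multinomial CIs behave per the Goodman construction", {
  ci <- multinomial_ci(c(25, 25, 25, 25))
  # symmetric counts: identical intervals, all overlapping
  expect_equal(ci$lower, rep(ci$lower[1], 4))
  expect_true(all(ci$lower <= 0.25 & ci$upper >= 0.25))
  ci2 <- multinomial_ci(c(97, 1, 1, 1))
  # dominant class separated from the rest
  expect_gt(ci2$lower[1], ci2$upper[2])
  expect_error(multinomial_ci(c(0, 0)), "zero")
})

test_that("window statistics: constant probabilities give zero slope", {
  probs <- data.frame(trial_id = rep(c("t1", "t2"), each = 3),
                      window_start = rep(c(0, 0.25, 0.5), 2),
                      p_A = 0.25, p_B = 0.25, p_C = 0.25, p_D = 0.25,
                      argmax = "A", stringsAsFactors = FALSE)
  ws <- suppressWarnings(window_stats(probs, pair = c("C", "B")))
  expect_equal(unname(ws$slopes), c(0, 0))
  expect_equal(ws$slope_mean, 0)
})

test_that("CMH subject control detects heterogeneity and ignores ordering", {
  cm <- matrix(c(20, 2, 1, 1,
                 2, 20, 1, 2,
                 1, 1, 20, 2,
                 1, 2, 2, 20), 4, 4, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  same <- list(s1 = cm, s2 = cm, s3 = cm)
  r1 <- cmh_subject_control(same)
  expect_gt(r1$p, 0.9)
  # a consistently biased session (over-predicts "A" for every true odor)
  biased <- cm; biased[, 1] <- biased[, 1] + 12
  mixed <- list(s1 = cm, s2 = cm, s3 = biased)
  r2 <- cmh_subject_control(mixed)
  expect_lt(r2$p, 0.01)
  r3 <- cmh_subject_control(rev(mixed))
  expect_equal(r2$statistic, r3$statistic, tolerance = 1e-9)
  expect_error(cmh_subject_control(list(s1 = cm)), ">= 2 sessions")
})
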
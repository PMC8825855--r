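test_that("interval merging follows the 15 ms rule and is idempotent", {
  iv <- data.frame(start = c(1.000, 1.020), end = c(1.010, 1.030))
  m <- merge_intervals(iv, gap = 0.015)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1.000, 1.030))
  expect_equal(merge_intervals(m, gap = 0.015), m)
  # separations of 15 ms or more stay separate
  iv2 <- data.frame(start = c(1.000, 1.026), end = c(1.010, 1.040))
  expect_equal(nrow(merge_intervals(iv2, gap = 0.015)), 2)
})

test_that("band event detection finds injected bursts and rejects constants", {
  set.seed(12)
  fs <- 1000
  x <- rnorm(20 * fs, 0, 10)
  tt <- (seq_along(x) - 1) / fs
  for (ct in c(5, 12)) {
    w <- abs(tt - ct) < 0.05
    x[w] <- x[w] + 80 * exp(-0.5 * ((tt[w] - ct) / 0.015)^2) *
      sin(2 * pi * 200 * (tt[w] - ct))
  }
  ev <- detect_band_events(x, fs, band = c(150, 250), threshold_sd = 3)
  hit <- function(ct) any(ev$start < ct + 0.05 & ev$end > ct - 0.05)
  expect_true(hit(5) && hit(12))
  expect_error(detect_band_events(rep(1, 5000), fs), "constant")
  # threshold 0: nearly the whole trace is one event
  ev0 <- detect_band_events(x, fs, band = c(150, 250), threshold_sd = -1)
  expect_equal(nrow(ev0), 1)
})

test_that("SWR events join sharp-wave and ripple intervals by union", {
  # construct a session with one co-timed pair and one lone ripple
  fs <- 1000
  set.seed(13)
  n <- 30 * fs
  tt <- (seq_len(n) - 1) / fs
  noise <- function() rnorm(n, 0, 10)
  rip <- noise(); sw <- noise()
  add_rip <- function(x, ct) {
    w <- abs(tt - ct) < 0.05
    x[w] <- x[w] + 90 * exp(-0.5 * ((tt[w] - ct) / 0.015)^2) *
      sin(2 * pi * 200 * (tt[w] - ct)); x
  }
  add_sw <- function(x, ct) {
    w <- abs(tt - ct) < 0.1
    x[w] <- x[w] - 90 * exp(-0.5 * ((tt[w] - ct) / 0.025)^2); x
  }
  rip <- add_rip(rip, 10); sw <- add_sw(sw, 10.01)   # co-timed pair
  rip <- add_rip(rip, 20)                            # ripple alone
  trl <- manual_trials(5)
  s <- new_session("swr", list(n1 = 6.0), c(n1 = "T1"),
                   lfp = list(T1 = list(samples = noise(), t0 = 0),
                              T2 = list(samples = rip, t0 = 0),
                              T3 = list(samples = sw, t0 = 0)),
                   trials = trl,
                   meta = list(ripple_tetrode = "T2", sharpwave_tetrode = "T3"))
  ev <- detect_swr(s)
  expect_equal(nrow(ev), 1)       # overlap required: lone ripple rejected
  expect_lt(ev$start, 10.01)
  expect_gt(ev$end, 10)
  bad <- s; bad$meta$ripple_tetrode <- "T9"
  expect_error(detect_swr(bad), "missing")
})

test_that("trial exclusion matches a brute-force interval oracle", {
  trl <- manual_trials(c(10, 20, 30, 40))
  ev <- data.frame(start = c(10.5, 19.8, 41.6), end = c(10.6, 19.9, 41.7))
  res <- suppressMessages(exclude_swr_trials(trl, ev, flank = 0.25))
  # oracle: any overlap with [poke_in - .25, poke_out + .25]
  oracle <- vapply(seq_len(nrow(trl)), function(i)
    any(ev$start < trl$poke_out[i] + 0.25 & ev$end > trl$poke_in[i] - 0.25),
    logical(1))
  expect_setequal(res$removed, trl$trial_id[oracle])
  expect_equal(unname(res$report["removed"]), sum(oracle))
  # windows: event inside the odor period removes exactly that trial
  expect_true("t001" %in% res$removed)
  # pre-entry flank event removes t002; far event does not remove t004
  expect_true("t002" %in% res$removed)
  expect_false("t004" %in% res$removed)
  # no events -> identity
  none <- suppressMessages(exclude_swr_trials(trl, ev[0, ]))
  expect_equal(none$trials, trl)
})
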
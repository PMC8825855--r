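test_that("session round-trips losslessly through a directory", {
  s <- small_session()$session
  dir <- tempfile("sess")
  write_session(s, dir)
  s2 <- load_session(dir)
  expect_equal(s2$trials$poke_in, s$trials$poke_in)
  expect_equal(s2$trials$odor, s$trials$odor)
  expect_equal(names(s2$neurons), names(s$neurons))
  for (nm in names(s$neurons))
    expect_equal(s2$neurons[[nm]], s$neurons[[nm]], tolerance = 1e-12)
  expect_equal(s2$tetrode_of_neuron, s$tetrode_of_neuron)
  unlink(dir, recursive = TRUE)
})

test_that("validation rejects broken sessions", {
  s <- small_session()$session
  bad <- s
  bad$trials$poke_out[3] <- bad$trials$poke_in[3] - 0.1
  expect_error(validate_session(bad), "poke_out")
  bad2 <- s
  bad2$trials$odor[bad2$trials$position == 1][1] <- "B"
  expect_error(validate_session(bad2), "position 1")
  bad3 <- s
  bad3$neurons[[1]] <- rev(bad3$neurons[[1]])
  expect_error(validate_session(bad3), "ascending")
  expect_error(load_session(tempfile()), "missing file")
})

test_that("select_trials filters by task criteria and preserves order", {
  tr <- small_session()$session$trials
  expect_equal(suppressMessages(select_trials(tr)), tr)
  ins <- suppressMessages(select_trials(tr, in_seq = TRUE))
  expect_equal(nrow(ins), sum(tr$in_seq))
  expect_false(is.unsorted(ins$poke_in))
  pos <- suppressMessages(select_trials(tr, exclude_positions = c(1, 5)))
  expect_true(all(pos$position %in% 2:4))
  cons <- suppressMessages(select_trials(tr, consecutive_inseq = TRUE))
  for (sq in unique(cons$sequence_id)) {
    d <- tr[tr$sequence_id == sq, ]
    expect_true(nrow(d) == 5 && all(d$in_seq) && all(d$correct))
  }
  expect_warning(suppressMessages(select_trials(tr, odors = "Z")), "empty")
})

test_that("windowed counts use half-open bins and conserve spikes", {
  trl <- manual_trials(10)
  s <- manual_session(list(n1 = c(10.10, 10.30), n2 = 10.25), trl)
  cnt <- window_spike_counts(s, trl, "poke_in", c(0, 0.5), bin = 0.25)
  expect_equal(as.numeric(cnt[1, "n1", ]), c(1, 1))
  # spike exactly at a bin edge belongs to the later bin
  expect_equal(as.numeric(cnt[1, "n2", ]), c(0, 1))
  # conservation on a random fixture
  ss <- small_session()$session
  w <- window_spike_counts(ss, ss$trials, "poke_in", c(0, 1.2), bin = 0.1)
  tot <- window_spike_counts(ss, ss$trials, "poke_in", c(0, 1.2), bin = 1.2)
  expect_equal(apply(w, c(1, 2), sum), tot[, , 1])
  expect_error(window_spike_counts(s, trl, "poke_in", c(0, 0.5), bin = 0.3),
               "divide")
})

test_that("permutation streams are reproducible and correct per scheme", {
  a <- perm_stream(10, 5, seed = 7)
  b <- perm_stream(10, 5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, perm_stream(10, 5, seed = 8)))
  d <- perm_stream(6, 3, seed = 1, scheme = "downsample", size = 6)
  for (x in d) expect_setequal(x, 1:6)
  expect_error(perm_stream(5, 2, 1, scheme = "downsample", size = 6),
               "exceeds")
  # label shuffle of balanced 4-class labels: fraction matching ~ 0.25
  labs <- rep(c("A", "B", "C", "D"), each = 25)
  pr <- perm_stream(100, 400, seed = 3, scheme = "label-shuffle")
  frac <- mean(vapply(pr, function(ix) mean(labs[ix] == labs), numeric(1)))
  expect_lt(abs(frac - 0.25), 0.01)
})
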
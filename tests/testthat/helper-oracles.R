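# independent term-by-term oracle for the Poisson time posterior (includes
# the factorial terms the log-space implementation cancels)
brute_posterior <- function(N, fmat, tau, eps = 1e-3) {
  fmat <- pmax(fmat, eps)
  P <- matrix(0, nrow(N), ncol(fmat))
  for (i in seq_len(nrow(N))) {
    for (k in seq_len(ncol(fmat))) {
      v <- 1
      for (j in seq_len(nrow(fmat)))
        v <- v * (tau * fmat[j, k])^N[i, j] / factorial(N[i, j])
      P[i, k] <- v * exp(-tau * sum(fmat[, k]))
    }
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  P
}

# three-way Fig 5a contrast: descending past > future, ascending future >
# past, trough present maximal; returns the three one-sided paired p values
theta_pattern_p <- function(session, seg, classes = c("A", "B", "C", "D")) {
  cls <- suppressWarnings(suppressMessages(
    train_trough_lasso(session, seg, classes, seed = 1)))
  tr <- suppressMessages(select_trials(session$trials, in_seq = TRUE,
                                       correct = TRUE, odors = c("B", "C")))
  dec <- decode_phase_sliding(cls, session, seg, tr, cycle_set = 1L)
  ro <- role_probabilities(dec, session$trials, classes)
  ag <- stats::aggregate(cbind(p_past, p_present, p_future) ~ phase + trial_id,
                         data = ro, FUN = mean)
  de <- ag[ag$phase == "descending", ]
  asc <- ag[ag$phase == "ascending", ]
  trg <- ag[ag$phase == "trough", ]
  c(desc = t.test(de$p_past, de$p_future, paired = TRUE,
                  alternative = "greater")$p.value,
    asc = t.test(asc$p_future, asc$p_past, paired = TRUE,
                 alternative = "greater")$p.value,
    trough = t.test(trg$p_present, pmax(trg$p_past, trg$p_future),
                    paired = TRUE, alternative = "greater")$p.value)
}
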
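#' Build a peri-stimulus time histogram matrix
#'
#' Per neuron: spike counts in 1 ms bins relative to the anchor, averaged
#' across the supplied trials, Gaussian-smoothed (kernel truncated at +/- 4
#' sd, reflected boundaries) and normalized to the row's peak rate. Neurons
#' silent on all included trials are dropped and logged.
#'
#' @param session session.
#' @param trials trial table (already selected).
#' @param window c(a, b) seconds relative to `anchor`.
#' @param smooth_sd_ms Gaussian kernel sd in ms (150 for single-odor, 250 for
#'   full-sequence histograms).
#' @param anchor "poke_in" or "poke_out".
#' @return object of class `seqmem_psth`: list(rates = neuron x bin matrix
#'   normalized to row peak, raw = mean rate Hz, bin_s, window, anchor,
#'   dropped = ids of silent neurons).
#' @export
build_psth <- function(session, trials, window = c(0, 1.2), smooth_sd_ms = 150,
                       anchor = "poke_in") {
  if (nrow(trials) == 0) stop("build_psth: empty trial selection")
  cnt <- window_spike_counts(session, trials, anchor, window, bin = 0.001)
  mean_cnt <- apply(cnt, c(2, 3), mean)         # neuron x bin, counts/ms
  rate <- mean_cnt * 1000                       # Hz
  sm <- t(apply(rate, 1, gauss_smooth, sd_bins = smooth_sd_ms))
  peaks <- apply(sm, 1, max)
  silent <- peaks <= 0
  if (any(silent))
    sm_log("build_psth: dropping %d silent neurons", sum(silent))
  norm <- sm[!silent, , drop = FALSE] / peaks[!silent]
  structure(list(rates = norm, raw = sm[!silent, , drop = FALSE],
                 bin_s = 0.001, window = window, anchor = anchor,
                 smooth_sd_ms = smooth_sd_ms,
                 dropped = rownames(sm)[silent]),
            class = "seqmem_psth")
}

#' Sort neurons by peak firing latency
#'
#' Peak = argmax of the smoothed, normalized row (first bin wins among equal
#' maxima); ties in latency are broken by neuron id, so the order is stable.
#'
#' @param psth `seqmem_psth`.
#' @return character vector of neuron ids in ascending peak-latency order.
#' @export
sort_by_peak <- function(psth) {
  lat <- apply(psth$rates, 1, which.max)
  ids <- rownames(psth$rates)
  ids[order(lat, ids)]
}

#' Trial-wise PSTH correlation analysis
#'
#' Builds a single-trial PSTH per included trial (same 1 ms binning,
#' smoothing and per-neuron peak normalization as the session PSTH; neurons
#' silent on a given trial contribute a zero row), vectorizes it in canonical
#' neuron order, and computes the Pearson correlation of every trial pair.
#' Pairs are classed by their odor combination (e.g. "AA", "AB"); a one-way
#' ANOVA across classes and Dunnett-style contrasts of each same-odor class
#' against its different-odor classes (pairwise Welch t tests, Holm-adjusted)
#' are computed with standard routines.
#'
#' @param session session.
#' @param trials candidate trials (typically correct InSeq).
#' @param odors odors to include.
#' @param n_per_odor trials used per odor (the first `n_per_odor` by time;
#'   the study used 14).
#' @param window,smooth_sd_ms as in [build_psth()].
#' @return list(pairs = tidy data.frame(trial_i, trial_j, odor_i, odor_j,
#'   pair_class, same_odor, r), anova_p, mean_same, mean_diff, same_vs_diff_p,
#'   dunnett = per-odor contrast table).
#' @export
psth_similarity <- function(session, trials, odors = c("A", "B", "C", "D"),
                            n_per_odor = 14, window = c(0, 1.2),
                            smooth_sd_ms = 150) {
  sel <- do.call(rbind, lapply(odors, function(o) {
    d <- trials[trials$odor == o, , drop = FALSE]
    if (nrow(d) < 2) stop("psth_similarity: need >= 2 trials for odor ", o)
    head(d[order(d$poke_in), , drop = FALSE], n_per_odor)
  }))
  cnt <- window_spike_counts(session, sel, "poke_in", window, bin = 0.001)
  ntr <- nrow(sel)
  vecs <- matrix(0, ntr, dim(cnt)[2] * dim(cnt)[3])
  for (i in seq_len(ntr)) {
    m <- t(apply(cnt[i, , , drop = TRUE], 1, gauss_smooth, sd_bins = smooth_sd_ms))
    pk <- apply(m, 1, max)
    m[pk > 0, ] <- m[pk > 0, , drop = FALSE] / pk[pk > 0]
    vecs[i, ] <- as.numeric(t(m))
  }
  pairs <- which(upper.tri(matrix(0, ntr, ntr)), arr.ind = TRUE)
  sds <- apply(vecs, 1, sd)
  r <- rep(NA_real_, nrow(pairs))
  ok <- sds[pairs[, 1]] > 0 & sds[pairs[, 2]] > 0
  if (any(!ok)) sm_log("psth_similarity: skipping %d constant-PSTH pairs", sum(!ok))
  if (any(ok)) {
    cm <- cor(t(vecs))
    r[ok] <- cm[pairs[ok, , drop = FALSE]]
  }
  oi <- sel$odor[pairs[, 1]]; oj <- sel$odor[pairs[, 2]]
  cls <- paste0(pmin(oi, oj), pmax(oi, oj))
  out <- data.frame(trial_i = sel$trial_id[pairs[, 1]],
                    trial_j = sel$trial_id[pairs[, 2]],
                    odor_i = oi, odor_j = oj, pair_class = cls,
                    same_odor = oi == oj, r = r,
                    stringsAsFactors = FALSE)
  ok2 <- !is.na(out$r)
  anova_p <- summary(aov(r ~ pair_class, data = out[ok2, ]))[[1]][["Pr(>F)"]][1]
  tt <- t.test(out$r[ok2 & out$same_odor], out$r[ok2 & !out$same_odor])
  dun <- do.call(rbind, lapply(odors, function(o) {
    ref <- out$r[ok2 & out$pair_class == paste0(o, o)]
    others <- setdiff(odors, o)
    ps <- vapply(others, function(o2) {
      cmp <- out$r[ok2 & out$pair_class == paste0(pmin(o, o2), pmax(o, o2))]
      if (length(cmp) < 2 || length(ref) < 2) return(NA_real_)
      t.test(ref, cmp)$p.value
    }, numeric(1))
    data.frame(odor = o, versus = others, p_raw = ps,
               p_adj = p.adjust(ps, "holm"), stringsAsFactors = FALSE)
  }))
  list(pairs = out, anova_p = anova_p,
       mean_same = mean(out$r[ok2 & out$same_odor]),
       mean_diff = mean(out$r[ok2 & !out$same_odor]),
       same_vs_diff_p = tt$p.value, dunnett = dun)
}
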
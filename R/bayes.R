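# sliding-bin spike counts: count in [start, start+tau) for each bin start
sliding_counts <- function(session, trials, starts, tau, anchor = "poke_in") {
  ids <- names(session$neurons)
  out <- array(0L, dim = c(nrow(trials), length(ids), length(starts)),
               dimnames = list(trials$trial_id, ids, NULL))
  anchors <- trials[[anchor]]
  for (j in seq_along(ids)) {
    st <- session$neurons[[ids[j]]]
    if (!length(st)) next
    for (i in seq_along(anchors)) {
      lo <- findInterval(anchors[i] + starts, st, left.open = TRUE)
      hi <- findInterval(anchors[i] + starts + tau, st, left.open = TRUE)
      out[i, j, ] <- hi - lo
    }
  }
  out
}

#' Fit the Poisson rate map f(neuron, time, odor)
#'
#' Mean firing rate of each neuron in overlapping time bins of length `tau`
#' advanced by `step`, per odor, estimated from the supplied training trials
#' only. Neurons with an all-zero training rate for an odor are flagged (they
#' are dropped from decodes of that odor, since a zero rate leaves the
#' Poisson likelihood undefined for nonzero counts).
#'
#' @param session session.
#' @param trials training trial table (caller is responsible for the
#'   selection protocol, typically consecutive correct InSeq sequences).
#' @param tau bin length (s); `step` bin advance (s).
#' @param window c(a, b) seconds relative to poke_in.
#' @param odors odors to fit (each must have >= 1 training trial).
#' @return `seqmem_ratemap`: list(f = neuron x bin x odor array in Hz,
#'   counts/trial_ids per odor, starts, tau, step, window, odors, zero_flag).
#' @export
fit_rate_map <- function(session, trials, tau = 0.05, step = 0.005,
                         window = c(0, 1.2), odors = c("A", "B", "C", "D")) {
  starts <- seq(window[1], window[2] - tau + 1e-12, by = step)
  ids <- names(session$neurons)
  f <- array(0, dim = c(length(ids), length(starts), length(odors)),
             dimnames = list(ids, NULL, odors))
  counts <- list(); trial_ids <- list()
  for (o in odors) {
    tr <- trials[trials$odor == o, , drop = FALSE]
    if (nrow(tr) == 0) stop("fit_rate_map: no training trials for odor ", o)
    cnt <- sliding_counts(session, tr, starts, tau)
    f[, , o] <- apply(cnt, c(2, 3), mean) / tau
    counts[[o]] <- cnt
    trial_ids[[o]] <- tr$trial_id
  }
  zero_flag <- matrix(FALSE, length(ids), length(odors),
                      dimnames = list(ids, odors))
  for (o in odors)
    zero_flag[, o] <- rowSums(matrix(f[, , o], nrow = length(ids))) == 0
  structure(list(f = f, counts = counts, trial_ids = trial_ids,
                 starts = starts, tau = tau, step = step, window = window,
                 odors = odors, zero_flag = zero_flag),
            class = "seqmem_ratemap")
}

# core posterior: counts N (rows x neurons), rates fmat (neurons x cols in Hz)
# returns rows x cols posterior, each row normalized to 1 (log-space).
posterior_from_rates <- function(N, fmat, obs_tau, eps = 1e-3) {
  fmat <- pmax(fmat, eps)
  L <- log(obs_tau * fmat)
  lp <- N %*% L
  lp <- sweep(lp, 2, obs_tau * colSums(fmat), `-`)
  P <- t(apply(lp, 1, function(row) {
    z <- logsumexp(row)
    if (!is.finite(z)) stop("decode_time: cannot normalize posterior row")
    exp(row - z)
  }))
  P
}

#' Memoryless Bayesian decoding of time (and odor) from spike counts
#'
#' For each actual-time bin (row of `counts`), computes the posterior over
#' reconstructed time bins under independent-Poisson spiking with a uniform
#' prior, in log space: `P(t' | n) ~ prod_i (tau f_i(t'))^{n_i} exp(-tau
#' sum_i f_i(t'))`, normalized so each row sums to 1. In joint mode the
#' posterior ranges over time x odor columns.
#'
#' @param rate_map `seqmem_ratemap`.
#' @param counts actual-bin x neuron count matrix (e.g. from
#'   [decode_counts()] for one test trial).
#' @param odor odor whose map is used (within-odor mode).
#' @param mode "within" (posterior over time for one odor) or "joint"
#'   (posterior over time x odor).
#' @param obs_tau duration (s) over which `counts` were observed; defaults to
#'   the rate map's `tau`.
#' @param eps rate floor in Hz applied before taking logs.
#' @return posterior matrix, class `seqmem_posterior` with attributes
#'   `starts`, `odors`, `mode`.
#' @export
decode_time <- function(rate_map, counts, odor = NULL,
                        mode = c("within", "joint"), obs_tau = NULL,
                        eps = 1e-3) {
  mode <- match.arg(mode)
  obs_tau <- obs_tau %||% rate_map$tau
  ids <- dimnames(rate_map$f)[[1]]
  counts <- counts[, ids, drop = FALSE]
  f_of <- function(o) matrix(rate_map$f[, , o], nrow = dim(rate_map$f)[1])
  if (mode == "within") {
    stopifnot(odor %in% rate_map$odors)
    keep <- !rate_map$zero_flag[, odor]
    fmat <- f_of(odor)[keep, , drop = FALSE]
    P <- posterior_from_rates(counts[, keep, drop = FALSE], fmat, obs_tau, eps)
    od <- rep(odor, length(rate_map$starts))
  } else {
    keep <- rowSums(!rate_map$zero_flag) > 0
    fmat <- do.call(cbind, lapply(rate_map$odors, function(o)
      f_of(o)[keep, , drop = FALSE]))
    P <- posterior_from_rates(counts[, keep, drop = FALSE], fmat, obs_tau, eps)
    od <- rep(rate_map$odors, each = length(rate_map$starts))
  }
  structure(P, class = c("seqmem_posterior", "matrix"),
            starts = rep(rate_map$starts, length.out = ncol(P)),
            odors = od, mode = mode)
}

#' Spike counts of one trial on the rate map's bin grid
#' @param session session; `trial` one-row trial table; `rate_map` the map.
#' @return actual-bin x neuron matrix.
#' @export
decode_counts <- function(session, trial, rate_map) {
  cnt <- sliding_counts(session, trial, rate_map$starts, rate_map$tau)
  matrix(cnt[1, , ], nrow = dim(cnt)[3], ncol = dim(cnt)[2], byrow = TRUE,
         dimnames = list(NULL, dimnames(cnt)[[2]]))
}

#' Accuracy of reconstructed time
#'
#' Mean over bin index i of the Pearson correlation between row i and column
#' i of a square posterior matrix. Pairs with zero variance are skipped; if
#' every pair is undefined the result is NaN (logged by callers).
#'
#' @param posterior square posterior matrix.
#' @return scalar accuracy.
#' @export
reconstruction_accuracy <- function(posterior) {
  P <- unclass(posterior)
  if (nrow(P) != ncol(P)) stop("reconstruction_accuracy: posterior not square")
  v <- vapply(seq_len(nrow(P)), function(i) {
    x <- P[i, ]; y <- P[, i]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  if (all(is.na(v))) return(NaN)
  mean(v, na.rm = TRUE)
}

# standardized rows/cols for fast permutation accuracy
std_rows <- function(P) {
  m <- rowMeans(P); s <- apply(P, 1, sd)
  R <- (P - m) / s
  R[s == 0, ] <- NA
  R
}

# accuracy of each column-permutation of a posterior, computed from the
# unpermuted posterior (permuting the time axis of the rate map permutes the
# posterior's columns).
accuracy_perms <- function(P, perms) {
  P <- unclass(P)
  n <- nrow(P)
  R <- std_rows(P)          # rows standardized (permutation-invariant stats)
  C <- std_rows(t(P))       # columns standardized, as rows
  vapply(perms, function(pr) {
    M <- R[, pr, drop = FALSE] %*% t(C)   # M[i,k] = sum_j R[i,pr(j)] C[k,j]
    v <- M[cbind(seq_len(n), pr)] / (n - 1)
    if (all(is.na(v))) NaN else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Leave-one-out reconstructed-time accuracy for one odor
#'
#' For each training trial, the rate map is refit without it (computed
#' incrementally from the stored count tensor) and the held-out trial is
#' decoded; training and test sets are disjoint by construction.
#'
#' @param rate_map `seqmem_ratemap` fit on the full training set.
#' @param odor odor to decode.
#' @param eps rate floor (Hz).
#' @return data.frame(trial_id, accuracy); attribute "posteriors" holds the
#'   per-trial posterior matrices.
#' @export
loo_accuracy <- function(rate_map, odor, eps = 1e-3) {
  cnt <- rate_map$counts[[odor]]
  ntr <- dim(cnt)[1]
  if (ntr < 2) stop("loo_accuracy: need >= 2 training trials")
  S <- apply(cnt, c(2, 3), sum)   # neuron x bin total counts
  posts <- vector("list", ntr)
  acc <- numeric(ntr)
  for (k in seq_len(ntr)) {
    Nk <- matrix(cnt[k, , ], nrow = dim(cnt)[3], byrow = TRUE)  # bins x neurons
    f_loo <- (S - t(Nk)) / ((ntr - 1) * rate_map$tau)
    keep <- rowSums(f_loo) > 0
    P <- posterior_from_rates(Nk[, keep, drop = FALSE],
                              f_loo[keep, , drop = FALSE], rate_map$tau, eps)
    posts[[k]] <- P
    acc[k] <- reconstruction_accuracy(P)
  }
  out <- data.frame(trial_id = rate_map$trial_ids[[odor]], accuracy = acc)
  attr(out, "posteriors") <- posts
  out
}

#' Permutation chance distribution of reconstructed-time accuracy
#'
#' Random permutations of the time factor of the rate map; because permuting
#' the map's time axis permutes the posterior's columns, chance accuracies
#' are computed directly from the observed posteriors.
#'
#' @param posteriors list of square posterior matrices (one per trial).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list(chance = per-permutation mean accuracies, mean, q95).
#' @export
chance_accuracy <- function(posteriors, n_perm = 1000, seed = 1) {
  nb <- nrow(posteriors[[1]])
  perms <- perm_stream(nb, n_perm, seed, "time-shuffle")
  per_trial <- vapply(posteriors, accuracy_perms, numeric(n_perm), perms = perms)
  ch <- rowMeans(as.matrix(per_trial), na.rm = TRUE)
  list(chance = ch, mean = mean(ch), q95 = unname(quantile(ch, 0.95)))
}

#' Reconstructed-time accuracy by sequence lag
#'
#' Trains the decoder per odor at its proper position (consecutive correct
#' InSeq sequences) and tests it on trials of the other positions; lag is the
#' signed position difference. Lag 0 is tested on correct InSeq trials not in
#' the training set (non-consecutive); if fewer than `min_lag0` such trials
#' exist, a held-out fifth of the training trials is used instead (train and
#' test always disjoint).
#'
#' @param session session.
#' @param tau,step,window decoder bin geometry.
#' @param odors odors to train on.
#' @param eps rate floor (Hz).
#' @param min_lag0 minimum lag-0 test trials before falling back to holdout.
#' @param seed seed for the holdout draw.
#' @return list(table = tidy data.frame(trial_id, train_odor, test_odor, lag,
#'   accuracy), by_abs_lag = mean accuracy at |lag| 0..3, anova_p, trend_p,
#'   trend_slope, posteriors_lag0).
#' @export
lag_analysis <- function(session, tau = 0.1, step = 0.1, window = c(0, 1.2),
                         odors = c("A", "B", "C", "D"), eps = 1e-3,
                         min_lag0 = 4, seed = 1) {
  trials <- session$trials
  train_all <- select_trials(trials, consecutive_inseq = TRUE)
  rows <- list(); posts0 <- list()
  for (o in odors) {
    pos_o <- odor_index(o)
    tr_o <- train_all[train_all$odor == o, , drop = FALSE]
    if (nrow(tr_o) < 3) { sm_log("lag_analysis: odor %s skipped (few trials)", o); next }
    nonconsec <- select_trials(trials, in_seq = TRUE, correct = TRUE, odors = o)
    nonconsec <- nonconsec[!(nonconsec$trial_id %in% tr_o$trial_id), , drop = FALSE]
    if (nrow(nonconsec) >= min_lag0) {
      test0 <- nonconsec
      train0 <- tr_o
    } else {
      hold <- with_seed(seed + pos_o, sample(nrow(tr_o), max(2, ceiling(nrow(tr_o) / 5))))
      test0 <- tr_o[hold, , drop = FALSE]
      train0 <- tr_o[-hold, , drop = FALSE]
      sm_log("lag_analysis: odor %s lag 0 uses a 20%% holdout", o)
    }
    rm0 <- fit_rate_map(session, train0, tau, step, window, odors = o)
    for (k in seq_len(nrow(test0))) {
      P <- decode_time(rm0, decode_counts(session, test0[k, ], rm0), odor = o)
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = test0$trial_id[k], train_odor = o, test_odor = o,
        lag = 0L, accuracy = reconstruction_accuracy(P))
      posts0[[length(posts0) + 1]] <- P
    }
    rm <- fit_rate_map(session, tr_o, tau, step, window, odors = o)
    for (lag in c(-3:-1, 1:3)) {
      pos_t <- pos_o + lag
      if (pos_t < 1 || pos_t > 5) next
      o_t <- c("A", "B", "C", "D", "E")[pos_t]
      test <- select_trials(trials, in_seq = TRUE, correct = TRUE, odors = o_t)
      if (nrow(test) == 0) { sm_log("lag_analysis: lag %d omitted for %s", lag, o); next }
      for (k in seq_len(nrow(test))) {
        P <- decode_time(rm, decode_counts(session, test[k, ], rm), odor = o)
        rows[[length(rows) + 1]] <- data.frame(
          trial_id = test$trial_id[k], train_odor = o, test_odor = o_t,
          lag = lag, accuracy = reconstruction_accuracy(P))
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!is.nan(tab$accuracy), , drop = FALSE]
  by_abs <- tapply(tab$accuracy, abs(tab$lag), mean)
  av <- aov(accuracy ~ factor(lag), data = tab)
  lt <- lm(accuracy ~ abs(lag), data = tab)
  list(table = tab, by_abs_lag = by_abs,
       anova_p = summary(av)[[1]][["Pr(>F)"]][1],
       trend_slope = unname(coef(lt)[2]),
       trend_p = summary(lt)$coefficients[2, 4],
       posteriors_lag0 = posts0)
}

#' KL-divergence comparison of pre-entry decoding on OutSeq trials
#'
#' Trains the joint (time x odor) model on correct consecutive InSeq
#' sequences, decodes the 250 ms window preceding port entry on OutSeq trials
#' at positions 2-4, and compares each OutSeq trial's posterior shape with
#' the mean posterior of InSeq trials via KL divergence. Correct vs incorrect
#' distributions are compared with a two-sample Kolmogorov-Smirnov test; an
#' optional downsampled repetition matches the correct-trial count to the
#' incorrect-trial count.
#'
#' @param session session.
#' @param tau,step,window joint rate-map geometry.
#' @param pre_window window before poke_in, default c(-0.25, 0).
#' @param positions OutSeq positions included.
#' @param n_downsample number of downsampled repetitions (0 = skip).
#' @param seed seed for downsampling.
#' @return list(kl = data.frame(trial_id, correct, kl), ks_D, ks_p,
#'   downsample = data.frame(D, p) or NULL).
#' @export
outcome_kl_comparison <- function(session, tau = 0.2, step = 0.2,
                                  window = c(0, 1.2), pre_window = c(-0.25, 0),
                                  positions = 2:4, n_downsample = 0, seed = 1) {
  trials <- session$trials
  train <- select_trials(trials, consecutive_inseq = TRUE)
  rm <- fit_rate_map(session, train, tau, step, window,
                     odors = c("A", "B", "C", "D", "E"))
  obs_tau <- diff(pre_window)
  pre_counts <- function(tr) {
    cnt <- sliding_counts(session, tr, starts = pre_window[1], tau = obs_tau)
    matrix(cnt[1, , 1], nrow = 1, dimnames = list(NULL, dimnames(cnt)[[2]]))
  }
  post_vec <- function(tr) {
    P <- decode_time(rm, pre_counts(tr), mode = "joint", obs_tau = obs_tau)
    as.numeric(P[1, ])
  }
  ins <- select_trials(trials, in_seq = TRUE, correct = TRUE, positions = positions)
  if (nrow(ins) == 0) stop("outcome_kl_comparison: no InSeq reference trials")
  Q <- colMeans(do.call(rbind, lapply(seq_len(nrow(ins)), function(k)
    post_vec(ins[k, ]))))
  outs <- select_trials(trials, in_seq = FALSE, positions = positions)
  if (!any(outs$correct) || all(outs$correct))
    stop("outcome_kl_comparison: need both correct and incorrect OutSeq trials")
  kl <- vapply(seq_len(nrow(outs)), function(k)
    kl_divergence(post_vec(outs[k, ]), Q), numeric(1))
  d <- data.frame(trial_id = outs$trial_id, correct = outs$correct, kl = kl)
  ks <- suppressWarnings(ks.test(d$kl[d$correct], d$kl[!d$correct]))
  down <- NULL
  if (n_downsample > 0) {
    nI <- sum(!d$correct)
    idxC <- which(d$correct)
    draws <- perm_stream(length(idxC), n_downsample, seed, "downsample",
                         size = min(nI, length(idxC)))
    down <- do.call(rbind, lapply(draws, function(ix) {
      k <- suppressWarnings(ks.test(d$kl[idxC[ix]], d$kl[!d$correct]))
      data.frame(D = unname(k$statistic), p = k$p.value)
    }))
  }
  list(kl = d, ks_D = unname(ks$statistic), ks_p = ks$p.value, downsample = down)
}

#' Split-half control for reconstructed-time accuracy
#'
#' 50:50 train/test validation: the rate map is fit on one half of the
#' training-eligible trials and decoded on the other half.
#'
#' @param session session.
#' @param odor odor to decode.
#' @param scheme "first-second", "quarters" (Q1&Q3 vs Q2&Q4) or "odd-even".
#' @param tau,step,window decoder geometry; `eps` rate floor.
#' @param n_perm,seed chance permutations.
#' @return list(accuracy = per-trial accuracies, mean, chance_q95,
#'   train_ids, test_ids).
#' @export
split_half_control <- function(session, odor, scheme = c("odd-even",
                               "first-second", "quarters"), tau = 0.1,
                               step = 0.1, window = c(0, 1.2), eps = 1e-3,
                               n_perm = 200, seed = 1) {
  scheme <- match.arg(scheme)
  tr <- select_trials(session$trials, consecutive_inseq = TRUE)
  tr <- tr[tr$odor == odor, , drop = FALSE]
  n <- nrow(tr)
  if (n < 4) stop("split_half_control: need >= 4 trials")
  idx <- switch(scheme,
    "odd-even" = seq_len(n) %% 2 == 1,
    "first-second" = seq_len(n) <= n / 2,
    "quarters" = ((seq_len(n) - 1) %/% ceiling(n / 4)) %% 2 == 0)
  train <- tr[idx, , drop = FALSE]; test <- tr[!idx, , drop = FALSE]
  if (nrow(train) < 2 || nrow(test) < 1)
    stop("split_half_control: degenerate split")
  rm <- fit_rate_map(session, train, tau, step, window, odors = odor)
  posts <- lapply(seq_len(nrow(test)), function(k)
    decode_time(rm, decode_counts(session, test[k, ], rm), odor = odor, eps = eps))
  acc <- vapply(posts, reconstruction_accuracy, numeric(1))
  ch <- chance_accuracy(posts, n_perm, seed)
  list(accuracy = acc, mean = mean(acc, na.rm = TRUE), chance_q95 = ch$q95,
       train_ids = train$trial_id, test_ids = test$trial_id)
}

#' Informative-neuron filter by single-neuron permutation test
#'
#' Runs the time decoder on each active neuron independently (leave-one-out
#' within the odor's training trials) and keeps neurons whose mean accuracy
#' exceeds their own time-permutation null at level `alpha`.
#'
#' @param session session.
#' @param odor odor analyzed.
#' @param tau,step,window decoder geometry.
#' @param n_perm permutations per neuron; `alpha` significance level;
#'   `seed` permutation seed.
#' @return data.frame(neuron_id, accuracy, p, significant); silent neurons
#'   are excluded a priori.
#' @export
informative_neuron_filter <- function(session, odor, tau = 0.1, step = 0.1,
                                      window = c(0, 1.2), n_perm = 1000,
                                      alpha = 0.05, seed = 1) {
  tr <- select_trials(session$trials, consecutive_inseq = TRUE)
  tr <- tr[tr$odor == odor, , drop = FALSE]
  rm_full <- fit_rate_map(session, tr, tau, step, window, odors = odor)
  cnt <- rm_full$counts[[odor]]
  active <- which(apply(cnt, 2, sum) > 0)
  res <- lapply(active, function(j) {
    cnt_j <- cnt[, j, , drop = FALSE]
    S <- apply(cnt_j, c(2, 3), sum)
    ntr <- dim(cnt_j)[1]
    posts <- list(); acc <- numeric(0)
    for (k in seq_len(ntr)) {
      Nk <- matrix(cnt_j[k, 1, ], ncol = 1)
      f_loo <- matrix((S - t(Nk))[1, ], nrow = 1) / ((ntr - 1) * tau)
      if (all(f_loo == 0)) next
      P <- posterior_from_rates(Nk, f_loo, tau)
      posts[[length(posts) + 1]] <- P
      acc <- c(acc, reconstruction_accuracy(P))
    }
    if (!length(posts) || all(is.nan(acc))) return(NULL)
    obs <- mean(acc, na.rm = TRUE)
    ch <- chance_accuracy(posts, n_perm, seed)$chance
    p <- (1 + sum(ch >= obs, na.rm = TRUE)) / (n_perm + 1)
    data.frame(neuron_id = names(session$neurons)[j], accuracy = obs, p = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("informative_neuron_filter: no decodable neurons")
  out$significant <- out$p <= alpha
  sm_log("informative_neuron_filter: %d/%d neurons significant at alpha=%g",
         sum(out$significant), nrow(out), alpha)
  out
}
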
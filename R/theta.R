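#' Instantaneous theta phase and amplitude of an LFP channel
#'
#' Butterworth band-pass (default 4-7 Hz, order 2, zero-phase via filtfilt)
#' followed by the analytic signal. Phase convention: 0 degrees at the peak
#' of the filtered trace, 180 at the trough, increasing through the cycle.
#'
#' @param samples LFP samples (microvolts).
#' @param fs sampling rate (Hz).
#' @param band band edges in Hz.
#' @param t0 time of the first sample (s).
#' @return list(phase_deg, amplitude, filtered, fs, t0, time).
#' @export
extract_phase <- function(samples, fs = 1000, band = c(4, 7), t0 = 0) {
  n <- length(samples)
  if (n < 2 * fs) stop("extract_phase: need >= 2 s of signal")
  # reflect-pad one second per side to keep filter and Hilbert transients
  # out of the analyzed span
  pad <- fs
  xp <- c(samples[(pad + 1):2], samples, samples[(n - 1):(n - pad)])
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, xp)
  a <- analytic_signal(filt)[(pad + 1):(pad + n)]
  list(phase_deg = (Arg(a) * 180 / pi) %% 360,
       amplitude = Mod(a), filtered = filt[(pad + 1):(pad + n)],
       fs = fs, t0 = t0,
       time = t0 + (seq_len(n) - 1) / fs)
}

# pick the session's theta channel: maximal band power after filtering
theta_channel <- function(session, band = c(4, 7)) {
  stopifnot(length(session$lfp) > 0)
  pow <- vapply(session$lfp, function(ch) {
    bf <- signal::butter(2, band / (session$sample_rate_lfp / 2), type = "pass")
    var(signal::filtfilt(bf, ch$samples))
  }, numeric(1))
  names(which.max(pow))
}

#' Segment theta cycles around each trial
#'
#' Cycles are delimited by ascending 0-degree crossings (peak-to-peak, so the
#' trough sits mid-cycle). Cycle 1 is the first cycle starting at or after
#' poke_in + 100 ms; later in-trial cycles count up while their start
#' precedes poke_out; cycles ending before poke_in count backwards (-1, -2,
#' ...). Trials whose cycle-1 amplitude falls in the lowest
#' `exclude_amp_pct` percentile across trials are marked excluded.
#'
#' @param session session (theta channel chosen by maximal 4-7 Hz power).
#' @param trials trial table.
#' @param exclude_amp_pct percentile of cycle-1 amplitudes excluded (0-100).
#' @param n_pre number of pre-entry cycles retained.
#' @param band theta band for phase extraction.
#' @return list(cycles = data.frame(trial_id, cycle, start, end, amplitude),
#'   excluded_trials, dropped_trials, phase = phase series, tetrode).
#' @export
segment_cycles <- function(session, trials, exclude_amp_pct = 20, n_pre = 4,
                           band = c(4, 7)) {
  tet <- session$meta$theta_tetrode %||% theta_channel(session, band)
  if (!tet %in% names(session$lfp)) tet <- theta_channel(session, band)
  ch <- session$lfp[[tet]]
  ph <- extract_phase(ch$samples, session$sample_rate_lfp, band, ch$t0)
  u <- unwrap_deg(ph$phase_deg)
  k <- floor(u / 360)
  bix <- which(diff(k) > 0) + 1L           # first sample of each new cycle
  tb <- ph$time[bix]
  rows <- list(); dropped <- character(0)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    post <- which(tb >= tr$poke_in + 0.1 & tb < tr$poke_out)
    post <- post[post < length(tb)]
    if (!length(post)) {
      dropped <- c(dropped, tr$trial_id)
      next
    }
    pre <- which(tb > tr$poke_in - 1.5)     # candidate pre-entry boundaries
    pre <- pre[pre < length(tb) & tb[pmin(pre + 1, length(tb))] <= tr$poke_in]
    pre <- tail(pre, n_pre)
    idx <- c(rev(seq_len(length(pre))) * -1L, seq_along(post))
    bnd <- c(pre, post)
    for (j in seq_along(bnd)) {
      b <- bnd[j]
      s0 <- bix[b]; s1 <- bix[b + 1] - 1L
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = tr$trial_id, cycle = idx[j],
        start = tb[b], end = ph$time[s1] + 1 / ph$fs,
        amplitude = mean(ph$amplitude[s0:s1]))
    }
  }
  if (length(dropped))
    sm_log("segment_cycles: dropped %d trials without a complete cycle", length(dropped))
  cyc <- do.call(rbind, rows)
  c1 <- cyc[cyc$cycle == 1, ]
  thr <- quantile(c1$amplitude, exclude_amp_pct / 100)
  excluded <- if (exclude_amp_pct > 0) c1$trial_id[c1$amplitude <= thr] else character(0)
  if (length(excluded))
    sm_log("segment_cycles: %d trials excluded by cycle-1 amplitude", length(excluded))
  list(cycles = cyc, excluded_trials = excluded, dropped_trials = dropped,
       phase = ph, tetrode = tet)
}

# per (trial, cycle) observation: spike counts per neuron per 10-degree bin
# and occupancy (s) per bin. Returns list(counts[obs, neuron, 36],
# dur[obs, 36], info).
cycle_phase_hists <- function(session, seg, obs) {
  ph <- seg$phase
  nbin <- 36L
  ids <- names(session$neurons)
  counts <- array(0L, dim = c(nrow(obs), length(ids), nbin))
  dur <- matrix(0, nrow(obs), nbin)
  for (r in seq_len(nrow(obs))) {
    s0 <- obs$start[r]; s1 <- obs$end[r]
    i0 <- max(1L, ceiling((s0 - ph$t0) * ph$fs) + 1L)
    i1 <- min(length(ph$phase_deg), floor((s1 - ph$t0) * ph$fs))
    pb <- pmin(floor(ph$phase_deg[i0:i1] / 10) + 1L, nbin)
    dur[r, ] <- tabulate(pb, nbin) / ph$fs
    for (j in seq_along(ids)) {
      st <- session$neurons[[ids[j]]]
      lo <- findInterval(s0, st, left.open = TRUE)
      hi <- findInterval(s1, st, left.open = TRUE)
      if (hi <= lo) next
      sp <- st[(lo + 1):hi]
      si <- pmax(1L, pmin(length(ph$phase_deg), round((sp - ph$t0) * ph$fs) + 1L))
      sb <- pmin(floor(ph$phase_deg[si] / 10) + 1L, nbin)
      counts[r, j, ] <- tabulate(sb, nbin)
    }
  }
  list(counts = counts, dur = dur, info = obs, neuron_ids = ids)
}

# circular sliding sum over 36 bins: window = bins b-6 .. b+5 (120 degrees)
circ_window_sum <- function(x) {
  nb <- length(x)
  xx <- c(x, x, x)
  vapply(seq_len(nb), function(b) sum(xx[(nb + b - 6):(nb + b + 5)]), numeric(1))
}

# sliding-window firing rates: list(rates[obs, neuron, 36]); NaN where the
# phase window has no occupancy
sliding_phase_rates <- function(hists) {
  dm <- dim(hists$counts)
  rates <- array(NA_real_, dm)
  for (r in seq_len(dm[1])) {
    wdur <- circ_window_sum(hists$dur[r, ])
    for (j in seq_len(dm[2])) {
      wc <- circ_window_sum(hists$counts[r, j, ])
      rates[r, j, ] <- ifelse(wdur > 0, wc / wdur, NaN)
    }
  }
  rates
}

# trough (120-240 deg) rate per observation per neuron
trough_rates <- function(hists) {
  tb <- 13:24
  dur <- rowSums(hists$dur[, tb, drop = FALSE])
  cnt <- apply(hists$counts[, , tb, drop = FALSE], c(1, 2), sum)
  sweep(cnt, 1, pmax(dur, 1e-9), `/`)
}

#' Train the trough-phase LASSO odor decoder
#'
#' Multinomial L1-penalized logistic regression on each neuron's firing rate
#' during the trough (120-240 degrees) of theta cycle 1 on correct InSeq
#' trials; the penalty is chosen by stratified 10-fold cross-validation.
#' Neurons not contributing to decoding receive exactly zero weight.
#'
#' @param session session; `seg` from [segment_cycles()].
#' @param classes odor classes decoded.
#' @param nfolds cross-validation folds (degraded with a warning when a class
#'   has fewer trials).
#' @param seed fold-assignment (and balancing) seed.
#' @param balance_classes subsample training trials so every odor class has
#'   the same count (sequence truncation oversamples early odors, which would
#'   otherwise bias the multinomial intercepts).
#' @return `seqmem_lasso`: list(fit, lambda, classes, zero_neurons,
#'   train_ids, predict_rates(function)).
#' @export
train_trough_lasso <- function(session, seg, classes = c("A", "B", "C", "D"),
                               nfolds = 10, seed = 1, balance_classes = TRUE) {
  tr <- select_trials(session$trials, in_seq = TRUE, correct = TRUE,
                      odors = classes)
  tr <- tr[!(tr$trial_id %in% seg$excluded_trials), , drop = FALSE]
  if (balance_classes) {
    nmin <- min(table(tr$odor))
    with_seed(seed + 7L, {
      keep <- unlist(lapply(split(seq_len(nrow(tr)), tr$odor), function(ix)
        sample(ix, nmin)))
    })
    tr <- tr[sort(keep), , drop = FALSE]
  }
  obs <- seg$cycles[seg$cycles$cycle == 1 & seg$cycles$trial_id %in% tr$trial_id, ]
  if (length(unique(tr$odor[match(obs$trial_id, tr$trial_id)])) < 2)
    stop("train_trough_lasso: need >= 2 odor classes")
  h <- cycle_phase_hists(session, seg, obs)
  X <- trough_rates(h)
  y <- tr$odor[match(obs$trial_id, tr$trial_id)]
  tab <- table(y)
  if (min(tab) < nfolds) {
    warning("train_trough_lasso: smallest class has ", min(tab),
            " trials; reducing folds")
    nfolds <- max(3, min(tab))
  }
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in names(tab)) {
      ix <- sample(which(y == cl))
      foldid[ix] <- rep_len(seq_len(nfolds), length(ix))
    }
  })
  cvfit <- glmnet::cv.glmnet(X, factor(y, levels = classes),
                             family = "multinomial", alpha = 1,
                             foldid = foldid, type.measure = "class",
                             standardize = TRUE)
  beta <- coef(cvfit, s = "lambda.min")
  bmat <- do.call(cbind, lapply(beta, function(b) as.numeric(b)[-1]))
  zero <- h$neuron_ids[rowSums(abs(bmat)) == 0]
  predict_rates <- function(R) {
    # R: rows x neuron rate matrix; returns rows x classes probabilities
    p <- predict(cvfit, newx = R, s = "lambda.min", type = "response")
    matrix(p[, , 1], nrow = nrow(R), dimnames = list(NULL, dimnames(p)[[2]]))
  }
  structure(list(fit = cvfit, lambda = cvfit$lambda.min, classes = classes,
                 neuron_ids = h$neuron_ids, zero_neurons = zero,
                 train_ids = obs$trial_id, predict_rates = predict_rates),
            class = "seqmem_lasso")
}

#' Sliding-phase decoding across theta cycles
#'
#' Applies a trough-trained classifier to firing rates in a 120-degree window
#' slid in 10-degree increments around each requested cycle of each trial.
#'
#' @param classifier `seqmem_lasso` (or any object with `predict_rates` and
#'   `classes`).
#' @param session session; `seg` from [segment_cycles()].
#' @param trials trials to decode.
#' @param cycle_set cycle indices (negative = pre-entry).
#' @return data.frame(trial_id, cycle, bin (1-36; label = 10*(bin-1) deg),
#'   p_<class>...); probability rows sum to 1, NaN where a phase window is
#'   empty.
#' @export
decode_phase_sliding <- function(classifier, session, seg, trials,
                                 cycle_set = 1L) {
  obs <- seg$cycles[seg$cycles$cycle %in% cycle_set &
                      seg$cycles$trial_id %in% trials$trial_id, ]
  if (!nrow(obs)) stop("decode_phase_sliding: no matching cycles")
  h <- cycle_phase_hists(session, seg, obs)
  rates <- sliding_phase_rates(h)
  nb <- dim(rates)[3]
  R <- do.call(rbind, lapply(seq_len(nb), function(b)
    matrix(rates[, , b], nrow = dim(rates)[1])))
  ok <- complete.cases(R)
  probs <- matrix(NaN, nrow(R), length(classifier$classes),
                  dimnames = list(NULL, classifier$classes))
  if (any(ok)) probs[ok, ] <- classifier$predict_rates(R[ok, , drop = FALSE])
  out <- data.frame(trial_id = rep(obs$trial_id, nb),
                    cycle = rep(obs$cycle, nb),
                    bin = rep(seq_len(nb), each = nrow(obs)))
  colnames(probs) <- paste0("p_", classifier$classes)
  cbind(out, probs)
}

#' Map decoded odor probabilities to past/present/future roles
#'
#' On a trial at sequence position p, past = the InSeq odor of position p-1,
#' present = the presented odor, future = the InSeq odor of position p+1.
#' Only trials whose three role odors all lie in the decoded classes are kept
#' (odors ABC on B trials, BCD on C trials).
#'
#' @param decoded output of [decode_phase_sliding()].
#' @param trials trial table.
#' @param classes decoded classes.
#' @return decoded table with columns p_past, p_present, p_future and
#'   phase ("descending", "trough", "ascending").
#' @export
role_probabilities <- function(decoded, trials,
                               classes = c("A", "B", "C", "D")) {
  odors <- c("A", "B", "C", "D", "E")
  tr <- trials[match(decoded$trial_id, trials$trial_id), ]
  past <- ifelse(tr$position > 1, odors[pmax(tr$position - 1, 1)], NA)
  future <- ifelse(tr$position < 5, odors[pmin(tr$position + 1, 5)], NA)
  present <- tr$odor
  ok <- !is.na(past) & !is.na(future) &
    past %in% classes & future %in% classes & present %in% classes
  d <- decoded[ok, , drop = FALSE]
  pick <- function(od) {
    m <- as.matrix(d[, paste0("p_", classes)])
    m[cbind(seq_len(nrow(d)), match(od[ok], classes))]
  }
  d$p_past <- pick(past); d$p_present <- pick(present); d$p_future <- pick(future)
  d$phase <- c("descending", "trough", "ascending")[
    findInterval((d$bin - 1) * 10, c(0, 120, 240))]
  d
}

#' Cross-cycle dynamics of past/present/future decoding
#'
#' Z-normalizes each role's probabilities over all bins, cycles and trials,
#' collapses across phase per cycle, and fits a two-way ANOVA (role x cycle)
#' with linear and quadratic trends per role. The same tests are run on the
#' raw probabilities; the significance pattern should not depend on the
#' normalization.
#'
#' @param roles output of [role_probabilities()] spanning several cycles.
#' @param cycle_set cycles analyzed (default c(-2, 1, 3, 5)).
#' @return list(summary = per trial x cycle x role values (z and raw),
#'   anova_p, trends = per-role slope and p (z scale), trends_raw).
#' @export
cross_cycle_analysis <- function(roles, cycle_set = c(-2L, 1L, 3L, 5L)) {
  d <- roles[roles$cycle %in% cycle_set, ]
  long <- do.call(rbind, lapply(c("past", "present", "future"), function(rl) {
    data.frame(trial_id = d$trial_id, cycle = d$cycle, role = rl,
               value = d[[paste0("p_", rl)]])
  }))
  long <- long[is.finite(long$value), ]
  long$z <- NA_real_
  for (rl in unique(long$role)) {
    ix <- long$role == rl
    long$z[ix] <- (long$value[ix] - mean(long$value[ix])) / sd(long$value[ix])
  }
  agg <- stats::aggregate(cbind(value, z) ~ trial_id + cycle + role,
                          data = long, FUN = mean)
  agg$cycle_rank <- match(agg$cycle, sort(cycle_set))
  av <- aov(z ~ role * factor(cycle), data = agg)
  ps <- summary(av)[[1]][["Pr(>F)"]]
  trends <- do.call(rbind, lapply(c("past", "present", "future"), function(rl) {
    s <- agg[agg$role == rl, ]
    lt <- lm(z ~ cycle_rank, data = s)
    qt_ <- lm(z ~ cycle_rank + I(cycle_rank^2), data = s)
    lr <- lm(value ~ cycle_rank, data = s)
    data.frame(role = rl, slope = unname(coef(lt)[2]),
               p_linear = summary(lt)$coefficients[2, 4],
               p_quad = summary(qt_)$coefficients[3, 4],
               slope_raw = unname(coef(lr)[2]),
               p_linear_raw = summary(lr)$coefficients[2, 4])
  }))
  list(summary = agg,
       anova_p = c(role = ps[1], cycle = ps[2], interaction = ps[3]),
       trends = trends)
}

#' Outcome and InSeq/OutSeq comparisons of theta-phase decoding
#'
#' `comparison = "outcome"`: OutSeq trials at positions 2-3, decoding of the
#' expected InSeq stimulus across the three phases averaged over the last two
#' pre-entry cycles, correct vs incorrect (two-way ANOVA group x phase,
#' Bonferroni-corrected per-phase t tests, optional downsampled repetitions).
#' `comparison = "inseq_outseq"`: cycle-1 phase profile of the InSeq
#' reference stimuli (past at descending, present at trough, future at
#' ascending) compared between InSeq and OutSeq trials.
#'
#' @param classifier trained decoder; `session`, `seg` as elsewhere.
#' @param comparison which contrast to run.
#' @param positions sequence positions included (default 2:3).
#' @param n_downsample,downsample_size,seed downsampled repetitions.
#' @return list(table, anova_p, phase_tests, downsample).
#' @export
trial_type_comparisons <- function(classifier, session, seg,
                                   comparison = c("outcome", "inseq_outseq"),
                                   positions = 2:3, n_downsample = 0,
                                   downsample_size = 30, seed = 1) {
  comparison <- match.arg(comparison)
  odors <- c("A", "B", "C", "D", "E")
  trials <- session$trials
  if (comparison == "outcome") {
    tt <- select_trials(trials, in_seq = FALSE, positions = positions)
    if (!any(tt$correct) || all(tt$correct))
      stop("trial_type_comparisons: need both outcome groups")
    dec <- decode_phase_sliding(classifier, session, seg, tt,
                                cycle_set = c(-1L, -2L))
    tr <- trials[match(dec$trial_id, trials$trial_id), ]
    expd <- odors[tr$position]
    m <- as.matrix(dec[, paste0("p_", classifier$classes)])
    dec$p_ref <- m[cbind(seq_len(nrow(dec)), match(expd, classifier$classes))]
    dec$phase <- c("descending", "trough", "ascending")[
      findInterval((dec$bin - 1) * 10, c(0, 120, 240))]
    dec$group <- ifelse(tr$correct, "correct", "incorrect")
  } else {
    tt <- select_trials(trials, correct = TRUE, positions = positions)
    dec <- decode_phase_sliding(classifier, session, seg, tt, cycle_set = 1L)
    tr <- trials[match(dec$trial_id, trials$trial_id), ]
    m <- as.matrix(dec[, paste0("p_", classifier$classes)])
    ref_od <- cbind(odors[tr$position - 1], odors[tr$position],
                    odors[pmin(tr$position + 1, 5)])
    dec$phase <- c("descending", "trough", "ascending")[
      findInterval((dec$bin - 1) * 10, c(0, 120, 240))]
    ref <- ref_od[cbind(seq_len(nrow(dec)),
                        match(dec$phase, c("descending", "trough", "ascending")))]
    keep <- ref %in% classifier$classes
    dec <- dec[keep, ]
    dec$p_ref <- m[keep, ][cbind(seq_len(sum(keep)),
                                 match(ref[keep], classifier$classes))]
    dec$group <- ifelse(tr$in_seq[keep], "inseq", "outseq")
  }
  dec <- dec[is.finite(dec$p_ref), ]
  agg <- stats::aggregate(p_ref ~ trial_id + phase + group, data = dec, FUN = mean)
  av <- aov(p_ref ~ group * phase, data = agg)
  ps <- summary(av)[[1]][["Pr(>F)"]]
  phases <- c("descending", "trough", "ascending")
  pt <- vapply(phases, function(phz) {
    s <- agg[agg$phase == phz, ]
    if (length(unique(s$group)) < 2) return(NA_real_)
    t.test(p_ref ~ group, data = s)$p.value
  }, numeric(1))
  pt_adj <- pmin(pt * 3, 1)  # Bonferroni over the three phases
  down <- NULL
  if (n_downsample > 0 && comparison == "outcome") {
    g1 <- unique(agg$trial_id[agg$group == "correct"])
    draws <- perm_stream(length(g1), n_downsample, seed, "downsample",
                         size = min(downsample_size, length(g1)))
    down <- vapply(draws, function(ix) {
      s <- agg[agg$group == "incorrect" | agg$trial_id %in% g1[ix], ]
      summary(aov(p_ref ~ group * phase, data = s))[[1]][["Pr(>F)"]][1]
    }, numeric(1))
  }
  list(table = agg,
       anova_p = c(group = ps[1], phase = ps[2], interaction = ps[3]),
       phase_tests = data.frame(phase = phases, p_raw = pt, p_bonf = pt_adj),
       downsample = down)
}

# univariate (single-neuron) multinomial decoders trained on cycle-1 trough
# rates; returns per-neuron prob arrays [obs, bin, class] on the given cycles
single_cell_decodings <- function(session, seg, classes = c("A", "B", "C", "D"),
                                  cycle_set = 1L, trials = NULL, seed = 1) {
  tr_train <- select_trials(session$trials, in_seq = TRUE, correct = TRUE,
                            odors = classes)
  tr_train <- tr_train[!(tr_train$trial_id %in% seg$excluded_trials), , drop = FALSE]
  nmin <- min(table(tr_train$odor))
  with_seed(seed + 7L, {
    keep <- unlist(lapply(split(seq_len(nrow(tr_train)), tr_train$odor),
                          function(ix) sample(ix, nmin)))
  })
  tr_train <- tr_train[sort(keep), , drop = FALSE]
  obs1 <- seg$cycles[seg$cycles$cycle == 1 &
                       seg$cycles$trial_id %in% tr_train$trial_id, ]
  h1 <- cycle_phase_hists(session, seg, obs1)
  Xtr <- trough_rates(h1)
  ytr <- factor(tr_train$odor[match(obs1$trial_id, tr_train$trial_id)],
                levels = classes)
  trials <- trials %||% tr_train
  obs <- seg$cycles[seg$cycles$cycle %in% cycle_set &
                      seg$cycles$trial_id %in% trials$trial_id, ]
  h <- cycle_phase_hists(session, seg, obs)
  rates <- sliding_phase_rates(h)
  nb <- dim(rates)[3]
  out <- list()
  for (j in seq_along(h$neuron_ids)) {
    x <- Xtr[, j]
    if (sd(x) == 0) next
    df <- data.frame(y = ytr, x = x)
    fit <- tryCatch(nnet::multinom(y ~ x, data = df, trace = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    newx <- data.frame(x = as.numeric(rates[, j, ]))
    pr <- predict(fit, newdata = newx, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-class fallback
    arr <- array(as.numeric(pr), dim = c(nrow(obs), nb, ncol(pr)),
                 dimnames = list(NULL, NULL, colnames(pr)))
    out[[h$neuron_ids[j]]] <- arr
  }
  list(probs = out, info = obs, classes = classes)
}

#' Single-cell phase map and diagonal permutation test
#'
#' Trains a univariate logistic decoder per neuron (cycle-1 trough rates),
#' z-normalizes each stimulus role's decoding across bins and trials, screens
#' neurons for phase modulation (one-way ANOVA of decoded probability across
#' the three phase windows at `alpha` for at least one odor), classifies each
#' phase bin's decoded role by highest mean z, and quantifies the diagonal
#' (past at descending, present at trough, future at ascending) by the
#' correlation between phase index and role index over neurons, with a
#' permutation test shuffling decoded roles within each phase bin.
#'
#' @param session,seg,classes as elsewhere.
#' @param alpha phase-modulation screen level.
#' @param n_perm,seed permutation test parameters.
#' @return list(map = proportion matrix (3 phases x 3 roles), per_bin
#'   proportions (36 x 3), diag_cor, p, n_neurons, n_modulated).
#' @export
single_cell_phase_map <- function(session, seg, classes = c("A", "B", "C", "D"),
                                  alpha = 0.05, n_perm = 1000, seed = 1) {
  sc <- single_cell_decodings(session, seg, classes, cycle_set = 1L)
  if (!length(sc$probs)) stop("single_cell_phase_map: no phase-modulated neurons")
  trials <- session$trials
  tr <- trials[match(sc$info$trial_id, trials$trial_id), ]
  odors <- c("A", "B", "C", "D", "E")
  past <- odors[pmax(tr$position - 1, 1)]
  future <- odors[pmin(tr$position + 1, 5)]
  present <- tr$odor
  keep <- tr$position > 1 & tr$position < 5 &
    past %in% classes & future %in% classes & present %in% classes
  phase_of_bin <- findInterval((seq_len(36) - 1) * 10, c(0, 120, 240))
  roles <- c("past", "present", "future")
  role_by_phase <- list(); modulated <- character(0)
  for (nm in names(sc$probs)) {
    arr <- sc$probs[[nm]][keep, , , drop = FALSE]
    role_p <- vapply(seq_len(3), function(k) {
      od <- switch(k, past[keep], present[keep], future[keep])
      m <- arr[cbind(rep(seq_len(dim(arr)[1]), dim(arr)[2]),
                     rep(seq_len(dim(arr)[2]), each = dim(arr)[1]),
                     rep(match(od, dimnames(arr)[[3]]), dim(arr)[2]))]
      matrix(m, dim(arr)[1], dim(arr)[2])
    }, matrix(0, sum(keep), 36))
    # z-normalize each role over all bins and trials
    z <- role_p
    for (k in 1:3) {
      v <- role_p[, , k]
      z[, , k] <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    }
    # phase-modulation screen on decoded class probabilities
    pmod <- vapply(dimnames(arr)[[3]], function(cl) {
      pc <- sc$probs[[nm]][keep, , cl]
      d <- data.frame(p = as.numeric(pc),
                      ph = factor(rep(phase_of_bin, each = nrow(pc))))
      if (sd(d$p, na.rm = TRUE) == 0) return(1)
      summary(aov(p ~ ph, data = d))[[1]][["Pr(>F)"]][1]
    }, numeric(1))
    if (!any(pmod < alpha, na.rm = TRUE)) next
    modulated <- c(modulated, nm)
    mz <- apply(z, c(2, 3), mean, na.rm = TRUE)  # 36 x 3 mean z
    # decoded role per phase window = argmax mean z within the window
    rbp <- vapply(1:3, function(phz)
      which.max(colMeans(mz[phase_of_bin == phz, , drop = FALSE])), integer(1))
    role_by_phase[[nm]] <- rbp
  }
  if (!length(role_by_phase)) stop("single_cell_phase_map: no phase-modulated neurons")
  M <- do.call(rbind, role_by_phase)  # neurons x 3 phases, entries role idx
  map <- t(vapply(1:3, function(phz)
    tabulate(M[, phz], 3) / nrow(M), numeric(3)))
  dimnames(map) <- list(c("descending", "trough", "ascending"), roles)
  obs_cor <- cor(rep(1:3, each = nrow(M)), as.numeric(M))
  # null: disturb the phase assignment while keeping each neuron's set of
  # decoded stimuli (permute every neuron's decoded roles across phases)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Mp <- t(apply(M, 1, function(r) r[sample.int(3)]))
    cor(rep(1:3, each = nrow(Mp)), as.numeric(Mp))
  }, numeric(1)))
  p <- (1 + sum(null >= obs_cor)) / (n_perm + 1)
  list(map = map, diag_cor = obs_cor, p = p,
       n_neurons = length(sc$probs), n_modulated = nrow(M))
}

#' Spike-phase precession statistics per neuron
#'
#' Circular-linear correlation between spike phase and normalized time within
#' the odor presentation (port entry to withdrawal), per neuron, pooled over
#' the included trials; neurons with fewer than `min_spikes` spikes are
#' skipped.
#'
#' @param session,seg as elsewhere.
#' @param trials trials included (typically correct InSeq odors B-D).
#' @param min_spikes minimum spikes per neuron.
#' @param alpha significance threshold reported (study used 0.01).
#' @return data.frame(neuron_id, n_spikes, rho, p, slope_deg,
#'   significant).
#' @export
spike_phase_precession <- function(session, seg, trials, min_spikes = 10,
                                   alpha = 0.01) {
  ph <- seg$phase
  res <- lapply(names(session$neurons), function(nm) {
    st <- session$neurons[[nm]]
    phs <- numeric(0); tim <- numeric(0)
    for (i in seq_len(nrow(trials))) {
      sp <- st[st >= trials$poke_in[i] & st < trials$poke_out[i]]
      if (!length(sp)) next
      si <- pmax(1L, pmin(length(ph$phase_deg), round((sp - ph$t0) * ph$fs) + 1L))
      phs <- c(phs, ph$phase_deg[si])
      tim <- c(tim, (sp - trials$poke_in[i]) /
                 (trials$poke_out[i] - trials$poke_in[i]))
    }
    if (length(phs) < min_spikes) {
      sm_log("spike_phase_precession: %s skipped (<%d spikes)", nm, min_spikes)
      return(NULL)
    }
    cl <- circ_lin_cor(phs, tim, slope_bound = 2)
    data.frame(neuron_id = nm, n_spikes = length(phs), rho = cl$rho,
               p = cl$p, slope_deg = cl$slope_deg_per_unit)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("spike_phase_precession: no neuron met the spike criterion")
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Ensemble precession of present-stimulus decoding across cycles
#'
#' Aggregates single-neuron present-stimulus decodings per 10-degree bin and
#' cycle (z-scored across neurons within each bin, summed), finds the phase
#' of peak decoding per cycle (values min-max normalized to [-1, 1] per
#' cycle), and correlates peak phase with cycle index. The null permutes the
#' order of theta cycles within each trial.
#'
#' @param session,seg,classes as elsewhere.
#' @param cycle_set cycles used (default -3..6 excluding 0).
#' @param n_perm,seed permutation parameters.
#' @return list(peaks = data.frame(cycle, peak_phase_deg), cor, p,
#'   profile = normalized bin x cycle matrix).
#' @export
ensemble_precession <- function(session, seg, classes = c("A", "B", "C", "D"),
                                cycle_set = c(-3:-1, 1:6), n_perm = 1000,
                                seed = 1) {
  trials <- select_trials(session$trials, in_seq = TRUE, correct = TRUE,
                          odors = c("B", "C"))
  sc <- single_cell_decodings(session, seg, classes, cycle_set, trials)
  if (!length(sc$probs)) stop("ensemble_precession: no usable neurons")
  info <- sc$info
  present <- trials$odor[match(info$trial_id, trials$trial_id)]
  # present-stimulus probability per neuron: [obs, bin]
  pp <- lapply(sc$probs, function(arr) {
    m <- arr[cbind(rep(seq_len(dim(arr)[1]), dim(arr)[2]),
                   rep(seq_len(dim(arr)[2]), each = dim(arr)[1]),
                   rep(match(present, dimnames(arr)[[3]]), dim(arr)[2]))]
    matrix(m, dim(arr)[1], dim(arr)[2])
  })
  cycles <- sort(unique(info$cycle))
  # stack all neurons' [obs x 36] probability matrices side by side so each
  # permutation reduces to one cross-product with a cycle indicator matrix
  BM <- do.call(cbind, pp)               # obs x (36 * n_neurons)
  BM[is.na(BM)] <- 0
  nn <- length(pp)
  agg_profile <- function(cycle_of_obs) {
    G <- outer(cycle_of_obs, cycles, `==`) * 1
    cnt <- colSums(G)
    means <- crossprod(G, BM) / pmax(cnt, 1)     # ncyc x (36 * nn)
    prof <- matrix(NA_real_, 36, length(cycles), dimnames = list(NULL, cycles))
    for (ci in seq_along(cycles)) {
      if (cnt[ci] == 0) next
      percell <- matrix(means[ci, ], nrow = 36)  # 36 x neurons
      # put neurons on a common scale (z per neuron over the cycle's bins),
      # then sum across neurons for the population decoding strength
      z <- scale(percell)
      z[, !is.finite(attr(z, "scaled:scale")) | attr(z, "scaled:scale") == 0] <- 0
      prof[, ci] <- rowSums(z, na.rm = TRUE)
    }
    prof
  }
  norm_prof <- function(prof) {
    apply(prof, 2, function(v) {
      if (all(is.na(v))) return(v)
      r <- range(v, na.rm = TRUE)
      if (diff(r) == 0) return(v * 0)
      2 * (v - r[1]) / diff(r) - 1
    })
  }
  peak_cor <- function(cycle_of_obs) {
    prof <- norm_prof(agg_profile(cycle_of_obs))
    pk <- apply(prof, 2, function(v) if (all(is.na(v))) NA else
      (which.max(v) - 1) * 10)
    ok <- !is.na(pk)
    if (sum(ok) < 3) return(list(cor = NA_real_, peaks = pk, prof = prof))
    list(cor = cor(seq_along(cycles)[ok], pk[ok]), peaks = pk, prof = prof)
  }
  obs_res <- peak_cor(info$cycle)
  # null: permute cycle order within each trial
  tid <- unique(info$trial_id)
  with_seed(seed, {
    perm_res <- lapply(seq_len(n_perm), function(i) {
      cyc_p <- info$cycle
      for (t1 in tid) {
        ix <- which(info$trial_id == t1)
        cyc_p[ix] <- info$cycle[ix][sample.int(length(ix))]
      }
      r <- peak_cor(cyc_p)
      list(cor = r$cor, peaks = r$peaks)
    })
  })
  null <- vapply(perm_res, `[[`, numeric(1), "cor")
  perm_peaks <- do.call(rbind, lapply(perm_res, `[[`, "peaks"))
  null_ok <- null[!is.na(null)]
  p <- (1 + sum(null_ok <= obs_res$cor)) / (length(null_ok) + 1) # one-sided: negative
  list(peaks = data.frame(cycle = cycles, peak_phase_deg = obs_res$peaks),
       cor = obs_res$cor, p = p, profile = obs_res$prof, null = null,
       perm_peaks = perm_peaks)
}
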
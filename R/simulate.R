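#' Generator configuration for synthetic sessions
#'
#' Defaults emulate the recorded task structure: five-odor sequences (ABCDE),
#' position 1 always InSeq odor A, 1.2 s InSeq holds, OutSeq withdrawals of
#' 0.75 +/- 0.23 s, inter-odor intervals log-normal with 5 s median floored
#' at 0.8 s, odor-specific Poisson time cells whose in-field gain decays as
#' `rho^|lag|` with sequence lag, theta-band LFP at 6 Hz with von Mises phase
#' gating of theta-coding neurons (past/present/future lobes at 60/180/300
#' degrees), optional phase precession, outcome-modulated units, pre-entry
#' predictive coding of the expected odor, optional within-trial reactivation
#' of upcoming odors, and injectable sharp-wave-ripple transients.
#'
#' @param ... overrides of any default field.
#' @return list of class `seqmem_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_neurons = 60, n_tetrodes = 4, n_sequences = 40,
    odors = c("A", "B", "C", "D", "E"),
    p_outseq = 0.15,            # per position 2-5; ~half of sequences all-InSeq
    p_incorrect = 0.10,         # OutSeq error rate
    p_incorrect_inseq = 0.02,   # InSeq errors are rare (anticipation)
    inseq_hold = 1.2,
    outseq_hold_mean = 0.75, outseq_hold_sd = 0.23,
    iti_median = 5, iti_sdlog = 0.4, iti_floor = 0.8,
    inter_seq_gap = 12,
    # time-cell tuning
    peak_rate_range = c(5, 25), baseline_range = c(0.5, 2),
    sigma_range = c(0.05, 0.2), rho = 0.6,
    # partial remapping: on a non-preferred odor the field center shifts by a
    # fixed per-(neuron, odor) offset with sd = field_jitter * (1-rho) * |lag|
    # (zero when rho = 1, so the lag symmetry invariant is preserved)
    field_jitter = 0.3,
    # theta / phase coding
    theta_freq = 6, theta_amp = 100, lfp_noise_sd = 30,
    theta_frac = 0.6, role_probs = c(past = 0.25, present = 0.5, future = 0.25),
    kappa = 3, phase_past = 60, phase_present = 180, phase_future = 300,
    theta_lobe_gain = 0.7, precession_slope = 0,
    # outcome and predictive coding
    frac_outcome = 0.2, outcome_gain = 0.5,
    pretrial_gain = 0.6, pretrial_window = 0.3, incorrect_pretrial_factor = 0.15,
    pretrial_phase = NA_real_,
    # within-trial reactivation of neighboring odors (off by default)
    react_gain = 0, react_decay = 0.6,
    # sharp-wave ripples (off by default)
    swr_rate = 0, swr_amp_sd = 6, swr_freq = 180, swr_dur = 0.06,
    sharpwave_dur = 0.05,
    # balanced tuning: assign preferred odors (and theta roles) round-robin
    # instead of at random, equalizing carriers per odor x role cell class
    balanced_tuning = FALSE,
    sample_rate_lfp = 1000
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$rho > 0, cfg$rho <= 1,
            all(unlist(cfg[c("p_outseq", "p_incorrect", "p_incorrect_inseq")]) >= 0),
            all(unlist(cfg[c("p_outseq", "p_incorrect", "p_incorrect_inseq")]) <= 1),
            cfg$inseq_hold > 0, cfg$kappa >= 0,
            all(cfg$peak_rate_range >= 0), all(cfg$baseline_range >= 0))
  structure(cfg, class = "seqmem_config")
}

odor_index <- function(odor, odors = c("A", "B", "C", "D", "E")) {
  match(odor, odors)
}

#' Preset: fully phase-coded ensemble for theta-sequence analyses
#'
#' A [sim_config()] preset in which every neuron is theta-coded with
#' past/present/future roles in equal proportion at 60/180/300 degrees,
#' tuning is balanced across odor x role cell classes, fields are wide enough
#' to cover early in-trial theta cycles, and ensembles are sized like the
#' recorded ones (120 units).
#'
#' @param ... further overrides passed to [sim_config()].
#' @return `seqmem_config`.
#' @export
phase_coded_config <- function(...) {
  sim_config(n_neurons = 120, kappa = 6, theta_frac = 1,
             theta_lobe_gain = 1, p_outseq = 0.1, p_incorrect = 0.05,
             peak_rate_range = c(15, 35), rho = 0.4, balanced_tuning = TRUE,
             sigma_range = c(0.15, 0.35), pretrial_phase = 180,
             pretrial_window = 0.6, field_jitter = 0,
             role_probs = c(past = 1, present = 1, future = 1) / 3, ...)
}

#' Simulate the trial table of a session
#'
#' Sequences of 5 positions; position 1 always odor A InSeq; OutSeq
#' substitutions at positions 2-5 with probability `p_outseq`; an incorrect
#' response terminates the sequence. Holds: InSeq correct >= 1.2 s (until the
#' tone), OutSeq correct withdrawals drawn from a truncated normal, errors
#' mirrored. Inter-odor intervals are log-normal with a hard floor.
#'
#' @param config `seqmem_config`.
#' @param seed integer seed.
#' @return trial table (see [new_session()]).
#' @export
simulate_trials <- function(config, seed = 1) {
  cfg <- config
  p_out <- rep(cfg$p_outseq, length.out = 4)
  with_seed(seed, {
    rows <- list(); t_now <- 5; trial_i <- 0
    for (sq in seq_len(cfg$n_sequences)) {
      for (pos in 1:5) {
        expected <- cfg$odors[pos]
        if (pos == 1) {
          odor <- "A"; in_seq <- TRUE
        } else if (runif(1) < p_out[pos - 1]) {
          odor <- sample(setdiff(cfg$odors, expected), 1); in_seq <- FALSE
        } else {
          odor <- expected; in_seq <- TRUE
        }
        correct <- runif(1) >= if (in_seq) cfg$p_incorrect_inseq else cfg$p_incorrect
        # hold duration by response type: a "hold" response (>= 1.2 s) is
        # correct on InSeq and incorrect on OutSeq; a withdrawal (< 1.2 s)
        # is the reverse.
        held <- (in_seq && correct) || (!in_seq && !correct)
        hold <- if (held) cfg$inseq_hold + runif(1, 0.005, 0.08)
                else {
                  h <- rnorm(1, cfg$outseq_hold_mean, cfg$outseq_hold_sd)
                  min(max(h, 0.3), cfg$inseq_hold - 0.02)
                }
        trial_i <- trial_i + 1
        rows[[trial_i]] <- data.frame(
          trial_id = sprintf("t%04d", trial_i),
          sequence_id = sprintf("s%03d", sq),
          position = pos, odor = odor, in_seq = in_seq,
          poke_in = t_now, poke_out = t_now + hold, correct = correct,
          stringsAsFactors = FALSE)
        t_now <- t_now + hold +
          max(cfg$iti_floor, rlnorm(1, log(cfg$iti_median), cfg$iti_sdlog))
        if (!correct) break  # an error terminates the sequence
      }
      t_now <- t_now + cfg$inter_seq_gap
    }
    do.call(rbind, rows)
  })
}

draw_neuron_params <- function(cfg) {
  n <- cfg$n_neurons
  roles <- rep("none", n)
  if (cfg$balanced_tuning) {
    n_theta <- round(cfg$theta_frac * n)
    is_theta <- seq_len(n) <= n_theta
    roles[is_theta] <- names(cfg$role_probs)[
      ((seq_len(n_theta) - 1) %/% length(cfg$odors)) %% length(cfg$role_probs) + 1]
    prefs <- rep(cfg$odors, length.out = n)
  } else {
    is_theta <- runif(n) < cfg$theta_frac
    roles[is_theta] <- sample(names(cfg$role_probs), sum(is_theta),
                              replace = TRUE, prob = cfg$role_probs)
    prefs <- sample(cfg$odors[1:5], n, replace = TRUE)
  }
  out <- data.frame(
    neuron_id = sprintf("n%03d", seq_len(n)),
    tetrode = sprintf("T%d", ((seq_len(n) - 1) %% cfg$n_tetrodes) + 1),
    pref_odor = prefs,
    t0 = runif(n, 0, cfg$inseq_hold),
    sigma = runif(n, cfg$sigma_range[1], cfg$sigma_range[2]),
    peak = runif(n, cfg$peak_rate_range[1], cfg$peak_rate_range[2]),
    baseline = runif(n, cfg$baseline_range[1], cfg$baseline_range[2]),
    theta_role = roles,
    outcome_mod = runif(n) < cfg$frac_outcome,
    stringsAsFactors = FALSE)
  # raw per-odor remapping offsets (scaled at emission time by
  # field_jitter * (1 - rho) * |lag to preferred odor|)
  for (o in cfg$odors) out[[paste0("dz_", o)]] <- rnorm(n)
  out
}

# true theta phase in degrees at time t (0 = peak of the cosine carrier)
true_phase_deg <- function(t, freq) (360 * freq * t) %% 360

#' Simulate spike trains given a trial table
#'
#' Inhomogeneous Poisson emission by exact thinning on each trial segment
#' plus homogeneous baseline firing across the whole session. In-trial rate
#' for a
#' neuron preferring odor q on a trial of odor o:
#' `baseline + peak * rho^|lag(o, q)| * exp(-(t - t0)^2 / (2 sigma^2))`,
#' multiplied for theta-coding neurons by a unit-mean von Mises phase factor
#' (preferred phase shifted by the precession slope per cycle). Neurons with
#' a past/future role carry an additional lobe at 60/300 degrees gated by the
#' previous/upcoming odor; outcome-modulated neurons change gain after
#' poke_out on incorrect trials; pre-entry predictive coding of the expected
#' odor is degraded on incorrect trials.
#'
#' @param config `seqmem_config`.
#' @param trials trial table from [simulate_trials()].
#' @param seed integer seed.
#' @param params optional pre-drawn neuron parameter table.
#' @return list(neurons, truth): named spike-time list plus ground-truth
#'   parameters (never read by the analysis modules).
#' @export
simulate_spikes <- function(config, trials, seed = 1, params = NULL) {
  cfg <- config
  with_seed(seed + 1L, {
    if (is.null(params)) params <- draw_neuron_params(cfg)
    n <- nrow(params)
    t_end <- max(trials$poke_out) + 5
    dt <- 0.001
    role_phase <- c(past = cfg$phase_past, present = cfg$phase_present,
                    future = cfg$phase_future)
    # expected (InSeq) odor of each trial position, and sequence context
    trials$expected <- cfg$odors[trials$position]
    prev_odor <- rep(NA_character_, nrow(trials))
    for (i in seq_len(nrow(trials)))
      if (trials$position[i] > 1) prev_odor[i] <- cfg$odors[trials$position[i] - 1]
    next_odor <- ifelse(trials$position < 5, cfg$odors[pmin(trials$position + 1, 5)], NA)

    neurons <- vector("list", n)
    names(neurons) <- params$neuron_id
    for (j in seq_len(n)) {
      pj <- params[j, ]
      # homogeneous baseline across the session
      base_spk <- {
        nb <- rpois(1, pj$baseline * t_end)
        sort(runif(nb, 0, t_end))
      }
      extra <- numeric(0)
      vmax <- if (cfg$kappa > 0) exp(cfg$kappa) / besselI(cfg$kappa, 0) else 1
      lag_to_pref <- function(od) abs(odor_index(od, cfg$odors) -
                                      odor_index(pj$pref_odor, cfg$odors))
      # field center for a given odor context: preferred-odor center plus a
      # lag-graded partial-remapping shift (zero at rho = 1)
      field_of <- function(od, t_eval) {
        t0e <- pj$t0 + cfg$field_jitter * (1 - cfg$rho) * lag_to_pref(od) *
          pj[[paste0("dz_", od)]]
        exp(-((t_eval - t0e)^2) / (2 * pj$sigma^2))
      }
      # exact thinning on each disjoint trial segment: candidates drawn at
      # the segment's rate bound, accepted at lam(t) / bound
      thin <- function(t_lo, t_hi, bound, lam_at) {
        if (bound <= 1e-9 || t_hi <= t_lo) return(numeric(0))
        m <- rpois(1, bound * (t_hi - t_lo))
        if (m == 0) return(numeric(0))
        tu <- runif(m, t_lo, t_hi)
        tu[runif(m) < lam_at(tu) / bound]
      }
      for (i in seq_len(nrow(trials))) {
        tr <- trials[i, ]
        hold <- tr$poke_out - tr$poke_in
        g_pres <- cfg$rho^lag_to_pref(tr$odor)
        eff <- if (pj$theta_role == "past") prev_odor[i] else
          if (pj$theta_role == "future") next_odor[i] else NA
        g2 <- if (!is.na(eff)) cfg$rho^lag_to_pref(eff) else 0
        pi_ <- odor_index(pj$pref_odor, cfg$odors)
        k_re <- pi_ - tr$position
        # odor-period rate (relative time in [0, hold))
        lam_odor <- function(trel) {
          tt <- tr$poke_in + trel
          phase <- true_phase_deg(tt, cfg$theta_freq)
          cyc <- floor(trel * cfg$theta_freq)
          lam <- numeric(length(trel))
          f1 <- field_of(tr$odor, trel)
          if (pj$theta_role == "none") {
            lam <- lam + pj$peak * g_pres * f1
          } else {
            mu <- cfg$phase_present + cfg$precession_slope * cyc
            vm <- exp(cfg$kappa * cos((phase - mu) * pi / 180)) /
              besselI(cfg$kappa, 0)
            lam <- lam + pj$peak * g_pres * f1 * vm
            if (!is.na(eff)) {
              mu2 <- role_phase[[pj$theta_role]] + cfg$precession_slope * cyc
              vm2 <- exp(cfg$kappa * cos((phase - mu2) * pi / 180)) /
                besselI(cfg$kappa, 0)
              # reactivated (past/future) lobe: time field of the reactivated
              # odor, so off-phase population patterns mirror the trough
              # pattern of that odor's own trials
              lam <- lam + pj$peak * cfg$theta_lobe_gain * g2 *
                field_of(eff, trel) * vm2
            }
          }
          # within-trial reactivation: upcoming odors ramp up, past odor fades
          if (cfg$react_gain > 0) {
            ramp <- pmin(pmax(trel / cfg$inseq_hold, 0), 1)
            if (k_re %in% c(1, 2))
              lam <- lam + pj$peak * cfg$react_gain *
                cfg$react_decay^(k_re - 1) * ramp
            if (k_re == -1)
              lam <- lam + pj$peak * cfg$react_gain * (1 - ramp)
          }
          lam
        }
        vm_bound <- if (pj$theta_role == "none") 1 else vmax
        b_odor <- pj$peak * g_pres * vm_bound +
          (if (!is.na(eff)) pj$peak * cfg$theta_lobe_gain * g2 * vmax else 0) +
          (if (cfg$react_gain > 0 && k_re %in% c(-1, 1, 2))
            pj$peak * cfg$react_gain * cfg$react_decay^max(k_re - 1, 0) else 0)
        extra <- c(extra, tr$poke_in +
                     thin(0, hold, b_odor, lam_odor))
        # pre-entry predictive coding: the whole ensemble pre-activates a
        # scaled preview of the expected odor's evoked pattern (each cell at
        # its rho-graded gain and early-field time course), so anticipatory
        # population vectors resemble the upcoming odor's evoked vectors
        if (cfg$pretrial_gain > 0) {
          g_exp <- cfg$rho^lag_to_pref(tr$expected)
          fac <- if (tr$correct) 1 else cfg$incorrect_pretrial_factor
          lam_pre <- function(trel) {
            preview <- field_of(tr$expected, trel + cfg$pretrial_window + 0.15)
            g <- cfg$pretrial_gain * pj$peak * g_exp * fac * preview
            if (is.na(cfg$pretrial_phase)) return(g)
            tt <- tr$poke_in + trel
            cyc <- floor(trel * cfg$theta_freq)
            mu_pre <- cfg$pretrial_phase + cfg$precession_slope * cyc
            g * exp(cfg$kappa * cos((true_phase_deg(tt, cfg$theta_freq) -
                                       mu_pre) * pi / 180)) /
              besselI(cfg$kappa, 0)
          }
          b_pre <- cfg$pretrial_gain * pj$peak * g_exp * fac *
            (if (is.na(cfg$pretrial_phase)) 1 else vmax)
          extra <- c(extra, tr$poke_in +
                       thin(-cfg$pretrial_window, 0, b_pre, lam_pre))
        }
        # outcome modulation after withdrawal on incorrect trials
        if (pj$outcome_mod && !tr$correct) {
          b_out <- cfg$outcome_gain * pj$peak
          extra <- c(extra, tr$poke_in +
                       thin(hold, hold + 0.5, b_out,
                            function(trel) rep(b_out, length(trel))))
        }
      }
      neurons[[j]] <- sort(c(base_spk, extra))
    }
    truth <- list(params = params,
                  trial_labels = trials[, c("trial_id", "expected", "correct")],
                  theta = list(freq = cfg$theta_freq, phase0_deg = 0),
                  precession_slope = cfg$precession_slope)
    list(neurons = neurons, truth = truth)
  })
}

#' Simulate LFP channels given a trial table
#'
#' Each tetrode carries a sinusoidal theta carrier at the configured
#' frequency plus Gaussian noise. Tetrode T1 is designated the theta channel
#' (slightly larger theta amplitude); T2 the ripple channel and T3 (or T2
#' when fewer tetrodes) the sharp-wave channel. When `swr_rate > 0`,
#' ripple bursts (Gaussian-windowed `swr_freq` sinusoids) and co-timed
#' sharp-wave deflections of `swr_amp_sd` background-SD amplitude are
#' injected at Poisson event times and recorded in the ground truth.
#'
#' @param config `seqmem_config`.
#' @param trials trial table (defines the session span).
#' @param seed integer seed.
#' @param duration optional total duration (s); default covers all trials.
#' @return list(lfp, swr_truth, roles): named channel list, injected event
#'   table, and the designated tetrode roles.
#' @export
simulate_lfp <- function(config, trials, seed = 1, duration = NULL) {
  cfg <- config
  with_seed(seed + 2L, {
    fs <- cfg$sample_rate_lfp
    t_end <- duration %||% (max(trials$poke_out) + 5)
    nsamp <- ceiling(t_end * fs)
    tt <- (seq_len(nsamp) - 1) / fs
    tets <- sprintf("T%d", seq_len(cfg$n_tetrodes))
    roles <- list(theta_tetrode = tets[1],
                  ripple_tetrode = tets[min(2, length(tets))],
                  sharpwave_tetrode = tets[min(3, length(tets))])
    theta <- cos(2 * pi * cfg$theta_freq * tt)
    lfp <- list()
    for (k in seq_along(tets)) {
      amp <- cfg$theta_amp * if (tets[k] == roles$theta_tetrode) 1.2 else 0.8
      lfp[[tets[k]]] <- list(samples = amp * theta + rnorm(nsamp, 0, cfg$lfp_noise_sd),
                             t0 = 0)
    }
    swr <- data.frame(start = numeric(0), end = numeric(0))
    if (cfg$swr_rate > 0 && cfg$lfp_noise_sd > 0) {
      n_ev <- rpois(1, cfg$swr_rate * (t_end - 4))
      centers <- sort(runif(n_ev, 2, t_end - 2))
      # enforce a minimum separation so injected events stay resolvable
      if (length(centers) > 1)
        centers <- centers[c(TRUE, diff(centers) > 0.5)]
      # event amplitude is specified in SD units of the channel background
      # (theta carrier plus noise), not of the noise alone
      sd_rip <- sd(lfp[[roles$ripple_tetrode]]$samples)
      sd_sw <- sd(lfp[[roles$sharpwave_tetrode]]$samples)
      for (ct in centers) {
        # ripple burst
        wi <- which(abs(tt - ct) <= cfg$swr_dur)
        env <- exp(-0.5 * ((tt[wi] - ct) / (cfg$swr_dur / 3))^2)
        rip <- cfg$swr_amp_sd * sd_rip * env *
          sin(2 * pi * cfg$swr_freq * (tt[wi] - ct))
        lfp[[roles$ripple_tetrode]]$samples[wi] <-
          lfp[[roles$ripple_tetrode]]$samples[wi] + rip
        # sharp-wave deflection
        wj <- which(abs(tt - ct) <= 2 * cfg$sharpwave_dur)
        sw <- -cfg$swr_amp_sd * sd_sw *
          exp(-0.5 * ((tt[wj] - ct) / (cfg$sharpwave_dur / 2))^2)
        lfp[[roles$sharpwave_tetrode]]$samples[wj] <-
          lfp[[roles$sharpwave_tetrode]]$samples[wj] + sw
        swr <- rbind(swr, data.frame(start = ct - cfg$swr_dur, end = ct + cfg$swr_dur))
      }
    }
    list(lfp = lfp, swr_truth = swr, roles = roles)
  })
}

#' Simulate a complete session with recorded ground truth
#'
#' @param config `seqmem_config`.
#' @param seed integer seed (drives trials, spikes and LFP).
#' @param make_lfp set FALSE to skip LFP synthesis (spike-only analyses).
#' @return list(session, truth); `truth` holds the neuron tuning table, trial
#'   labels, theta phase track parameters and injected SWR intervals.
#' @export
simulate_session <- function(config = sim_config(), seed = 1, make_lfp = TRUE) {
  trials <- simulate_trials(config, seed)
  spk <- simulate_spikes(config, trials, seed)
  lfp <- if (make_lfp) simulate_lfp(config, trials, seed) else
    list(lfp = list(), swr_truth = NULL, roles = list())
  tet <- setNames(spk$truth$params$tetrode, spk$truth$params$neuron_id)
  s <- new_session(
    session_id = sprintf("synthetic-seed%d", seed),
    neurons = spk$neurons, tetrode_of_neuron = tet, lfp = lfp$lfp,
    trials = trials[, c("trial_id", "sequence_id", "position", "odor",
                        "in_seq", "poke_in", "poke_out", "correct")],
    sample_rate_lfp = config$sample_rate_lfp,
    meta = c(lfp$roles, list(generator_seed = seed)))
  truth <- spk$truth
  truth$swr <- lfp$swr_truth
  list(session = s, truth = truth)
}
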
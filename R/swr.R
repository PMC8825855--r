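#' Detect supra-threshold band events in an LFP channel
#'
#' Filters the signal into the requested band (high-pass when `band[2]` is
#' NA), takes the analytic-signal envelope, z-scores it against the
#' whole-channel mean/SD, and returns intervals where the envelope exceeds
#' `threshold_sd`; intervals separated by less than `merge_gap` are merged
#' into a common event.
#'
#' @param samples LFP samples; `fs` sampling rate; `t0` time of first sample.
#' @param band c(lo, hi) Hz; hi = NA for a high-pass filter.
#' @param threshold_sd detection threshold in envelope SD units.
#' @param merge_gap merge gap in seconds (default 0.015).
#' @return data.frame(start, end, peak_z), non-overlapping after merging.
#' @export
detect_band_events <- function(samples, fs = 1000, band = c(150, 250),
                               threshold_sd = 3, merge_gap = 0.015, t0 = 0) {
  if (length(samples) < 2 * fs) stop("detect_band_events: need >= 2 s of signal")
  if (sd(samples) == 0) stop("detect_band_events: constant signal")
  bf <- if (is.na(band[2]))
    signal::butter(2, band[1] / (fs / 2), type = "high")
  else signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, samples)
  env <- Mod(analytic_signal(filt))
  z <- (env - mean(env)) / sd(env)
  above <- z >= threshold_sd
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0),
                                     peak_z = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- data.frame(start = t0 + (starts[r$values] - 1) / fs,
                   end = t0 + ends[r$values] / fs)
  iv <- merge_intervals(iv, merge_gap)
  iv$peak_z <- vapply(seq_len(nrow(iv)), function(i) {
    i0 <- max(1, round((iv$start[i] - t0) * fs) + 1)
    i1 <- min(length(z), round((iv$end[i] - t0) * fs))
    max(z[i0:i1])
  }, numeric(1))
  iv
}

#' Merge intervals separated by less than a gap
#'
#' Idempotent: merging already-merged intervals changes nothing.
#'
#' @param iv data.frame(start, end); `gap` in the same units.
#' @return merged data.frame(start, end), sorted and non-overlapping.
#' @export
merge_intervals <- function(iv, gap = 0.015) {
  if (nrow(iv) == 0) return(iv[, c("start", "end")])
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- list(c(iv$start[1], iv$end[1]))
  for (i in seq_len(nrow(iv))[-1]) {
    last <- out[[length(out)]]
    if (iv$start[i] - last[2] < gap)
      out[[length(out)]] <- c(last[1], max(last[2], iv$end[i]))
    else out[[length(out) + 1]] <- c(iv$start[i], iv$end[i])
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Detect sharp-wave-ripple events
#'
#' A SWR is the temporal overlap of a sharp-wave event (high-pass > 4 Hz) on
#' the designated sharp-wave tetrode and a ripple event (150-250 Hz band) on
#' the designated ripple tetrode; the event boundary is the union (earliest
#' start, latest end) of the overlapping pair.
#'
#' @param session session with `meta$ripple_tetrode` and
#'   `meta$sharpwave_tetrode` designated.
#' @param threshold_sd envelope threshold; `merge_gap` merge gap (s).
#' @return data.frame(start, end, peak_z, sharpwave_tetrode, ripple_tetrode).
#' @export
detect_swr <- function(session, threshold_sd = 3, merge_gap = 0.015) {
  rip_t <- session$meta$ripple_tetrode
  sw_t <- session$meta$sharpwave_tetrode
  if (is.null(rip_t) || is.null(sw_t) ||
      !rip_t %in% names(session$lfp) || !sw_t %in% names(session$lfp))
    stop("detect_swr: designated sharp-wave/ripple tetrodes missing")
  fs <- session$sample_rate_lfp
  rip <- detect_band_events(session$lfp[[rip_t]]$samples, fs, c(150, 250),
                            threshold_sd, merge_gap, session$lfp[[rip_t]]$t0)
  sw <- detect_band_events(session$lfp[[sw_t]]$samples, fs, c(4, NA),
                           threshold_sd, merge_gap, session$lfp[[sw_t]]$t0)
  if (nrow(rip) == 0 || nrow(sw) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), peak_z = numeric(0),
                      sharpwave_tetrode = character(0), ripple_tetrode = character(0)))
  ev <- list()
  for (i in seq_len(nrow(rip))) {
    ov <- which(sw$start < rip$end[i] & sw$end > rip$start[i])
    for (j in ov)
      ev[[length(ev) + 1]] <- data.frame(
        start = min(rip$start[i], sw$start[j]),
        end = max(rip$end[i], sw$end[j]),
        peak_z = max(rip$peak_z[i], sw$peak_z[j]))
  }
  if (!length(ev))
    return(data.frame(start = numeric(0), end = numeric(0), peak_z = numeric(0),
                      sharpwave_tetrode = character(0), ripple_tetrode = character(0)))
  out <- merge_intervals(do.call(rbind, ev), gap = 0)
  out$peak_z <- vapply(seq_len(nrow(out)), function(i) {
    max(do.call(rbind, ev)$peak_z[do.call(rbind, ev)$start >= out$start[i] - 1e-9 &
                                    do.call(rbind, ev)$end <= out$end[i] + 1e-9])
  }, numeric(1))
  out$sharpwave_tetrode <- sw_t
  out$ripple_tetrode <- rip_t
  out
}

#' Exclude trials that intersect SWR events
#'
#' A trial is removed when any event overlaps the odor period or its flanking
#' windows (default 250 ms before and after).
#'
#' @param trials trial table; `events` data.frame(start, end).
#' @param flank flank width (s) around the odor period.
#' @return list(trials = retained table, report = counts per window,
#'   removed = trial ids).
#' @export
exclude_swr_trials <- function(trials, events, flank = 0.25) {
  hits <- function(lo, hi) vapply(seq_len(nrow(trials)), function(i)
    any(events$start < hi[i] & events$end > lo[i]), logical(1))
  in_odor <- if (nrow(events)) hits(trials$poke_in, trials$poke_out) else
    rep(FALSE, nrow(trials))
  in_pre <- if (nrow(events)) hits(trials$poke_in - flank, trials$poke_in) else
    rep(FALSE, nrow(trials))
  in_post <- if (nrow(events)) hits(trials$poke_out, trials$poke_out + flank) else
    rep(FALSE, nrow(trials))
  bad <- in_odor | in_pre | in_post
  sm_log("exclude_swr_trials: removing %d/%d trials", sum(bad), nrow(trials))
  list(trials = trials[!bad, , drop = FALSE],
       report = c(odor = sum(in_odor), pre = sum(in_pre), post = sum(in_post),
                  removed = sum(bad)),
       removed = trials$trial_id[bad])
}
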
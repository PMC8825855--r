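#' Construct an ensemble recording session
#'
#' A session bundles per-neuron spike times, per-tetrode LFP channels sampled
#' on a fixed grid, and a trial table of odor presentations. All times are in
#' seconds from session start.
#'
#' @param session_id character id.
#' @param neurons named list: neuron id -> numeric vector of ascending spike
#'   times (s).
#' @param tetrode_of_neuron named character vector mapping neuron id ->
#'   tetrode id.
#' @param lfp named list: tetrode id -> list(samples = microvolts, t0 =
#'   start time s).
#' @param trials data.frame with columns trial_id, sequence_id, position
#'   (1-5), odor (A-E), in_seq (logical), poke_in (s), poke_out (s),
#'   correct (logical).
#' @param sample_rate_lfp LFP sampling rate in Hz.
#' @param meta optional list of extra metadata (e.g. designated theta /
#'   sharp-wave / ripple tetrodes, generator config for synthetic sessions).
#' @return object of class `seqmem_session`.
#' @export
new_session <- function(session_id, neurons, tetrode_of_neuron, lfp = list(),
                        trials, sample_rate_lfp = 1000, meta = list()) {
  s <- structure(list(
    session_id = session_id,
    neurons = neurons,
    tetrode_of_neuron = tetrode_of_neuron,
    lfp = lfp,
    trials = trials,
    sample_rate_lfp = sample_rate_lfp,
    meta = meta
  ), class = "seqmem_session")
  validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks: spike times finite, nondecreasing and >= 0; every neuron mapped to
#' exactly one tetrode; poke_out > poke_in; position 1 is odor A and InSeq;
#' poke_in ascending within each sequence; trial events inside the LFP span
#' (when LFP channels are present).
#'
#' @param s a `seqmem_session`.
#' @return the session, invisibly; stops with an informative error otherwise.
#' @export
validate_session <- function(s) {
  tr <- s$trials
  need <- c("trial_id", "sequence_id", "position", "odor", "in_seq",
            "poke_in", "poke_out", "correct")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trials table missing columns: ", paste(miss, collapse = ", "))
  for (id in names(s$neurons)) {
    st <- s$neurons[[id]]
    if (length(st)) {
      if (any(!is.finite(st))) stop("neuron ", id, ": non-finite spike time")
      if (any(st < 0)) stop("neuron ", id, ": negative spike time")
      if (is.unsorted(st)) stop("neuron ", id, ": spike times not ascending")
    }
    if (is.na(s$tetrode_of_neuron[id]))
      stop("neuron ", id, ": no tetrode assignment")
  }
  bad <- which(!(tr$poke_out > tr$poke_in))
  if (length(bad)) stop("trial ", tr$trial_id[bad[1]], ": poke_out <= poke_in")
  p1 <- tr[tr$position == 1, , drop = FALSE]
  bad <- which(!(p1$odor == "A" & p1$in_seq))
  if (length(bad)) stop("trial ", p1$trial_id[bad[1]],
                        ": position 1 must be odor A and InSeq")
  for (sq in unique(tr$sequence_id)) {
    ti <- tr$poke_in[tr$sequence_id == sq]
    if (is.unsorted(ti)) stop("sequence ", sq, ": poke_in times not ascending")
  }
  if (length(s$lfp)) {
    spans <- vapply(s$lfp, function(ch)
      ch$t0 + (length(ch$samples) - 1) / s$sample_rate_lfp, numeric(1))
    t0s <- vapply(s$lfp, function(ch) ch$t0, numeric(1))
    if (any(tr$poke_in < max(t0s)) || any(tr$poke_out > min(spans)))
      stop("trial event times outside LFP span")
  }
  invisible(s)
}

#' @method print seqmem_session
#' @export
print.seqmem_session <- function(x, ...) {
  cat(sprintf("<seqmem_session> %s: %d neurons on %d tetrodes, %d trials, %d LFP channels\n",
              x$session_id, length(x$neurons),
              length(unique(x$tetrode_of_neuron)), nrow(x$trials),
              length(x$lfp)))
  invisible(x)
}

#' Write a session to a directory of plain-text files
#'
#' Layout: `spikes.csv` (neuron_id, spike_time_s), `trials.csv`,
#' `lfp_<tetrode>.csv` (t_s, uv) and `session.json` metadata.
#'
#' @param s session.
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sp <- data.frame(
    neuron_id = rep(names(s$neurons), lengths(s$neurons)),
    spike_time_s = unlist(s$neurons, use.names = FALSE)
  )
  write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  write.csv(s$trials, file.path(path, "trials.csv"), row.names = FALSE)
  for (tet in names(s$lfp)) {
    ch <- s$lfp[[tet]]
    write.csv(data.frame(
      t_s = ch$t0 + seq_along(ch$samples) / s$sample_rate_lfp - 1 / s$sample_rate_lfp,
      uv = ch$samples), file.path(path, paste0("lfp_", tet, ".csv")),
      row.names = FALSE)
  }
  meta <- list(session_id = s$session_id,
               sample_rate_lfp = s$sample_rate_lfp,
               tetrode_of_neuron = as.list(s$tetrode_of_neuron),
               neuron_ids = names(s$neurons),
               meta = s$meta)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a session from a directory written by [write_session()]
#'
#' @param path session directory.
#' @return `seqmem_session`.
#' @export
load_session <- function(path) {
  f <- function(x) file.path(path, x)
  for (x in c("spikes.csv", "trials.csv", "session.json"))
    if (!file.exists(f(x))) stop("missing file: ", f(x))
  meta <- jsonlite::read_json(f("session.json"))
  sp <- read.csv(f("spikes.csv"), stringsAsFactors = FALSE)
  ids <- unlist(meta$neuron_ids)
  neurons <- lapply(setNames(ids, ids), function(id)
    sort(sp$spike_time_s[sp$neuron_id == id]))
  trials <- read.csv(f("trials.csv"), stringsAsFactors = FALSE)
  trials$in_seq <- as.logical(trials$in_seq)
  trials$correct <- as.logical(trials$correct)
  tet <- unlist(meta$tetrode_of_neuron)
  lfp <- list()
  for (fn in list.files(path, pattern = "^lfp_.*\\.csv$")) {
    tid <- sub("^lfp_(.*)\\.csv$", "\\1", fn)
    d <- read.csv(f(fn))
    lfp[[tid]] <- list(samples = d$uv, t0 = d$t_s[1])
  }
  new_session(meta$session_id, neurons, tet, lfp, trials,
              sample_rate_lfp = meta$sample_rate_lfp,
              meta = meta$meta %||% list())
}

#' Filter a trial table by task criteria
#'
#' Criteria follow the study protocol: InSeq/correct flags, odor and position
#' sets, minimum hold duration, removal of edge positions, and restriction to
#' intact sequences (all five positions present, InSeq, consecutively
#' presented and correct). Order is preserved; the before/after counts are
#' logged. An empty result is a warning, not an error.
#'
#' @param trials trial table.
#' @param in_seq,correct logical filters (NULL = no filter).
#' @param odors,positions keep only these odors / positions (NULL = all).
#' @param min_hold minimum poke_out - poke_in in seconds.
#' @param consecutive_inseq if TRUE keep only trials from sequences in which
#'   all 5 odors were InSeq, consecutive, and correctly identified.
#' @param exclude_positions positions to drop (e.g. c(1, 5)).
#' @return filtered trial table.
#' @export
select_trials <- function(trials, in_seq = NULL, correct = NULL, odors = NULL,
                          positions = NULL, min_hold = NULL,
                          consecutive_inseq = FALSE, exclude_positions = NULL) {
  n0 <- nrow(trials)
  keep <- rep(TRUE, n0)
  if (!is.null(in_seq))  keep <- keep & trials$in_seq == in_seq
  if (!is.null(correct)) keep <- keep & trials$correct == correct
  if (!is.null(odors))   keep <- keep & trials$odor %in% odors
  if (!is.null(positions)) keep <- keep & trials$position %in% positions
  if (!is.null(exclude_positions)) keep <- keep & !(trials$position %in% exclude_positions)
  if (!is.null(min_hold)) keep <- keep & (trials$poke_out - trials$poke_in) >= min_hold
  if (consecutive_inseq) {
    ok <- vapply(split(trials, trials$sequence_id), function(d)
      nrow(d) == 5 && all(d$in_seq) && all(d$correct) &&
        all(sort(d$position) == 1:5), logical(1))
    keep <- keep & trials$sequence_id %in% names(ok)[ok]
  }
  out <- trials[keep, , drop = FALSE]
  sm_log("select_trials: %d -> %d trials", n0, nrow(out))
  if (nrow(out) == 0) warning("select_trials: empty selection")
  out
}

#' Windowed spike counts around a trial event
#'
#' Bins are half-open `[t, t + bin)`: a spike exactly at a right edge belongs
#' to the next bin. Total spikes in the window are conserved across bins.
#'
#' @param session session.
#' @param trials trial table (rows define the anchors).
#' @param anchor "poke_in" or "poke_out".
#' @param window c(a, b) in seconds relative to the anchor; `bin` must divide
#'   `b - a` (tolerance 1e-9).
#' @param bin bin width in seconds.
#' @return integer array trial x neuron x bin with dimnames.
#' @export
window_spike_counts <- function(session, trials, anchor = "poke_in",
                                window = c(0, 1.2), bin = 0.1) {
  stopifnot(anchor %in% c("poke_in", "poke_out"))
  nb <- (window[2] - window[1]) / bin
  if (abs(nb - round(nb)) > 1e-9) stop("bin must divide the window length")
  nb <- as.integer(round(nb))
  anchors <- trials[[anchor]]
  if (length(session$lfp)) {
    span <- range(unlist(lapply(session$lfp, function(ch)
      ch$t0 + c(0, (length(ch$samples) - 1) / session$sample_rate_lfp))))
    if (any(anchors + window[1] < span[1] - 1e-9) ||
        any(anchors + window[2] > span[2] + 1e-9))
      stop("window outside recording span")
  }
  ids <- names(session$neurons)
  out <- array(0L, dim = c(nrow(trials), length(ids), nb),
               dimnames = list(trials$trial_id, ids, NULL))
  edges_rel <- window[1] + bin * (0:nb)
  for (j in seq_along(ids)) {
    st <- session$neurons[[ids[j]]]
    if (!length(st)) next
    for (i in seq_along(anchors)) {
      e <- anchors[i] + edges_rel
      # half-open bins: right edge goes to the next bin
      cnt <- findInterval(st, e, left.open = FALSE)
      tb <- tabulate(cnt[cnt >= 1 & cnt <= nb], nbins = nb)
      out[i, j, ] <- tb
    }
  }
  out
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded permutation / subsample stream
#'
#' Shared randomization engine for all permutation tests. Streams are
#' bit-reproducible given (seed, n_perm, scheme, n, size).
#'
#' @param n number of items being permuted.
#' @param n_perm number of draws.
#' @param seed integer seed.
#' @param scheme "label-shuffle", "time-shuffle" or "cycle-order-shuffle"
#'   (all full permutations of 1:n) or "downsample" (subsets of size `size`
#'   drawn without replacement).
#' @param size subset size for the downsample scheme.
#' @return list of `n_perm` integer index vectors.
#' @export
perm_stream <- function(n, n_perm, seed,
                        scheme = c("label-shuffle", "time-shuffle",
                                   "cycle-order-shuffle", "downsample"),
                        size = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  if (scheme == "downsample") {
    if (is.null(size)) stop("downsample scheme needs `size`")
    if (size > n) stop("downsample size exceeds population")
  }
  with_seed(seed, {
    lapply(seq_len(n_perm), function(i) {
      if (scheme == "downsample") sample.int(n, size) else sample.int(n)
    })
  })
}
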
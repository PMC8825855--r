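# shared fixtures: built in code, cached across test files within a run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small default-structure session (spikes only) for generic tests
small_session <- function() cached("small", {
  suppressMessages(simulate_session(
    sim_config(n_neurons = 20, n_sequences = 8),
    seed = 42, make_lfp = FALSE))
})

# small session including LFP (theta + swr channels)
small_lfp_session <- function() cached("small_lfp", {
  suppressMessages(simulate_session(
    sim_config(n_neurons = 15, n_sequences = 6), seed = 43))
})

# hand-built two-neuron session with exactly placed spikes
manual_session <- function(neurons, trials, lfp = list()) {
  tet <- setNames(rep("T1", length(neurons)), names(neurons))
  new_session("manual", neurons, tet, lfp, trials)
}

manual_trials <- function(poke_in, hold = 1.25, odor = "A", position = 1,
                          in_seq = TRUE, correct = TRUE, sequence_id = NULL) {
  n <- length(poke_in)
  data.frame(trial_id = sprintf("t%03d", seq_len(n)),
             sequence_id = sequence_id %||% sprintf("s%03d", seq_len(n)),
             position = rep(position, length.out = n),
             odor = rep(odor, length.out = n),
             in_seq = rep(in_seq, length.out = n),
             poke_in = poke_in,
             poke_out = poke_in + rep(hold, length.out = n),
             correct = rep(correct, length.out = n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
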
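# Fixtures are built in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir().

# A small hand-built session: `n` neurons, `K` trials, deterministic
# spike times (one spike train per neuron per trial laid out on a grid).
make_tiny_session <- function(n = 3, K = 8, iei = 2, padding = 0.1,
                              rate = 10) {
  trials <- lapply(seq_len(K), function(k) {
    t0 <- 5 * k
    spikes <- lapply(seq_len(n), function(j) {
      # regular spikes inside the padded window, phase-offset per neuron
      seq(t0 + 0.01 * j, t0 + iei - 0.01, by = 1 / rate)
    })
    list(trial_id = k, stimulus = STIMULI_TEST[(k - 1) %% 4 + 1],
         outcome = if (k %% 5 == 0) "incorrect" else "correct",
         taste_time = t0, decision_time = t0 + iei, spikes = spikes)
  })
  spike_session("tiny", seq_len(n), trials, padding = padding)
}

STIMULI_TEST <- c("S", "Q", "M", "O")

# Build a fake decoded_states object from a trials x states logical
# detection matrix; each detection becomes one admissible interval with
# a given onset (seconds relative to taste).
fake_decoded <- function(detected, onset = 0.5, bin = 0.002,
                         window_start = -0.1) {
  n_trials <- nrow(detected)
  M <- ncol(detected)
  idx <- which(detected, arr.ind = TRUE)
  onset <- rep_len(onset, nrow(idx))
  start_bin <- floor((onset - window_start) / bin) + 1L
  intervals <- data.frame(trial = idx[, 1], state = idx[, 2],
                          start = onset, end = onset + 0.06,
                          start_bin = start_bin,
                          end_bin = start_bin + 29L)
  intervals <- intervals[order(intervals$trial, intervals$state), ]
  structure(list(posteriors = vector("list", n_trials),
                 intervals = intervals, M = M, bin = bin,
                 window_start = window_start, n_trials = n_trials),
            class = "decoded_states")
}

# Trial-label frame for classification fixtures: `n_cor` correct and
# `n_inc` incorrect trials per stimulus, IEI fixed.
make_labels <- function(n_cor = 40, n_inc = 20, iei = 2.5) {
  stim <- rep(STIMULI_TEST, each = n_cor + n_inc)
  outcome <- rep(rep(c("correct", "incorrect"), c(n_cor, n_inc)), 4)
  data.frame(trial_id = seq_along(stim), stimulus = stim,
             outcome = outcome, taste_time = 0, decision_time = iei,
             iei = iei, direction = stimulus_direction(stim),
             quality = stimulus_quality(stim), stringsAsFactors = FALSE)
}

# Deterministic detection vector: TRUE for round(p * n) of n trials.
det_frac <- function(n, p) {
  k <- round(p * n)
  c(rep(TRUE, k), rep(FALSE, n - k))
}

# Detection column over the make_labels() layout given per-(stimulus,
# outcome) occurrence probabilities (named lists cor/inc by stimulus).
det_pattern <- function(labels, p_cor, p_inc) {
  det <- logical(nrow(labels))
  for (st in STIMULI_TEST) {
    for (out in c("correct", "incorrect")) {
      sel <- labels$stimulus == st & labels$outcome == out
      p <- if (out == "correct") p_cor[[st]] else p_inc[[st]]
      det[sel] <- det_frac(sum(sel), p)
    }
  }
  det
}

# Exhaustive-path log-likelihood for tiny HMMs (oracle for the forward
# algorithm); uniform initial distribution.
brute_force_ll <- function(T, E, obs) {
  M <- nrow(T)
  B <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), B)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    p <- (1 / M) * E[pth[1], obs[1]]
    if (B > 1) for (t in 2:B) p <- p * T[pth[t - 1], pth[t]] *
        E[pth[t], obs[t]]
    tot <- tot + p
  }
  log(tot)
}
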
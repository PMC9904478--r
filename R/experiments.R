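#' Plan for an in-silico behavioural experiment
#'
#' Bundles everything needed to run a set of networks through the
#' four-taste task: the architecture and neuron constants, the number
#' of network instances and trials, the stimulus settings, the HMM
#' search range and the master seed. Trials are balanced across the
#' four tastants; the gate onset is drawn uniformly over [1.1, 1.9] s
#' per trial.
#'
#' @param n_networks Number of independently wired network instances.
#' @param trials_per_network Trials per network (multiple of 4).
#' @param gain Stimulus gain in percent.
#' @param tau_d Stimulus decay time constant in seconds.
#' @param segment Stimulus segment (`"full"`, `"head"`, `"tail"`).
#' @param duration Trial duration in seconds.
#' @param m_range HMM state-number search range for model sessions.
#' @param n_init Baum-Welch initializations per state count.
#' @param net_params A [network_params()] object.
#' @param constants A [neuron_params()] object.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(n_networks = 10, trials_per_network = 100,
                            gain = 60, tau_d = 0.160, segment = "full",
                            duration = 3, m_range = 2:30, n_init = 10,
                            net_params = network_params(),
                            constants = neuron_params(), seed = 1) {
  stopifnot(trials_per_network %% 4 == 0)
  structure(as.list(environment()), class = "experiment_plan")
}

# Simulate one network session: balanced tastes, per-trial gate onsets,
# optional silencing (a silence_pulse, or a function(trial_index,
# cue_onset) -> pulse). Returns spikes, per-trial metadata, and the
# role-cluster rate series used for scoring.
simulate_session <- function(net, constants, n_trials, gain, tau_d,
                             segment = "full", duration = 3,
                             silencing = NULL, seed = 1, v0_list = NULL,
                             gate_onsets = NULL, cue_onsets = NULL) {
  stim <- stimulus_spec(gain = gain, tau_d = tau_d, segment = segment)
  tastes <- rep(STIMULI, length.out = n_trials)
  seeds <- derive_seeds(seed, n_trials + 1)
  gate_onsets <- gate_onsets %||%
    with_seed(seeds[n_trials + 1], runif(n_trials, 1.1, 1.9))
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    sil <- if (is.function(silencing))
      silencing(i, if (is.null(cue_onsets)) NA else cue_onsets[i])
    else silencing
    sp <- simulate_trial(net, constants, stimulus = stim,
                         taste = tastes[i], gate = gate_spec(gate_onsets[i]),
                         silencing = sil, duration = duration,
                         seed = seeds[i],
                         v0 = if (is.null(v0_list)) NULL else v0_list[[i]])
    trials[[i]] <- list(
      spikes = sp,
      rates = cluster_rate_series(sp, net, bin = 0.05),
      taste = tastes[i], gate_onset = gate_onsets[i])
  }
  list(trials = trials, tastes = tastes, gate_onsets = gate_onsets,
       duration = duration,
       v0 = lapply(trials, function(tr) tr$spikes$v0))
}

#' Score a simulated session's behaviour
#'
#' Applies the action-cluster thresholding rule trial by trial: a
#' cluster is on at >= 40% of its maximum rate over the whole session
#' (or at a fixed absolute rate), and the trial outcome follows from
#' which action cluster comes on inside the decision window. Cue-onset
#' times are detected with the same rule applied to the cue clusters.
#'
#' @param sim A session from the internal simulator (see
#'   [run_control()]).
#' @param mode,threshold Thresholding mode and value as in
#'   [cluster_on_intervals()].
#' @param window Decision window in seconds.
#' @param seed Seed for random decisions on ambiguous trials.
#' @return A data frame with one row per trial: `taste`, `direction`
#'   (cued), `decision`, `outcome`, `ambiguous`, `excluded`,
#'   `decision_time` (onset of the chosen action cluster, or the trial
#'   end when no cluster came on), and `cue_onset`.
#' @export
score_session <- function(sim, mode = "relative", threshold = 0.40,
                          window = c(0.5, 3.0), seed = 1) {
  n_trials <- length(sim$trials)
  roles <- c("ActL", "ActR", "CueL", "CueR")
  smax <- sapply(roles, function(r)
    max(vapply(sim$trials, function(tr) max(tr$rates[r, ]), 0)))
  seeds <- derive_seeds(seed, n_trials)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    r <- sim$trials[[i]]$rates
    iv <- lapply(roles, function(ro)
      cluster_on_intervals(r[ro, ], session_max = smax[[ro]], mode = mode,
                           threshold = threshold))
    names(iv) <- roles
    sc <- score_trial(iv$ActL, iv$ActR,
                      stimulus_direction(sim$tastes[i]),
                      window = window, seed = seeds[i])
    chosen <- iv[[if (sc$decision == "left") "ActL" else "ActR"]]
    hit <- chosen[chosen$start < window[2] & chosen$end > window[1], ]
    dtime <- if (nrow(hit)) max(hit$start[1], window[1]) else sim$duration
    rows[[i]] <- data.frame(
      taste = sim$tastes[i],
      direction = stimulus_direction(sim$tastes[i]),
      decision = sc$decision, outcome = sc$scored,
      ambiguous = sc$ambiguous, excluded = sc$excluded_from_coding,
      decision_time = dtime,
      cue_onset = detect_cue_onset(iv$CueL, iv$CueR))
  }
  do.call(rbind, rows)
}

#' Build an ensemble session from a simulated network run
#'
#' Samples one excitatory neuron per cluster (avoiding neurons firing
#' below `min_rate` where possible) and packages the sampled spike
#' trains with the scored behaviour as a [spike_session()]: the taste
#' event is the stimulus onset and the decision event the scored
#' action-cluster onset.
#'
#' @param sim Simulated session (internal structure).
#' @param scored Output of [score_session()].
#' @param net The `synaptic_matrix`.
#' @param min_rate Sampling exclusion threshold in Hz.
#' @param padding Session padding in seconds.
#' @param seed Sampling seed.
#' @param session_id Session identifier.
#' @return A `spike_session` with one trial per simulated trial.
#' @export
sample_model_session <- function(sim, scored, net, min_rate = 2,
                                 padding = 0.1, seed = 1,
                                 session_id = "model") {
  n_clusters <- length(net$role_of_cluster)
  dur <- sim$duration
  # mean rate per E neuron across the session
  counts <- integer(net$n_e + net$n_i)
  for (tr in sim$trials) {
    tb <- tabulate(tr$spikes$neuron, nbins = net$n_e + net$n_i)
    counts <- counts + tb
  }
  rate <- counts / (length(sim$trials) * dur)
  picked <- with_seed(seed, {
    vapply(seq_len(n_clusters), function(cl) {
      mem <- which(net$cluster == cl & !net$is_inh)
      ok <- mem[rate[mem] >= min_rate]
      pool <- if (length(ok)) ok else mem
      pool[sample.int(length(pool), 1)]
    }, integer(1))
  })
  trials <- vector("list", length(sim$trials))
  t_cursor <- 10
  for (i in seq_along(sim$trials)) {
    sp <- sim$trials[[i]]$spikes
    spikes <- lapply(picked, function(nr) {
      s <- sp$time[sp$neuron == nr]
      t_cursor + s
    })
    trials[[i]] <- list(
      trial_id = i, stimulus = sim$tastes[i],
      outcome = scored$outcome[i],
      taste_time = t_cursor,
      decision_time = t_cursor + scored$decision_time[i],
      spikes = spikes)
    t_cursor <- t_cursor + dur + 1
  }
  s <- spike_session(session_id, seq_len(n_clusters), trials,
                     subject = "network", padding = padding)
  attr(s, "sampled_neurons") <- picked
  s
}

#' Run the control experiment on a set of networks
#'
#' For each network instance: simulate the trials, score behaviour,
#' sample a 14-neuron ensemble session, fit and select a spike-train
#' HMM, decode admissible states, classify their coding properties
#' (ambiguous trials excluded), and collect warped onset times of the
#' coding states. Accuracy is summarized per network.
#'
#' @param plan An [experiment_plan()].
#' @param fit_hmms Set `FALSE` to skip the HMM analysis (behaviour
#'   only).
#' @return A list with `performance` (per-network accuracy),
#'   `sessions`, `decodings` (model, decoded, classification, trials),
#'   and `onsets` (pooled warped onsets with coding classes).
#' @export
run_control <- function(plan, fit_hmms = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  seeds <- matrix(derive_seeds(plan$seed, plan$n_networks * 4),
                  plan$n_networks, 4)
  res <- list(performance = NULL, sessions = list(), decodings = list(),
              onsets = NULL)
  perf <- numeric(plan$n_networks)
  onset_pool <- list()
  for (k in seq_len(plan$n_networks)) {
    net <- build_network(plan$net_params, seed = seeds[k, 1])
    sim <- simulate_session(net, plan$constants, plan$trials_per_network,
                            plan$gain, plan$tau_d, plan$segment,
                            duration = plan$duration, seed = seeds[k, 2])
    scored <- score_session(sim, seed = seeds[k, 3])
    perf[k] <- mean(scored$outcome == "correct")
    session <- sample_model_session(sim, scored, net,
                                    seed = seeds[k, 4],
                                    session_id = sprintf("net%02d", k))
    res$sessions[[k]] <- session
    if (!fit_hmms) next
    dec <- analyze_model_session(session, scored, plan, seeds[k, 4])
    res$decodings[[k]] <- dec
    if (!is.null(dec$onsets)) onset_pool[[length(onset_pool) + 1]] <-
      dec$onsets
  }
  res$performance <- data.frame(network = seq_len(plan$n_networks),
                                accuracy = perf)
  if (length(onset_pool)) res$onsets <- do.call(rbind, onset_pool)
  res
}

# HMM analysis of one sampled model session: preprocess, symbolize,
# model selection, decoding, classification, warped onsets.
analyze_model_session <- function(session, scored, plan, seed) {
  sub_seeds <- derive_seeds(seed, 3)
  ps <- preprocess_session(session)
  if (inherits(ps, "session_rejection")) return(list(rejected = TRUE))
  sy <- symbolize(ps, seed = sub_seeds[1])
  model <- select_model(sy, M_range = plan$m_range, n_init = plan$n_init,
                        seed = sub_seeds[2])
  dec <- decode(model, sy)
  tr <- session_trials(session)
  cl <- suppressWarnings(
    classify_states(dec, tr, use_trials = !scored$excluded))
  classes <- coding_class(cl)
  onsets <- if (any(!is.na(classes)))
    warp_onsets(dec, tr, classes) else NULL
  list(model = model, decoded = dec, classification = cl,
       classes = classes, trials = tr, onsets = onsets,
       sequences = sy, rejected = FALSE)
}

#' Repeated-measures ANOVA from sums of squares
#'
#' Within-subject ANOVA for a complete balanced design, computed from
#' the standard sums-of-squares decomposition (subjects = networks).
#' `rm_anova_1way` tests a single within-subject factor;
#' `rm_anova_2way` tests two factors and their interaction, each
#' against its own factor-by-subject error term.
#'
#' @param y Numeric response (e.g. accuracy).
#' @param subject Subject (network) identifier per observation.
#' @param f1,f2 Factor levels per observation.
#' @return A data frame with effect, df, F and p columns.
#' @export
rm_anova_1way <- function(y, subject, f1) {
  subject <- factor(subject); f1 <- factor(f1)
  k <- nlevels(f1); n <- nlevels(subject)
  stopifnot(length(y) == k * n)
  grand <- mean(y)
  m_t <- tapply(y, f1, mean)
  m_s <- tapply(y, subject, mean)
  ss_t <- n * sum((m_t - grand)^2)
  ss_s <- k * sum((m_s - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_t - ss_s
  df_t <- k - 1; df_e <- (k - 1) * (n - 1)
  f <- (ss_t / df_t) / (ss_err / df_e)
  data.frame(effect = "factor", df1 = df_t, df2 = df_e, F = f,
             p = stats::pf(f, df_t, df_e, lower.tail = FALSE))
}

#' @rdname rm_anova_1way
#' @export
rm_anova_2way <- function(y, subject, f1, f2) {
  subject <- factor(subject); f1 <- factor(f1); f2 <- factor(f2)
  a <- nlevels(f1); b <- nlevels(f2); n <- nlevels(subject)
  stopifnot(length(y) == a * b * n)
  grand <- mean(y)
  m_a <- tapply(y, f1, mean); m_b <- tapply(y, f2, mean)
  m_s <- tapply(y, subject, mean)
  m_ab <- tapply(y, list(f1, f2), mean)
  m_as <- tapply(y, list(f1, subject), mean)
  m_bs <- tapply(y, list(f2, subject), mean)
  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  # interaction SS: n * sum over cells of (cell - A - B + grand)^2
  dev_ab <- sweep(sweep(m_ab, 1, m_a, "-"), 2, m_b, "-") + grand
  ss_ab <- n * sum(dev_ab^2)
  ss_as <- b * sum((m_as - outer(m_a, m_s, "+") + grand)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, m_s, "+") + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  eff <- function(name, ss, df1, ss_err, df2) {
    f <- (ss / df1) / (ss_err / df2)
    data.frame(effect = name, df1 = df1, df2 = df2, F = f,
               p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  rbind(
    eff("f1", ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
    eff("f2", ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
    eff("f1:f2", ss_ab, (a - 1) * (b - 1), ss_abs,
        (a - 1) * (b - 1) * (n - 1)))
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Paired t-tests between condition levels within subjects, with
#' p-values multiplied by the number of comparisons (capped at 1).
#'
#' @param y Response vector.
#' @param subject Subject per observation.
#' @param f Condition level per observation.
#' @return A data frame of pairwise comparisons.
#' @export
bonferroni_posthoc <- function(y, subject, f) {
  f <- factor(f); subject <- factor(subject)
  lv <- levels(f)
  pairs <- utils::combn(length(lv), 2)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (q in seq_len(m)) {
    i <- lv[pairs[1, q]]; j <- lv[pairs[2, q]]
    yi <- y[f == i][order(subject[f == i])]
    yj <- y[f == j][order(subject[f == j])]
    d <- yi - yj
    tt <- if (stats::sd(d) == 0) list(p.value = as.numeric(all(d == 0)),
                                      statistic = NA)
    else stats::t.test(d)
    out[[q]] <- data.frame(a = i, b = j, mean_diff = mean(d),
                           p_raw = tt$p.value,
                           p_bonf = min(1, tt$p.value * m))
  }
  do.call(rbind, out)
}

#' Silencing-by-stimulus factorial experiment
#'
#' Runs each network through the conditions {None, Sampling, Delay}
#' silencing crossed with stimulus segments, measuring behavioural
#' accuracy. Sampling silencing is a 100% square pulse over [0, 0.5] s
#' (centre 0.25 s); Delay silencing covers [0.5, 3] s (centre 1.75 s).
#'
#' @param plan An [experiment_plan()] (its `gain`, `tau_d` apply).
#' @param segments Stimulus segments to cross with silencing.
#' @param silencing Conditions to run, a subset of
#'   `c("None", "Sampling", "Delay")`.
#' @return A list with `accuracy` (long data frame: network, silencing,
#'   segment, accuracy), the fitted `anova` table (2-way repeated
#'   measures when both factors vary, else 1-way), and Bonferroni
#'   post-hoc comparisons across silencing levels.
#' @export
run_silencing_grid <- function(plan,
                               segments = c("full", "head", "tail"),
                               silencing = c("None", "Sampling",
                                             "Delay")) {
  stopifnot(inherits(plan, "experiment_plan"))
  pulses <- list(None = NULL,
                 Sampling = silence_pulse(0.25, 0.5, 100),
                 Delay = silence_pulse(1.75, 2.5, 100))
  seeds <- matrix(derive_seeds(plan$seed, plan$n_networks * 3),
                  plan$n_networks, 3)
  rows <- list()
  for (k in seq_len(plan$n_networks)) {
    net <- build_network(plan$net_params, seed = seeds[k, 1])
    for (seg in segments) for (cond in silencing) {
      sim <- simulate_session(net, plan$constants,
                              plan$trials_per_network, plan$gain,
                              plan$tau_d, seg, duration = plan$duration,
                              silencing = pulses[[cond]],
                              seed = seeds[k, 2])
      scored <- score_session(sim, seed = seeds[k, 3])
      rows[[length(rows) + 1]] <- data.frame(
        network = k, silencing = cond, segment = seg,
        accuracy = mean(scored$outcome == "correct"))
    }
  }
  acc <- do.call(rbind, rows)
  anova_tab <- if (length(segments) > 1 && length(silencing) > 1)
    rm_anova_2way(acc$accuracy, acc$network,
                  factor(acc$silencing), factor(acc$segment))
  else if (length(silencing) > 1)
    rm_anova_1way(acc$accuracy, acc$network, factor(acc$silencing))
  else NULL
  ph <- if (length(silencing) > 1) {
    sub <- acc[acc$segment == segments[1], ]
    bonferroni_posthoc(sub$accuracy, sub$network, sub$silencing)
  } else NULL
  list(accuracy = acc, anova = anova_tab, posthoc = ph)
}

#' Sliding silencing-pulse sweep
#'
#' Slides a square silencing pulse (default 250 ms wide) along the
#' trial in steps of `dc` seconds at the given strengths and measures
#' network accuracy at each pulse centre, averaged over networks.
#'
#' @param plan An [experiment_plan()].
#' @param centers Pulse centres in seconds (default `seq(0, 3, 0.05)`).
#' @param strengths Pulse strengths in percent (default `c(25, 100)`).
#' @param duration_sil Pulse width in seconds (default 0.25).
#' @return A data frame: strength, center, accuracy (pooled over all
#'   networks' trials).
#' @export
run_sliding_pulse <- function(plan, centers = seq(0, 3, by = 0.05),
                              strengths = c(25, 100),
                              duration_sil = 0.25) {
  stopifnot(inherits(plan, "experiment_plan"))
  seeds <- matrix(derive_seeds(plan$seed, plan$n_networks * 3),
                  plan$n_networks, 3)
  nets <- lapply(seq_len(plan$n_networks), function(k)
    build_network(plan$net_params, seed = seeds[k, 1]))
  rows <- list()
  for (str in strengths) for (cc in centers) {
    correct <- 0; total <- 0
    for (k in seq_len(plan$n_networks)) {
      net <- nets[[k]]
      sim <- simulate_session(net, plan$constants,
                              plan$trials_per_network, plan$gain,
                              plan$tau_d, plan$segment,
                              duration = plan$duration,
                              silencing = silence_pulse(cc, duration_sil,
                                                        str),
                              seed = seeds[k, 2])
      scored <- score_session(sim, seed = seeds[k, 3])
      correct <- correct + sum(scored$outcome == "correct")
      total <- total + nrow(scored)
    }
    rows[[length(rows) + 1]] <- data.frame(strength = str, center = cc,
                                           accuracy = correct / total)
  }
  do.call(rbind, rows)
}

#' Shared-initial-condition silencing protocol on one network
#'
#' Runs a control session, then re-runs its trials six times with the
#' same initial membrane potentials under {Weak (25%), Strong (100%)}
#' x {Beginning (centre 125 ms), Cue onset (centred on the control
#' trial's detected cue onset), Middle (centre 1.5 s)} silencing pulses
#' of 250 ms. A single HMM is fitted to all 7 x trials, decoded per
#' condition, and each silenced condition's decoded state sequences are
#' compared with control via the normalized similarity trace. Action-
#' coding states are counted as correct/incorrect per trial, and the
#' fraction of trials containing a correct Action-coding state is
#' compared across conditions (chi-squared plus Marascuilo post-hocs
#' against control).
#'
#' @param plan An [experiment_plan()]; `trials_per_network` trials are
#'   used for each condition.
#' @param network_seed Seed of the network instance to use.
#' @param cue_default Fallback pulse centre (seconds) for control
#'   trials without a detected cue onset.
#' @return A list with `conditions`, `accuracy` per condition, the
#'   shared `model`, per-condition `decoded`, `similarity` traces,
#'   `action_counts` (correct/incorrect/none per condition) and the
#'   `tests` (chi-squared p, Marascuilo table).
#' @export
run_fig7_protocol <- function(plan, network_seed = 1,
                              cue_default = 0.6) {
  stopifnot(inherits(plan, "experiment_plan"))
  seeds <- derive_seeds(plan$seed, 6)
  net <- build_network(plan$net_params, seed = network_seed)
  n_tr <- plan$trials_per_network
  control <- simulate_session(net, plan$constants, n_tr, plan$gain,
                              plan$tau_d, plan$segment,
                              duration = plan$duration, seed = seeds[1])
  scored0 <- score_session(control, seed = seeds[2])
  cue_on <- ifelse(is.na(scored0$cue_onset), cue_default,
                   scored0$cue_onset)
  conds <- expand.grid(strength = c(Weak = 25, Strong = 100),
                       window = c("Beginning", "CueOnset", "Middle"),
                       stringsAsFactors = FALSE)
  cond_names <- paste(names(c(Weak = 25, Strong = 100))[
    match(conds$strength, c(25, 100))], conds$window, sep = "/")
  sims <- list(Control = control)
  scores <- list(Control = scored0)
  for (q in seq_len(nrow(conds))) {
    centre_of <- function(i, cue) switch(conds$window[q],
      Beginning = 0.125, CueOnset = if (is.na(cue)) cue_default else cue,
      Middle = 1.5)
    silf <- local({
      qq <- q
      function(i, cue) silence_pulse(centre_of(i, cue), 0.25,
                                     conds$strength[qq])
    })
    sim_k <- simulate_session(net, plan$constants, n_tr, plan$gain,
                              plan$tau_d, plan$segment,
                              duration = plan$duration,
                              silencing = silf, seed = seeds[1],
                              v0_list = control$v0,
                              gate_onsets = control$gate_onsets,
                              cue_onsets = cue_on)
    sims[[cond_names[q]]] <- sim_k
    scores[[cond_names[q]]] <- score_session(sim_k, seed = seeds[3])
  }
  # one session over all conditions; a single HMM sees all 7 x n_tr
  # trials so that state labels are comparable across conditions
  all_sim <- list(trials = do.call(c, lapply(sims, `[[`, "trials")),
                  tastes = do.call(c, lapply(sims, `[[`, "tastes")),
                  duration = plan$duration)
  all_scored <- do.call(rbind, scores)
  session <- sample_model_session(all_sim, all_scored, net,
                                  seed = seeds[4],
                                  session_id = "fig7")
  dec_all <- analyze_model_session(session, all_scored, plan, seeds[5])
  cond_of_trial <- rep(names(sims), each = n_tr)
  accuracy <- vapply(names(sims), function(cn)
    mean(scores[[cn]]$outcome == "correct"), numeric(1))

  # per-condition decoded views and similarity traces
  n_bins <- floor(plan$duration / dec_all$decoded$bin)
  split_decoded <- function(cn) {
    idx <- which(cond_of_trial == cn)
    iv <- dec_all$decoded$intervals
    iv <- iv[iv$trial %in% idx, ]
    iv$trial <- match(iv$trial, idx)
    structure(list(posteriors = dec_all$decoded$posteriors[idx],
                   intervals = iv, M = dec_all$decoded$M,
                   bin = dec_all$decoded$bin,
                   window_start = dec_all$decoded$window_start,
                   n_trials = length(idx)),
              class = "decoded_states")
  }
  dec0 <- split_decoded("Control")
  similarity <- list()
  for (cn in names(sims)) {
    similarity[[cn]] <- sequence_similarity(
      split_decoded(cn), dec0, sims[[cn]]$tastes, control$tastes,
      trials_per_stimulus = n_tr / 4, n_bins = n_bins)
  }

  # Action-coding state accounting
  classes <- dec_all$classes
  act_states <- which(!is.na(classes) & classes == "Action")
  pref <- dec_all$classification$pref_correct[act_states]
  counts <- list()
  det <- occurrence_table(dec_all$decoded,
                          dec_all$trials)$detected
  for (cn in names(sims)) {
    idx <- which(cond_of_trial == cn)
    cor_n <- inc_n <- none_n <- 0
    for (i in idx) {
      present <- act_states[det[i, act_states]]
      if (!length(present)) { none_n <- none_n + 1; next }
      correct_dir <- stimulus_direction(all_sim$tastes[i])
      if (any(pref[match(present, act_states)] == correct_dir))
        cor_n <- cor_n + 1
      else inc_n <- inc_n + 1
    }
    counts[[cn]] <- c(correct = cor_n, incorrect = inc_n, none = none_n)
  }
  counts_m <- do.call(rbind, counts)
  x <- counts_m[, "correct"]
  n <- rowSums(counts_m)
  chi_p <- prop_chisq_p(x, n)
  mar <- marascuilo_pairs(x / n, n)
  list(conditions = names(sims), accuracy = accuracy, session = session,
       analysis = dec_all, similarity = similarity,
       action_counts = counts_m,
       tests = list(chisq_p = chi_p, marascuilo = mar),
       scores = scores)
}
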
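#' Leaky integrate-and-fire neuron constants
#'
#' Membrane and synaptic constants of the simulated neurons. The
#' membrane obeys `dV/dt = -(V - V_L)/tau_m + (I_ext + I_syn)/C`; on
#' reaching `V_th` the neuron spikes and is clamped to `V_r` for the
#' refractory period `tau_r`. Currents are expressed in units of
#' mV/ms with `C = 1`, so a weight J (pA x ms in the matrix's own
#' units) injects a current transient whose time-integral is J mV.
#'
#' @param tau_m_e,tau_m_i Membrane time constants (ms).
#' @param v_l Leak/equilibrium potential (mV).
#' @param v_th Spike threshold (mV).
#' @param v_r Reset potential (mV).
#' @param tau_r_e,tau_r_i Refractory periods (ms).
#' @param tau_syn_e,tau_syn_i Synaptic time constants (ms) for
#'   excitatory / inhibitory presynaptic input (per-neuron multipliers
#'   for cue/action clusters come from the network).
#' @param i_ext_e,i_ext_i Baseline external currents (mV/ms).
#' @param noise_sd Standard deviation (mV/ms) of the ongoing external
#'   current noise: an independent Gaussian value per cluster (shared
#'   by the cluster's neurons, separately for its E and I members, so
#'   it emulates correlated afferent fluctuations), held for
#'   `noise_dt` ms then redrawn. Set to 0 for fully deterministic
#'   dynamics given the initial membrane potentials.
#' @param noise_dt Noise refresh interval in ms.
#' @param capacitance Membrane capacitance; currents are divided by it.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m_e = 20, tau_m_i = 10,
                          v_l = 0, v_th = 20, v_r = 0,
                          tau_r_e = 5, tau_r_i = 3,
                          tau_syn_e = 4, tau_syn_i = 3,
                          i_ext_e = 1.5, i_ext_i = 1.0,
                          noise_sd = 0.8, noise_dt = 1,
                          capacitance = 1) {
  p <- as.list(environment())
  if (!(p$v_r < p$v_th)) abort_field("need v_r < v_th")
  if (any(unlist(p[c("tau_m_e", "tau_m_i", "tau_syn_e", "tau_syn_i")]) <= 0))
    abort_field("time constants must be positive")
  structure(p, class = "neuron_params")
}

#' Double-exponential stimulus waveform
#'
#' The taste stimulus is an alpha-like function
#' `f(t) = (G/h) (exp(-t/tau_d) - exp(-t/tau_r))` for `t >= onset`
#' (0 before), where the normalization
#' `h = (tau_r/tau_d)^(tau_r/(tau_d - tau_r)) -
#' (tau_r/tau_d)^(tau_d/(tau_d - tau_r))` makes the peak value equal to
#' the gain `G` (a percent increase of the baseline external current of
#' the targeted neurons). The `segment` argument selects the full
#' waveform, only its head (first 0.5 s after onset) or only its tail.
#'
#' @param gain Peak gain G in percent.
#' @param tau_d,tau_r Decay and rise time constants in seconds
#'   (`tau_d > tau_r > 0`).
#' @param onset Stimulus onset in seconds.
#' @param segment `"full"`, `"head"` or `"tail"`.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(gain = 60, tau_d = 0.160, tau_r = 0.020,
                          onset = 0, segment = c("full", "head", "tail")) {
  segment <- match.arg(segment)
  if (tau_d == tau_r)
    abort_field("tau_d must differ from tau_r (normalization undefined)")
  if (!(tau_d > tau_r && tau_r > 0))
    abort_field("need tau_d > tau_r > 0")
  r <- tau_r / tau_d
  h <- r^(tau_r / (tau_d - tau_r)) - r^(tau_d / (tau_d - tau_r))
  structure(list(gain = gain, tau_d = tau_d, tau_r = tau_r, h = h,
                 onset = onset, segment = segment),
            class = "stimulus_spec")
}

#' @rdname stimulus_spec
#' @param t Time(s) in seconds.
#' @param spec A `stimulus_spec`.
#' @return `stimulus_waveform`: the percent increase `f(t)` at each `t`.
#' @export
stimulus_waveform <- function(t, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  tt <- t - spec$onset
  f <- ifelse(tt >= 0,
              (spec$gain / spec$h) *
                (exp(-tt / spec$tau_d) - exp(-tt / spec$tau_r)), 0)
  if (spec$segment == "head") f[tt > 0.5] <- 0
  if (spec$segment == "tail") f[tt <= 0.5] <- 0
  f
}

#' Action gate signal
#'
#' A multiplicative gate on the synaptic input of action-cluster
#' neurons, modelling the approach of the lateral spouts: 0 before its
#' onset, ramping linearly to 1 over `ramp` seconds, then 1. The onset
#' is drawn uniformly over [1.1, 1.9] s in the experiments.
#'
#' @param onset Gate onset in seconds.
#' @param ramp Ramp duration in seconds (default 0.5).
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(onset, ramp = 0.5) {
  structure(list(onset = onset, ramp = ramp), class = "gate_spec")
}

#' @rdname gate_spec
#' @param t Time(s) in seconds.
#' @param gate A `gate_spec`.
#' @return `gate_signal`: the gate multiplier in [0, 1] at each `t`.
#' @export
gate_signal <- function(t, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  pmin(pmax((t - gate$onset) / gate$ramp, 0), 1)
}

#' Square silencing pulse
#'
#' Simulated optogenetic silencing: a square pulse
#' `phi(t) = k_sil * [Theta(t - (c - d/2)) - Theta(t - (c + d/2))]`
#' (Theta the Heaviside function) added as a percent increase of the
#' baseline external current of all inhibitory neurons.
#'
#' @param center Pulse centre c in seconds.
#' @param duration Pulse duration in seconds.
#' @param strength Pulse height in percent of the baseline current.
#' @return An object of class `silence_pulse`.
#' @export
silence_pulse <- function(center, duration, strength) {
  structure(list(center = center, duration = duration,
                 strength = strength), class = "silence_pulse")
}

#' @rdname silence_pulse
#' @param t Time(s) in seconds.
#' @param pulse A `silence_pulse` (or `NULL` for no silencing).
#' @return `silencing_pulse`: the percent increase at each `t`.
#' @export
silencing_pulse <- function(t, pulse) {
  if (is.null(pulse)) return(rep(0, length(t)))
  stopifnot(inherits(pulse, "silence_pulse"))
  lo <- pulse$center - pulse$duration / 2
  hi <- pulse$center + pulse$duration / 2
  ifelse(t >= lo & t < hi, pulse$strength, 0)
}

#' Simulate one trial of the clustered network
#'
#' Integrates the network with forward Euler at `dt` (default 0.05 ms)
#' for `duration` seconds. Initial membrane potentials are drawn from
#' Normal(0, sd = 4) under the seed; the dynamics themselves are
#' deterministic, so identical seeds and inputs give bitwise identical
#' spike trains. The stimulus multiplies the baseline external current
#' of the targeted taste-cluster neurons; the gate multiplies the total
#' synaptic current of excitatory action-cluster neurons until open;
#' the silencing pulse raises the baseline external current of all
#' inhibitory neurons.
#'
#' @param net A `synaptic_matrix` from [build_network()].
#' @param constants A [neuron_params()] object.
#' @param stimulus A `stimulus_spec`, or `NULL` for spontaneous
#'   activity. Its name must match a taste role (`"S","Q","M","O"`) via
#'   the `taste` argument.
#' @param taste Which taste is presented (`"S","Q","M","O"`), or `NULL`.
#' @param gate A `gate_spec`, or `NULL` to leave action clusters
#'   ungated (gate open).
#' @param silencing A `silence_pulse` or `NULL`.
#' @param duration Trial duration in seconds (default 3).
#' @param dt Integration step in milliseconds (default 0.05).
#' @param seed Seed for the initial condition.
#' @param gate_mode Which synaptic input the gate withholds from
#'   excitatory action-cluster neurons: `"excitatory"` (default; the
#'   recurrent excitatory current is gated while inhibition always
#'   reaches the cluster) or `"total"` (all synaptic input gated).
#' @param v0 Optional explicit initial membrane potentials (mV),
#'   overriding the seeded draw; used to reuse initial conditions
#'   across silencing conditions.
#' @return An object of class `spike_data`: a list with `time`
#'   (seconds), `neuron` (indices), `duration`, `taste`, `gate_onset`,
#'   and `v0`.
#' @export
simulate_trial <- function(net, constants = neuron_params(),
                           stimulus = stimulus_spec(), taste = "S",
                           gate = NULL, silencing = NULL,
                           duration = 3, dt = 0.05, seed = 1,
                           gate_mode = c("excitatory", "total"),
                           v0 = NULL) {
  gate_mode <- match.arg(gate_mode)
  stopifnot(inherits(net, "synaptic_matrix"),
            inherits(constants, "neuron_params"))
  n <- net$n_e + net$n_i
  if (is.null(v0)) v0 <- with_seed(seed, rnorm(n, 0, 4))
  noise_seed <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  stopifnot(length(v0) == n)
  n_steps <- round(duration * 1000 / dt)
  t_grid <- (seq_len(n_steps) - 1) * dt / 1000   # seconds, left edges

  stim_f <- rep(0, n_steps)
  stim_target <- rep(FALSE, n)
  if (!is.null(stimulus) && !is.null(taste)) {
    stopifnot(taste %in% c("S", "Q", "M", "O"))
    stim_f <- stimulus_waveform(t_grid, stimulus)
    stim_target[net$stimulus_targets[[taste]]] <- TRUE
  }
  gate_g <- if (is.null(gate)) rep(1, n_steps) else gate_signal(t_grid, gate)
  gate_target <- rep(FALSE, n)
  for (r in c("ActL", "ActR")) {
    cl <- which(net$role_of_cluster == r)
    gate_target[net$cluster == cl & !net$is_inh] <- TRUE
  }
  sil_f <- silencing_pulse(t_grid, silencing)

  cc <- constants
  tau_m <- ifelse(net$is_inh, cc$tau_m_i, cc$tau_m_e)
  tau_r <- ifelse(net$is_inh, cc$tau_r_i, cc$tau_r_e)
  tau_se <- cc$tau_syn_e * net$tau_mult_e
  tau_si <- cc$tau_syn_i * net$tau_mult_i
  i_ext <- ifelse(net$is_inh, cc$i_ext_i, cc$i_ext_e) / cc$capacitance

  W <- net$weights
  res <- cpp_simulate_lif(n_steps, dt,
                          W@p, W@i, W@x / cc$capacitance,
                          net$is_inh, v0,
                          tau_m, cc$v_l, cc$v_th, cc$v_r, tau_r,
                          tau_se, tau_si, i_ext,
                          stim_target, stim_f, gate_target, gate_g,
                          sil_f, gate_mode == "total",
                          cc$noise_sd %||% 0,
                          as.integer(round((cc$noise_dt %||% 1) / dt)),
                          noise_seed,
                          as.integer(net$cluster * 2L + net$is_inh))
  structure(list(time = res$time / 1000, neuron = res$neuron,
                 duration = duration, taste = taste,
                 gate_onset = if (is.null(gate)) NA_real_ else gate$onset,
                 silencing = silencing, v0 = v0, seed = seed),
            class = "spike_data")
}

#' @exportS3Method base::print
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d spikes over %g s (taste %s)\n",
              length(x$time), x$duration,
              x$taste %||% "none"))
  invisible(x)
}
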
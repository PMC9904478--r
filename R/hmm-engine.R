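#' Symbolize a preprocessed session for HMM fitting
#'
#' Spike trains of all neurons in a trial are reduced to a single
#' symbol sequence at 2 ms resolution: each bin gets the index of the
#' neuron that fired in it, or the null symbol `N + 1` if no neuron
#' fired. Bins in which several neurons fired (rare at 2 ms) are
#' assigned one of the firing neurons uniformly at random, under the
#' given seed. Bins are half-open `[t, t + bin)` over the padded trial
#' window `[taste - padding, decision + padding)`.
#'
#' @param session A `preprocessed_session` (see [preprocess_session()]).
#' @param bin Bin width in seconds (default 0.002).
#' @param seed Seed for the multi-spike tie-breaking stream.
#' @return An object of class `symbol_sequences`: a list of integer
#'   vectors (one per trial, symbols in `1..N+1`), with attributes
#'   `n_neurons`, `bin`, `padding` and `window_start` (per-trial window
#'   start relative to the taste event, i.e. `-padding`).
#' @export
symbolize <- function(session, bin = 0.002, seed = 1) {
  stopifnot(inherits(session, "spike_session"))
  n <- length(session$neuron_ids)
  null_sym <- n + 1L
  with_seed(seed, {
    seqs <- lapply(session$trials, function(tr) {
      lo <- tr$taste_time - session$padding
      hi <- tr$decision_time + session$padding
      n_bins <- ceiling((hi - lo) / bin)
      sym <- rep(null_sym, n_bins)
      multi <- list()
      for (j in seq_len(n)) {
        sp <- tr$spikes[[j]]
        sp <- sp[sp >= lo & sp < lo + n_bins * bin]
        b <- floor((sp - lo) / bin) + 1L
        b <- unique(b)
        clash <- sym[b] != null_sym
        sym[b[!clash]] <- j
        for (bb in b[clash])
          multi[[as.character(bb)]] <- c(multi[[as.character(bb)]] %||%
                                           sym[bb], j)
      }
      if (length(multi))
        for (bb in names(multi)) {
          cand <- multi[[bb]]
          sym[as.integer(bb)] <- cand[sample.int(length(cand), 1)]
        }
      as.integer(sym)
    })
    structure(seqs, class = "symbol_sequences", n_neurons = n, bin = bin,
              padding = session$padding, window_start = -session$padding)
  })
}

#' Fit a spike-train HMM with multi-start Baum-Welch
#'
#' Fits an `M`-state hidden Markov model to the symbol sequences of a
#' session by maximum likelihood using the Baum-Welch
#' expectation-maximization algorithm, run from `n_init` random initial
#' conditions; the fit with the highest log-likelihood wins. Initial
#' transition matrices have diagonal entries near 1 (0.99, jittered) and
#' small off-diagonal entries; initial emission rows are uniform(0,1)
#' draws, normalized. Each run stops after `max_iter` iterations or when
#' the changes in log-likelihood, transition and emission probabilities
#' all drop below `tol`. The initial state distribution is fixed uniform
#' and is not fitted.
#'
#' @param sequences A `symbol_sequences` object or plain list of integer
#'   vectors with symbols in `1..N+1`.
#' @param M Number of hidden states (>= 2, or 1 for a degenerate fit).
#' @param n_init Number of random initializations (default 10).
#' @param max_iter Maximum EM iterations per run (default 50).
#' @param tol Joint convergence tolerance (default 1e-10).
#' @param seed Seed for the initialization stream.
#' @param n_neurons Number of neurons `N`; taken from `sequences` if
#'   available.
#' @return An object of class `hmm_model`: a list with `M`, `T` (M x M
#'   transitions), `E` (M x (N+1) emissions), `log_likelihood`,
#'   `n_params`, `n_obs` (total bins), `bic`, `n_neurons`, `bin`, plus
#'   the per-init log-likelihoods and the winning run's LL trace.
#' @export
fit_hmm <- function(sequences, M, n_init = 10, max_iter = 50, tol = 1e-10,
                    seed = 1, n_neurons = NULL) {
  n_neurons <- n_neurons %||% attr(sequences, "n_neurons")
  if (is.null(n_neurons))
    abort_field("n_neurons not given and not an attribute of sequences")
  S <- n_neurons + 1L
  seqs <- lapply(unclass(sequences), as.integer)
  if (!length(seqs) || !sum(lengths(seqs)))
    abort_field("no observations to fit")
  if (any(unlist(lapply(seqs, range)) < 1) ||
      any(vapply(seqs, max, 1L) > S))
    abort_field("symbols must lie in 1..N+1 = 1..%d", S)
  if (length(unique(unlist(seqs))) == 1L)
    warning("degenerate data: a single symbol everywhere", call. = FALSE)
  stopifnot(M >= 1)
  B <- sum(lengths(seqs))
  init_seeds <- derive_seeds(seed, n_init)
  best <- NULL
  ll_by_init <- numeric(n_init)
  for (r in seq_len(n_init)) {
    init <- with_seed(init_seeds[r], {
      T0 <- matrix(0.01 / max(M - 1, 1), M, M)
      diag(T0) <- 0
      off <- rowSums(T0)
      # small jitter keeps runs distinct while staying near-diagonal
      diag(T0) <- 1 - off
      if (M > 1) {
        jit <- matrix(runif(M * M, 0, 0.002), M, M)
        T0 <- T0 + jit
        T0 <- T0 / rowSums(T0)
      }
      E0 <- matrix(runif(M * S), M, S)
      E0 <- E0 / rowSums(E0)
      list(T0 = T0, E0 = E0)
    })
    fit <- cpp_baum_welch(seqs, init$T0, init$E0, max_iter, tol)
    ll_by_init[r] <- fit$log_likelihood
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  n_params <- M * (M - 1) + M * n_neurons
  structure(
    list(M = M, T = best$T, E = best$E,
         log_likelihood = best$log_likelihood,
         n_params = n_params, n_obs = B,
         bic = bic_score(best$log_likelihood, M, n_neurons, B),
         n_neurons = n_neurons,
         bin = attr(sequences, "bin") %||% 0.002,
         window_start = attr(sequences, "window_start") %||% 0,
         ll_by_init = ll_by_init, ll_trace = best$ll_trace,
         n_iter = best$n_iter),
    class = "hmm_model")
}

#' @exportS3Method base::print
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> M = %d states, N = %d neurons, LL = %.2f, BIC = %.2f\n",
              x$M, x$n_neurons, x$log_likelihood, x$bic))
  invisible(x)
}

#' Bayesian information criterion for a spike-train HMM
#'
#' `-2 LL + (M (M - 1) + M N) log(B)`, where `LL` is the log-likelihood,
#' `M` the number of hidden states, `N` the number of neurons (so
#' `M(M-1) + MN` free parameters: transitions plus emissions), and `B`
#' the total number of 2 ms bins across all trials.
#'
#' @param LL Log-likelihood in nats.
#' @param M Number of hidden states.
#' @param N Number of neurons.
#' @param B Total number of observed bins (>= 1).
#' @return The BIC score (smaller is better).
#' @export
bic_score <- function(LL, M, N, B) {
  stopifnot(B >= 1)
  -2 * LL + (M * (M - 1) + M * N) * log(B)
}

#' Select the number of hidden states by BIC
#'
#' Fits an HMM for each candidate number of states and returns the model
#' minimizing the BIC score. The full selection table is attached.
#'
#' @inheritParams fit_hmm
#' @param M_range Candidate numbers of states (default `2:50`).
#' @return The winning `hmm_model`, with attribute `selection`: a data
#'   frame with columns `M`, `log_likelihood`, `bic`.
#' @export
select_model <- function(sequences, M_range = 2:50, n_init = 10,
                         max_iter = 50, tol = 1e-10, seed = 1,
                         n_neurons = NULL) {
  stopifnot(length(M_range) >= 1)
  fit_seeds <- derive_seeds(seed, length(M_range))
  fits <- vector("list", length(M_range))
  for (k in seq_along(M_range))
    fits[[k]] <- fit_hmm(sequences, M_range[k], n_init = n_init,
                         max_iter = max_iter, tol = tol,
                         seed = fit_seeds[k], n_neurons = n_neurons)
  tab <- data.frame(M = M_range,
                    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
                    bic = vapply(fits, `[[`, 0, "bic"))
  best <- fits[[which.min(tab$bic)]]
  attr(best, "selection") <- tab
  best
}

#' Decode hidden states with the admissibility criterion
#'
#' Computes per-bin posterior probabilities of each hidden state by the
#' forward-backward algorithm and extracts admissible state intervals:
#' maximal runs of bins in which one state's posterior stays at or above
#' `min_posterior` for at least `min_duration` seconds. Intervals never
#' span trial boundaries.
#'
#' @param model An `hmm_model`.
#' @param sequences The `symbol_sequences` the model is applied to (must
#'   have the same number of neurons the model was fitted with).
#' @param min_posterior Posterior threshold (default 0.8).
#' @param min_duration Minimum duration in seconds (default 0.05).
#' @return An object of class `decoded_states`: a list with
#'   `posteriors` (one `M x n_bins` matrix per trial) and `intervals`, a
#'   data frame with columns `trial`, `state`, `start`, `end` (seconds
#'   relative to the taste event), `start_bin`, `end_bin`.
#' @export
decode <- function(model, sequences, min_posterior = 0.8,
                   min_duration = 0.05) {
  stopifnot(inherits(model, "hmm_model"))
  seqs <- lapply(unclass(sequences), as.integer)
  S <- model$n_neurons + 1L
  if (any(vapply(seqs, max, 1L) > S))
    abort_field("sequences use more symbols than the model's N + 1 = %d", S)
  bin <- attr(sequences, "bin") %||% model$bin
  w0 <- attr(sequences, "window_start") %||% model$window_start
  min_bins <- ceiling(min_duration / bin)
  post <- vector("list", length(seqs))
  rows <- list()
  for (k in seq_along(seqs)) {
    G <- cpp_posterior(model$T, model$E, seqs[[k]])
    post[[k]] <- G
    top <- max.col(t(G))            # best state per bin
    pmax_ok <- G[cbind(top, seq_len(ncol(G)))] >= min_posterior
    lab <- ifelse(pmax_ok, top, 0L)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L & r$lengths >= min_bins
    if (any(keep))
      rows[[length(rows) + 1]] <- data.frame(
        trial = k, state = r$values[keep],
        start = w0 + (starts[keep] - 1L) * bin,
        end = w0 + ends[keep] * bin,
        start_bin = starts[keep], end_bin = ends[keep])
  }
  intervals <- if (length(rows)) do.call(rbind, rows)
  else data.frame(trial = integer(), state = integer(), start = numeric(),
                  end = numeric(), start_bin = integer(),
                  end_bin = integer())
  structure(list(posteriors = post, intervals = intervals,
                 M = model$M, bin = bin, window_start = w0,
                 n_trials = length(seqs)),
            class = "decoded_states")
}

#' @exportS3Method base::print
print.decoded_states <- function(x, ...) {
  cat(sprintf("<decoded_states> %d trials, %d admissible intervals, M = %d\n",
              x$n_trials, nrow(x$intervals), x$M))
  invisible(x)
}
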
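test_that("symbolization maps bins to neuron symbols as defined", {
  # neuron 1 spikes in bin 3, neuron 2 in bin 5, both in bin 8
  t0 <- 10; padding <- 0.1
  mk <- function(bins) t0 - padding + (bins - 1) * 0.002 + 0.001
  trials <- list(list(trial_id = 1, stimulus = "S", outcome = "correct",
                      taste_time = t0, decision_time = t0 + 1,
                      spikes = list(mk(c(3, 8)), mk(c(5, 8)))))
  s <- spike_session("sym", 1:2, trials, padding = padding)
  sy <- symbolize(s, seed = 1)
  expect_identical(length(sy[[1]]), as.integer(ceiling(1.2 / 0.002)))
  expect_identical(sy[[1]][3], 1L)
  expect_identical(sy[[1]][5], 2L)
  expect_identical(sy[[1]][1], 3L)          # null symbol = N + 1
  # the contested bin resolves to either neuron with probability 1/2
  draws <- vapply(1:400, function(k) symbolize(s, seed = k)[[1]][8],
                  integer(1))
  expect_setequal(unique(draws), c(1L, 2L))
  expect_lt(abs(mean(draws == 1L) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:3) {
    T <- matrix(runif(4), 2, 2); T <- T / rowSums(T)
    E <- matrix(runif(8), 2, 4); E <- E / rowSums(E)
    obs <- sample(1:4, 6, replace = TRUE)
    ll_fwd <- spikestates:::cpp_hmm_loglik(T, E, list(as.integer(obs)))
    expect_equal(ll_fwd, brute_force_ll(T, E, obs), tolerance = 1e-12)
  }
  # multi-sequence likelihood adds over sequences
  obs2 <- sample(1:4, 5, replace = TRUE)
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  E <- matrix(0.25, 2, 4)
  expect_equal(
    spikestates:::cpp_hmm_loglik(T, E, list(as.integer(obs2),
                                            as.integer(obs2))),
    2 * brute_force_ll(T, E, obs2), tolerance = 1e-10)
})

test_that("EM log-likelihood is nondecreasing and improves on refit", {
  spec <- generative_spec(n_neurons = 2, n_trials = 20,
                          rate_matrix = rbind(c(40, 2), c(2, 40)),
                          self_transition = 0.99,
                          iei_range = c(1, 1.5))
  gs <- generate_session(spec, seed = 2)
  sy <- symbolize(preprocess_session(gs$session, min_neurons = 2), seed = 1)
  m <- fit_hmm(sy, M = 2, n_init = 4, seed = 9)
  expect_true(all(diff(m$ll_trace) >= -1e-8))
  # decode-refit stability: restarting EM from the fitted model cannot
  # lower the likelihood
  refit <- spikestates:::cpp_baum_welch(lapply(unclass(sy), as.integer),
                                        m$T, m$E, 10L, 1e-10)
  expect_gte(refit$log_likelihood, m$log_likelihood - 1e-6)
})

test_that("two-state parameter recovery from synthetic spike trains", {
  spec <- generative_spec(n_neurons = 2, n_trials = 100,
                          rate_matrix = rbind(c(2, 40), c(40, 2)),
                          self_transition = 0.996,
                          iei_range = c(2.8, 3.0))
  gs <- generate_session(spec, seed = 4)
  sy <- symbolize(preprocess_session(gs$session, min_neurons = 2), seed = 1)
  m <- fit_hmm(sy, M = 2, n_init = 10, seed = 7)
  expect_lt(max(abs(sort(diag(m$T)) - 0.996)), 0.05)
  # posteriors are proper distributions in every bin
  d <- decode(m, sy)
  sums <- unlist(lapply(d$posteriors, colSums))
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("BIC formula, degenerate cases and monotonicity", {
  expect_equal(bic_score(-500, 2, 3, 100), 1000 + 8 * log(100))
  expect_equal(bic_score(-500, 2, 3, 100), 1036.841, tolerance = 1e-4)
  # M = 1 leaves only the emission parameters
  expect_equal(bic_score(0, 1, 5, 50), 5 * log(50))
  expect_gt(bic_score(-10, 3, 4, 200), bic_score(-10, 3, 4, 100))
})

test_that("model selection returns the trivial model for a single M", {
  spec <- generative_spec(n_neurons = 2, n_trials = 10,
                          rate_matrix = rbind(c(30, 2), c(2, 30)),
                          iei_range = c(1, 1))
  gs <- generate_session(spec, seed = 3)
  sy <- symbolize(preprocess_session(gs$session, min_neurons = 2), seed = 1)
  m <- select_model(sy, M_range = 2, n_init = 2, seed = 5)
  expect_identical(m$M, 2)
  expect_identical(nrow(attr(m, "selection")), 1L)
})

test_that("admissibility requires posterior >= 0.8 for >= 50 ms", {
  # hand-built model and sequences give full-confidence posteriors
  model <- structure(list(
    M = 2, T = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2),
    E = rbind(c(0.98, 0.01, 0.01), c(0.01, 0.98, 0.01)),
    n_neurons = 2, bin = 0.002, window_start = 0), class = "hmm_model")
  # 60 ms (30 bins) of symbol 1 then 200 bins of symbol 2
  seq1 <- c(rep(1L, 30), rep(2L, 200))
  seqs <- structure(list(seq1), class = "symbol_sequences",
                    n_neurons = 2, bin = 0.002, window_start = 0)
  d <- decode(model, seqs)
  iv1 <- d$intervals[d$intervals$state == 1, ]
  expect_identical(nrow(iv1), 1L)
  expect_gte((iv1$end_bin - iv1$start_bin + 1) * 0.002, 0.05)
  # a 40 ms run (20 bins) is below the admissibility duration
  seq2 <- c(rep(1L, 20), rep(2L, 200))
  seqs2 <- structure(list(seq2), class = "symbol_sequences",
                     n_neurons = 2, bin = 0.002, window_start = 0)
  d2 <- decode(model, seqs2)
  expect_identical(nrow(d2$intervals[d2$intervals$state == 1, ]), 0L)
})
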
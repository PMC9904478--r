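test_that("corrected significance level follows the Sidak form", {
  expect_equal(corrected_alpha(1), 0.05)
  expect_equal(corrected_alpha(5), 1 - 0.95^(1 / 5))
  expect_equal(corrected_alpha(5), 0.010206, tolerance = 1e-4)
  a <- vapply(1:10, corrected_alpha, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("Marascuilo pairwise tests flag the right pairs", {
  # equal proportions: nothing significant
  m0 <- marascuilo_pairs(rep(0.4, 4), 50)
  expect_false(any(m0$significant))
  # strong (0.9 vs 0.1) pair significant at n = 50
  m1 <- marascuilo_pairs(c(0.9, 0.1, 0.5, 0.5), 50)
  expect_true(m1$significant[m1$i == 1 & m1$j == 2])
  # hand evaluation of the critical range for that pair
  crit <- sqrt(qchisq(0.95, 3)) * sqrt(0.9 * 0.1 / 50 + 0.1 * 0.9 / 50)
  expect_equal(m1$critical[m1$i == 1 & m1$j == 2], crit)
  expect_equal(abs(0.9 - 0.1) > crit, TRUE)
  # symmetry under group relabelling
  m2 <- marascuilo_pairs(c(0.1, 0.9, 0.5, 0.5), 50)
  expect_identical(m2$significant[m2$i == 1 & m2$j == 2],
                   m1$significant[m1$i == 1 & m1$j == 2])
})

test_that("every branch of the classification pipeline is reached", {
  labels <- make_labels(n_cor = 40, n_inc = 20)
  hi <- 0.9; lo <- 0.1
  pats <- list(
    TasteID = det_pattern(labels,
                          list(S = hi, Q = lo, M = lo, O = lo),
                          list(S = hi, Q = lo, M = lo, O = lo)),
    Quality = det_pattern(labels,
                          list(S = hi, Q = lo, M = hi, O = lo),
                          list(S = hi, Q = lo, M = hi, O = lo)),
    Cue = det_pattern(labels,
                      list(S = hi, Q = hi, M = lo, O = lo),
                      list(S = hi, Q = hi, M = lo, O = lo)),
    Action = det_pattern(labels,
                         list(S = hi, Q = hi, M = lo, O = lo),
                         list(S = lo, Q = lo, M = hi, O = hi)),
    Dual = det_pattern(labels,
                       list(S = hi, Q = 0.5, M = 0.5, O = lo),
                       list(S = hi, Q = 0.5, M = 0.5, O = lo)),
    Noncoding = det_pattern(labels,
                            list(S = 0.5, Q = 0.5, M = 0.5, O = 0.5),
                            list(S = 0.5, Q = 0.5, M = 0.5, O = 0.5)))
  detected <- do.call(cbind, pats)
  d <- fake_decoded(detected)
  cl <- classify_states(d, labels)
  expect_identical(cl$label,
                   c("TasteID", "Quality", "Decision", "Decision",
                     "Dual", "Noncoding"))
  expect_identical(cl$decision_sublabel[3], "Cue")
  expect_identical(cl$decision_sublabel[4], "Action")
  expect_identical(cl$pref_correct[4], "left")
  expect_identical(cl$pref_incorrect[4], "right")
  expect_identical(coding_class(cl),
                   c(NA, "Quality", "Cue", "Action", NA, NA))
})

test_that("stricter incorrect-trial requirements only remove sublabels", {
  labels <- make_labels(n_cor = 40, n_inc = 4)   # few incorrect trials
  det <- det_pattern(labels,
                     list(S = 0.9, Q = 0.9, M = 0.1, O = 0.1),
                     list(S = 0.9, Q = 0.9, M = 0.1, O = 0.1))
  d <- fake_decoded(cbind(det))
  lax <- classify_states(d, labels, strict_incorrect = 0)
  strict <- classify_states(d, labels, strict_incorrect = 10)
  n_sub <- function(cl) sum(cl$decision_sublabel %in% c("Cue", "Action"))
  expect_lte(n_sub(strict), n_sub(lax))
  expect_identical(strict$decision_sublabel[1], "unsubclassified")
})

test_that("label permutation preserves counts and is reproducible", {
  labels <- make_labels(n_cor = 30, n_inc = 10)
  det <- det_pattern(labels,
                     list(S = 0.9, Q = 0.1, M = 0.9, O = 0.1),
                     list(S = 0.9, Q = 0.1, M = 0.9, O = 0.1))
  d <- fake_decoded(cbind(det))
  pr <- permute_stimulus_labels(d, labels, n_perm = 5, seed = 3)
  for (lab in pr$labels) {
    expect_identical(table(lab$stimulus), table(labels$stimulus))
    expect_identical(table(lab$stimulus, lab$outcome),
                     table(labels$stimulus, labels$outcome))
  }
  pr2 <- permute_stimulus_labels(d, labels, n_perm = 5, seed = 3)
  expect_identical(pr, pr2)
  # the planted Quality state is rarely preserved under permutation
  base <- classify_states(d, labels)
  expect_identical(base$label[1], "Quality")
  expect_lt(mean(pr$counts$Quality + pr$counts$Dual), 1)
})

test_that("circular shuffle preserves counts and autocorrelation", {
  s <- make_tiny_session(n = 2, K = 6, iei = 2, rate = 20)
  sh <- circular_shuffle(s, seed = 5)
  # the multiset of pairwise circular spike-time differences determines
  # the circular autocorrelation and is exactly invariant under a
  # circular shift of the whole train
  circ_diffs <- function(sp, lo, len) {
    d <- outer(sp - lo, sp - lo, "-") %% len
    sort(as.vector(d))
  }
  for (k in seq_along(s$trials)) {
    lo <- s$trials[[k]]$taste_time - s$padding
    len <- s$trials[[k]]$decision_time + s$padding - lo
    for (j in 1:2) {
      a <- s$trials[[k]]$spikes[[j]]
      b <- sh$trials[[k]]$spikes[[j]]
      expect_identical(length(a), length(b))
      expect_true(all(b >= lo & b <= lo + len))
      expect_equal(circ_diffs(a, lo, len), circ_diffs(b, lo, len),
                   tolerance = 1e-9)
    }
  }
})

test_that("circular shuffle destroys cross-neuron synchrony", {
  # two perfectly synchronous neurons
  trials <- lapply(1:10, function(k) {
    t0 <- 4 * k
    sp <- t0 + seq(0.05, 1.95, by = 0.1)
    list(trial_id = k, stimulus = "S", outcome = "correct",
         taste_time = t0, decision_time = t0 + 2,
         spikes = list(sp, sp))
  })
  s <- spike_session("sync", 1:2, trials)
  sync_rate <- function(sess, bin = 0.005) {
    hits <- 0; total <- 0
    for (tr in sess$trials) {
      lo <- tr$taste_time - sess$padding
      n_bins <- ceiling((tr$decision_time + sess$padding - lo) / bin)
      b1 <- tabulate(floor((tr$spikes[[1]] - lo) / bin) + 1, n_bins) > 0
      b2 <- tabulate(floor((tr$spikes[[2]] - lo) / bin) + 1, n_bins) > 0
      hits <- hits + sum(b1 & b2); total <- total + sum(b1)
    }
    hits / total
  }
  expect_equal(sync_rate(s), 1)
  shuffled <- vapply(1:20, function(k)
    sync_rate(circular_shuffle(s, seed = k)), numeric(1))
  expect_lt(mean(shuffled), 0.2)   # chance level ~ rate * bin
})

test_that("swap shuffle preserves co-activation but kills periodicity", {
  # strictly periodic neuron plus a partner synchronized with it
  trials <- lapply(1:6, function(k) {
    t0 <- 4 * k
    sp <- t0 + seq(0.0525, 1.9525, by = 0.1)   # period 100 ms
    list(trial_id = k, stimulus = "S", outcome = "correct",
         taste_time = t0, decision_time = t0 + 2,
         spikes = list(sp, sp))
  })
  s <- spike_session("period", 1:2, trials)
  sh <- swap_shuffle(s, bin = 0.005, seed = 2)
  for (k in seq_along(s$trials)) {
    # per-neuron counts unchanged
    expect_identical(lengths(sh$trials[[k]]$spikes),
                     lengths(s$trials[[k]]$spikes))
    # co-activation preserved exactly: neurons stay in the same 5 ms bin
    lo <- s$trials[[k]]$taste_time - s$padding
    b1 <- floor((sh$trials[[k]]$spikes[[1]] - lo) / 0.005)
    b2 <- floor((sh$trials[[k]]$spikes[[2]] - lo) / 0.005)
    expect_identical(sort(b1), sort(b2))
  }
  # periodicity at 100 ms is abolished: the fraction of consecutive
  # ISIs equal to 100 ms collapses
  isi_frac <- function(sess) {
    isis <- unlist(lapply(sess$trials, function(tr)
      diff(tr$spikes[[1]])))
    mean(abs(isis - 0.1) < 0.004)
  }
  expect_equal(isi_frac(s), 1)
  expect_lt(isi_frac(sh), 0.2)
})
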
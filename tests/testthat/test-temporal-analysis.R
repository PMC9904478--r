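test_that("onset warping clips padding and normalizes by the IEI", {
  labels <- data.frame(trial_id = 1:3, stimulus = "S",
                       outcome = "correct", taste_time = 0,
                       decision_time = 2.5, iei = 2.5,
                       direction = "left", quality = "sweet")
  d <- fake_decoded(matrix(TRUE, 3, 1), onset = c(1.25, -0.05, 2.6))
  w <- warp_onsets(d, labels, classes = "Quality")
  w <- w[order(w$trial), ]
  expect_equal(w$onset, c(0.5, 0, 1.0))
  # unwarping recovers the raw onset for unclipped values
  expect_equal(w$onset[1] * labels$iei[1], 1.25)
})

test_that("onset distributions behave at point mass and uniformity", {
  d1 <- onset_distribution(rep(0.5, 40))
  expect_equal(d1$mean_onset, 0.5)
  expect_lt(abs(d1$peak - 0.5), 0.05)
  # area under the smoothed density is 1
  dx <- diff(d1$x[1:2])
  expect_equal(sum(d1$density) * dx, 1, tolerance = 1e-6)
  set.seed(1)
  u <- runif(1e4)
  d2 <- onset_distribution(u)
  # flat density within Monte-Carlo tolerance over the interior
  interior <- d2$x > 0.15 & d2$x < 0.85
  expect_lt(max(abs(d2$density[interior] - 1)), 0.15)
  # empty class: no peak
  d0 <- onset_distribution(numeric())
  expect_true(is.na(d0$peak))
  expect_identical(sum(d1$counts), 40L)
})

test_that("ordering fraction detects proper and reversed sequences", {
  labels <- data.frame(trial_id = 1:4, stimulus = "S",
                       outcome = "correct", taste_time = 0,
                       decision_time = 2, iei = 2,
                       direction = "left", quality = "sweet")
  mk <- function(q, c, a) {
    det <- matrix(TRUE, 4, 3)
    d <- fake_decoded(det, onset = rep(c(q, c, a), each = 4))
    warp_onsets(d, labels, classes = c("Quality", "Cue", "Action"))
  }
  expect_equal(ordering_fraction(mk(0.2, 0.8, 1.4))$fraction, 1)
  expect_equal(ordering_fraction(mk(1.4, 0.8, 0.2))$fraction, 0)
  # trials with fewer than two classes are ineligible
  one <- warp_onsets(fake_decoded(matrix(TRUE, 4, 1), onset = 0.3),
                     labels, classes = "Cue")
  expect_identical(ordering_fraction(one)$n_eligible, 0L)
})

test_that("planted synthetic sessions are properly ordered in truth", {
  spec <- default_session_spec()
  fracs <- vapply(1:10, function(seed) {
    gs <- generate_session(spec, seed = seed)
    tr <- session_trials(gs$session)
    rows <- do.call(rbind, lapply(seq_along(gs$truth$onsets), function(k) {
      on <- gs$truth$onsets[[k]]
      if (!length(on)) return(NULL)
      data.frame(trial = k,
                 class = vapply(on, `[[`, "", "class"),
                 onset = pmin(pmax(vapply(on, `[[`, 0, "onset"), 0) /
                                tr$iei[k], 1))
    }))
    ordering_fraction(rows)$fraction
  }, numeric(1))
  expect_true(all(fracs >= 0.8))
})

test_that("sequence similarity matches hand-counted fixtures", {
  # build decoded objects over 4 stimuli x 2 trials each, 10 bins
  n_tr <- 8; n_bins <- 10
  stim <- rep(c("S", "Q", "M", "O"), each = 2)
  mk_decoded <- function(lab) {   # lab: n_tr x n_bins state labels
    rows <- list()
    for (tr in seq_len(n_tr)) {
      r <- rle(lab[tr, ])
      e <- cumsum(r$lengths); s <- e - r$lengths + 1
      keep <- r$values != 0
      if (any(keep))
        rows[[length(rows) + 1]] <- data.frame(
          trial = tr, state = r$values[keep],
          start = (s[keep] - 1) * 0.002, end = e[keep] * 0.002,
          start_bin = s[keep], end_bin = e[keep])
    }
    structure(list(posteriors = lapply(seq_len(n_tr), function(i)
      matrix(0, 2, n_bins)),
      intervals = do.call(rbind, rows), M = 2, bin = 0.002,
      window_start = 0, n_trials = n_tr), class = "decoded_states")
  }
  lab0 <- matrix(1L, n_tr, n_bins)
  # identical conditions: rho = 1 everywhere
  d0 <- mk_decoded(lab0)
  ss <- sequence_similarity(d0, d0, stim, stim, trials_per_stimulus = 2,
                            smooth_width = 1)
  expect_equal(ss$rho, rep(1, n_bins))
  # disjoint labels, no zeros: raw similarity 0
  lab2 <- matrix(2L, n_tr, n_bins)
  ss2 <- sequence_similarity(mk_decoded(lab2), d0, stim, stim,
                             trials_per_stimulus = 2, smooth_width = 1)
  expect_equal(ss2$raw, rep(0, n_bins))
  # hand-counted mixed case in bin 1: per stimulus, x^k = (1, 2),
  # x_0 = (1, 1): matches = 2 of 4 pairs
  labk <- lab0; labk[c(2, 4, 6, 8), ] <- 2L
  ss3 <- sequence_similarity(mk_decoded(labk), d0, stim, stim,
                             trials_per_stimulus = 2, smooth_width = 1)
  expect_equal(ss3$raw[1], 0.5)
  expect_equal(ss3$rho[1], 0.5)   # self-similarity of x_0 is 1
  # zeros count as matches in the raw measure
  labz <- lab0; labz[, 1] <- 0L
  d0z <- mk_decoded(labz)
  ssz <- sequence_similarity(d0z, d0z, stim, stim,
                             trials_per_stimulus = 2, smooth_width = 1)
  expect_equal(ssz$rho[1], 1)
  # unequal trial counts are rejected
  expect_error(sequence_similarity(d0, d0, stim, rev(stim)[1:8],
                                   trials_per_stimulus = 3),
               "exactly 3 trials")
})

test_that("similarity is invariant to consistent state relabelling", {
  set.seed(9)
  n_tr <- 8; n_bins <- 30
  stim <- rep(c("S", "Q", "M", "O"), each = 2)
  lab_a <- matrix(sample(0:2, n_tr * n_bins, TRUE), n_tr, n_bins)
  lab_b <- matrix(sample(0:2, n_tr * n_bins, TRUE), n_tr, n_bins)
  mk <- function(lab, M = 3) {
    rows <- list()
    for (tr in seq_len(n_tr)) {
      r <- rle(lab[tr, ])
      e <- cumsum(r$lengths); s <- e - r$lengths + 1
      keep <- r$values != 0
      if (any(keep))
        rows[[length(rows) + 1]] <- data.frame(
          trial = tr, state = r$values[keep],
          start = (s[keep] - 1) * 0.002, end = e[keep] * 0.002,
          start_bin = s[keep], end_bin = e[keep])
    }
    structure(list(posteriors = lapply(seq_len(n_tr), function(i)
      matrix(0, M, n_bins)),
      intervals = do.call(rbind, rows), M = M, bin = 0.002,
      window_start = 0, n_trials = n_tr), class = "decoded_states")
  }
  ss <- sequence_similarity(mk(lab_a), mk(lab_b), stim, stim,
                            trials_per_stimulus = 2, smooth_width = 1)
  # relabel 1 <-> 2 in both conditions
  swap <- function(lab) { out <- lab; out[lab == 1] <- 2; out[lab == 2] <- 1
    out }
  ss_swapped <- sequence_similarity(mk(swap(lab_a)), mk(swap(lab_b)),
                                    stim, stim, trials_per_stimulus = 2,
                                    smooth_width = 1)
  expect_equal(ss$raw, ss_swapped$raw)
  expect_true(all(ss$raw >= 0 & ss$raw <= 1))
})
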
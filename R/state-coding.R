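#' Multiple-comparison corrected significance level
#'
#' When `N_d` decoded states are each tested for coding properties, the
#' per-state significance level is corrected to
#' `1 - (1 - alpha)^(1/N_d)` (Sidak-style), so the familywise error over
#' the states stays at `alpha`.
#'
#' @param N_d Number of decoded states (>= 1).
#' @param alpha Familywise significance level (default 0.05).
#' @return The corrected per-test significance level.
#' @export
corrected_alpha <- function(N_d, alpha = 0.05) {
  stopifnot(N_d >= 1)
  1 - (1 - alpha)^(1 / N_d)
}

#' Marascuilo pairwise comparison of proportions
#'
#' Post-hoc procedure after a k-sample chi-squared test of equal
#' proportions: the pair (i, j) is significant when
#' `|p_i - p_j| > sqrt(qchisq(1 - alpha, k - 1)) *
#' sqrt(p_i (1 - p_i) / n_i + p_j (1 - p_j) / n_j)`.
#'
#' @param proportions Vector of k sample proportions.
#' @param n Vector of k group sizes (recycled if scalar).
#' @param alpha Significance level.
#' @return A data frame with columns `i`, `j`, `diff`, `critical`,
#'   `significant`.
#' @export
marascuilo_pairs <- function(proportions, n, alpha = 0.05) {
  k <- length(proportions)
  stopifnot(k >= 2, all(n > 0))
  n <- rep_len(n, k)
  chi_crit <- sqrt(qchisq(1 - alpha, df = k - 1))
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  d <- abs(proportions[i] - proportions[j])
  crit <- chi_crit * sqrt(proportions[i] * (1 - proportions[i]) / n[i] +
                          proportions[j] * (1 - proportions[j]) / n[j])
  data.frame(i = i, j = j, diff = d, critical = crit,
             significant = d > crit)
}

# k-sample chi-squared test of equal proportions on detected /
# not-detected counts (df = k - 1, no continuity correction). Returns
# the p-value; degenerate margins (all detected or none) give p = 1.
prop_chisq_p <- function(x, n) {
  if (sum(x) == 0 || sum(x) == sum(n)) return(1)
  p <- sum(x) / sum(n)
  expd <- n * p
  expn <- n * (1 - p)
  stat <- sum((x - expd)^2 / expd + ((n - x) - expn)^2 / expn)
  pchisq(stat, df = length(x) - 1, lower.tail = FALSE)
}

#' Per-state occurrence table by trial condition
#'
#' For every decoded state, the fraction of trials of each condition in
#' which the state was admissible at least once. Conditions cover the
#' four stimuli crossed with outcome, plus the cue-direction and
#' taste-quality groupings.
#'
#' @param decoded A `decoded_states` object.
#' @param trials Trial labels: a data frame as from [session_trials()]
#'   (rows aligned with the decoded trials).
#' @param use_trials Optional logical vector marking trials to include
#'   (e.g. to drop ambiguous model trials). Default: all.
#' @return A list with `detected` (trials x states logical matrix) and
#'   `trials` (the labels, with an `included` column).
#' @export
occurrence_table <- function(decoded, trials, use_trials = NULL) {
  stopifnot(inherits(decoded, "decoded_states"),
            nrow(trials) == decoded$n_trials)
  states <- seq_len(decoded$M)
  detected <- matrix(FALSE, decoded$n_trials, decoded$M,
                     dimnames = list(NULL, paste0("state", states)))
  if (nrow(decoded$intervals))
    detected[cbind(decoded$intervals$trial, decoded$intervals$state)] <- TRUE
  trials$included <- use_trials %||% rep(TRUE, nrow(trials))
  list(detected = detected, trials = trials)
}

# Occurrence proportion of one state in a subset of trials.
occ_prop <- function(det, sel) {
  n <- sum(sel)
  if (n == 0) return(c(x = NA, n = 0, p = NA))
  x <- sum(det[sel])
  c(x = x, n = n, p = x / n)
}

#' Classify decoded states by coding property
#'
#' Implements the full classification pipeline. For each decoded state,
#' using correct trials only: (1) a 4-way chi-squared test of equal
#' occurrence proportions across the four stimuli at the corrected
#' significance level; non-significant states are Noncoding. (2) If
#' significant, the 6 pairwise Marascuilo post-hoc tests are examined;
#' if there is exactly one stimulus for which all three of its pairwise
#' tests are significant, the state is TasteID-coding. (3) Otherwise two
#' independent chi-squared tests compare sweet vs bitter and cue-left vs
#' cue-right correct trials, yielding Quality, Decision, Dual, or
#' Noncoding. (4) Decision states are subclassified by their preferred
#' direction in correct vs incorrect trials: same direction in both is
#' Cue-coding, opposite directions is Action-coding; exact ties leave
#' the state unsubclassified.
#'
#' @param decoded A `decoded_states` object.
#' @param trials Trial labels as from [session_trials()].
#' @param alpha Familywise significance level (default 0.05).
#' @param use_trials Optional logical mask of trials to analyse.
#' @param strict_incorrect If > 0, require at least this many incorrect
#'   trials of each cued direction before subclassifying a Decision
#'   state (0 disables the requirement).
#' @return A data frame, one row per state, with columns `state`,
#'   `label` (TasteID/Quality/Decision/Dual/Noncoding),
#'   `decision_sublabel` (Cue/Action/unsubclassified/NA), preferred
#'   directions in correct and incorrect trials, and the test p-values.
#' @export
classify_states <- function(decoded, trials, alpha = 0.05,
                            use_trials = NULL, strict_incorrect = 0) {
  occ <- occurrence_table(decoded, trials, use_trials)
  det <- occ$detected
  tr <- occ$trials
  inc <- tr$included
  # Only states that were actually decoded in some trial count toward N_d.
  decoded_states <- which(colSums(det[inc, , drop = FALSE]) > 0)
  N_d <- max(length(decoded_states), 1L)
  a_corr <- corrected_alpha(N_d, alpha)
  correct <- inc & tr$outcome == "correct"
  incorrect <- inc & tr$outcome == "incorrect"
  res <- data.frame(state = seq_len(ncol(det)), label = "Noncoding",
                    decision_sublabel = NA_character_,
                    pref_correct = NA_character_,
                    pref_incorrect = NA_character_,
                    p_stimulus = NA_real_, p_quality = NA_real_,
                    p_direction = NA_real_, stringsAsFactors = FALSE)
  for (s in seq_len(ncol(det))) {
    if (!s %in% decoded_states) next
    d <- det[, s]
    by_stim <- vapply(STIMULI, function(st)
      occ_prop(d, correct & tr$stimulus == st), numeric(3))
    if (any(by_stim["n", ] == 0)) {
      warning(sprintf("state %d: a stimulus has no correct trials; left %s",
                      s, "Noncoding"), call. = FALSE)
      next
    }
    p4 <- prop_chisq_p(by_stim["x", ], by_stim["n", ])
    res$p_stimulus[s] <- p4
    if (p4 >= a_corr) next                       # Noncoding
    mar <- marascuilo_pairs(by_stim["p", ], by_stim["n", ], alpha = a_corr)
    solo <- vapply(1:4, function(st)
      all(mar$significant[mar$i == st | mar$j == st]), logical(1))
    if (sum(solo) == 1) {
      res$label[s] <- "TasteID"
      next
    }
    pq <- prop_chisq_p(
      c(sum(d[correct & tr$quality == "sweet"]),
        sum(d[correct & tr$quality == "bitter"])),
      c(sum(correct & tr$quality == "sweet"),
        sum(correct & tr$quality == "bitter")))
    pd <- prop_chisq_p(
      c(sum(d[correct & tr$direction == "left"]),
        sum(d[correct & tr$direction == "right"])),
      c(sum(correct & tr$direction == "left"),
        sum(correct & tr$direction == "right")))
    res$p_quality[s] <- pq
    res$p_direction[s] <- pd
    sig_q <- pq < a_corr
    sig_d <- pd < a_corr
    res$label[s] <- if (sig_q && sig_d) "Dual"
    else if (sig_q) "Quality"
    else if (sig_d) "Decision"
    else "Noncoding"
    if (res$label[s] == "Decision") {
      if (strict_incorrect > 0) {
        n_inc_l <- sum(incorrect & tr$direction == "left")
        n_inc_r <- sum(incorrect & tr$direction == "right")
        if (n_inc_l < strict_incorrect || n_inc_r < strict_incorrect) {
          res$decision_sublabel[s] <- "unsubclassified"
          next
        }
      }
      pref <- function(sel) {
        pl <- occ_prop(d, sel & tr$direction == "left")["p"]
        pr <- occ_prop(d, sel & tr$direction == "right")["p"]
        if (any(is.na(c(pl, pr))) || pl == pr) return(NA_character_)
        if (pl > pr) "left" else "right"
      }
      pc <- pref(correct)
      pi <- pref(incorrect)
      res$pref_correct[s] <- pc
      res$pref_incorrect[s] <- pi
      res$decision_sublabel[s] <-
        if (is.na(pc) || is.na(pi)) "unsubclassified"
        else if (pc == pi) "Cue" else "Action"
    }
  }
  res
}

#' Coding class of each state from a classification table
#'
#' Collapses [classify_states()] output to the three temporally ordered
#' coding classes: Quality, Cue (Decision/Cue) and Action
#' (Decision/Action). Other states map to `NA`.
#'
#' @param classification Output of [classify_states()].
#' @return Character vector indexed by state.
#' @export
coding_class <- function(classification) {
  cls <- rep(NA_character_, nrow(classification))
  cls[classification$label == "Quality"] <- "Quality"
  dec <- classification$label == "Decision"
  cls[dec & classification$decision_sublabel %in% "Cue"] <- "Cue"
  cls[dec & classification$decision_sublabel %in% "Action"] <- "Action"
  cls
}

#' Stimulus-label permutation control
#'
#' Randomly permutes the stimulus labels of the trials (within correct
#' trials and within incorrect trials separately, preserving the
#' outcome structure and per-stimulus trial counts) and re-runs the
#' classification, returning the number of coding states found in each
#' permutation.
#'
#' @param decoded A `decoded_states` object.
#' @param trials Trial labels as from [session_trials()].
#' @param n_perm Number of permutations (default 10).
#' @param seed Seed.
#' @param ... Passed to [classify_states()].
#' @return A list with `counts`: a data frame (one row per permutation)
#'   of coding-state counts by label, and `labels`: the permuted label
#'   frames.
#' @export
permute_stimulus_labels <- function(decoded, trials, n_perm = 10, seed = 1,
                                    ...) {
  seeds <- derive_seeds(seed, n_perm)
  labels <- vector("list", n_perm)
  counts <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    perm <- with_seed(seeds[r], {
      tr <- trials
      for (out in c("correct", "incorrect")) {
        idx <- which(tr$outcome == out)
        tr$stimulus[idx] <- tr$stimulus[sample(idx)]
      }
      tr$direction <- stimulus_direction(tr$stimulus)
      tr$quality <- stimulus_quality(tr$stimulus)
      tr
    })
    labels[[r]] <- perm
    cl <- suppressWarnings(classify_states(decoded, perm, ...))
    counts[[r]] <- data.frame(
      perm = r,
      TasteID = sum(cl$label == "TasteID"),
      Quality = sum(cl$label == "Quality"),
      Decision = sum(cl$label == "Decision"),
      Dual = sum(cl$label == "Dual"))
  }
  list(counts = do.call(rbind, counts), labels = labels)
}

#' Circular-shift surrogate sessions
#'
#' Shuffles each spike train circularly and independently per neuron and
#' per trial: a shift drawn uniformly on `[0, t_trial]` is added to the
#' neuron's spike times within the padded trial window, wrapping spikes
#' that fall off the end back to the beginning. Autocorrelations of
#' individual neurons are preserved; co-activation across neurons is
#' destroyed. Per-neuron per-trial spike counts are unchanged.
#'
#' @param session A (preprocessed) `spike_session`.
#' @param seed Seed.
#' @return A `spike_session` of the same shape.
#' @export
circular_shuffle <- function(session, seed = 1) {
  stopifnot(inherits(session, "spike_session"))
  with_seed(seed, {
    out <- session
    for (k in seq_along(session$trials)) {
      tr <- session$trials[[k]]
      lo <- tr$taste_time - session$padding
      hi <- tr$decision_time + session$padding
      len <- hi - lo
      for (j in seq_along(tr$spikes)) {
        dt <- runif(1, 0, len)
        s <- tr$spikes[[j]] - lo + dt
        s <- ifelse(s < len, s, s - len)
        out$trials[[k]]$spikes[[j]] <- sort(s + lo)
      }
    }
    out
  })
}

#' Column-swap surrogate sessions
#'
#' Segments each trial's neuron-by-time raster into fixed-width bins
#' (default 5 ms) and permutes the bins (columns) uniformly at random,
#' with the same permutation applied to all neurons of the trial;
#' spikes keep their offsets within the bin. Co-activation across
#' neurons within a bin is preserved; single-neuron autocorrelations are
#' destroyed.
#'
#' @param session A (preprocessed) `spike_session`.
#' @param bin Bin width in seconds (default 0.005).
#' @param seed Seed.
#' @return A `spike_session` of the same shape.
#' @export
swap_shuffle <- function(session, bin = 0.005, seed = 1) {
  stopifnot(inherits(session, "spike_session"))
  with_seed(seed, {
    out <- session
    for (k in seq_along(session$trials)) {
      tr <- session$trials[[k]]
      lo <- tr$taste_time - session$padding
      hi <- tr$decision_time + session$padding
      n_bins <- ceiling((hi - lo) / bin)
      perm <- sample.int(n_bins)       # perm[b] = new position of bin b
      for (j in seq_along(tr$spikes)) {
        s <- tr$spikes[[j]] - lo
        b <- pmin(floor(s / bin), n_bins - 1)     # 0-based bin index
        off <- s - b * bin
        out$trials[[k]]$spikes[[j]] <- sort(lo + (perm[b + 1] - 1) * bin +
                                              off)
      }
    }
    out
  })
}
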
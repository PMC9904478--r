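#' Warped onset times of coding states
#'
#' Onset times of admissible coding-state intervals are expressed
#' relative to the trial's taste event, clipped below at 0 (states
#' beginning during the left padding) and divided by the trial's
#' inter-event interval (IEI), so that 0 is the taste event and 1 the
#' decision event in every trial. Onsets falling after the decision
#' event (right padding) are clipped to 1. All onsets of a state in a
#' trial contribute.
#'
#' @param decoded A `decoded_states` object (its `intervals` carry
#'   per-trial onsets relative to the taste event).
#' @param trials Trial labels as from [session_trials()] (for the IEI).
#' @param classes Character vector giving the coding class per state
#'   (e.g. from [coding_class()]); states with `NA` are skipped.
#' @return A data frame with columns `class`, `trial`, `state`, `onset`
#'   (warped, in [0, 1]) and `onset_s` (unwarped seconds, unclipped).
#' @export
warp_onsets <- function(decoded, trials, classes) {
  iv <- decoded$intervals
  out <- data.frame(class = character(), trial = integer(),
                    state = integer(), onset = numeric(),
                    onset_s = numeric(), stringsAsFactors = FALSE)
  if (!nrow(iv)) return(out)
  cls <- classes[iv$state]
  keep <- !is.na(cls)
  if (!any(keep)) return(out)
  iv <- iv[keep, ]
  cls <- cls[keep]
  iei <- trials$iei[iv$trial]
  if (anyNA(iei)) {
    warning("trials with missing events skipped", call. = FALSE)
    ok <- !is.na(iei)
    iv <- iv[ok, ]; cls <- cls[ok]; iei <- iei[ok]
  }
  warped <- pmin(pmax(iv$start, 0) / iei, 1)
  data.frame(class = cls, trial = iv$trial, state = iv$state,
             onset = warped, onset_s = iv$start, stringsAsFactors = FALSE)
}

#' Onset-time distribution in warped units
#'
#' Histogram of pooled warped onsets (bin 0.05 warped units), linearly
#' interpolated between bin centres (100 points per gap), smoothed with
#' a Gaussian filter (400-point width, sigma = width/6), normalized to
#' unit area, with the mean onset and inferred peak (argmax of the
#' smoothed density).
#'
#' @param onsets Numeric vector of warped onsets in [0, 1] (e.g. one
#'   class from [warp_onsets()]).
#' @param bin Histogram bin size (default 0.05).
#' @param interp_points Interpolation points per bin gap (default 100).
#' @param smooth_width Gaussian filter width in points (default 400).
#' @return A list with `breaks`, `counts`, `x`, `density`,
#'   `mean_onset`, `peak`.
#' @export
onset_distribution <- function(onsets, bin = 0.05, interp_points = 100,
                               smooth_width = 400) {
  if (length(onsets) == 0)
    return(list(breaks = numeric(), counts = integer(), x = numeric(),
                density = numeric(), mean_onset = NA_real_,
                peak = NA_real_))
  breaks <- seq(0, 1, by = bin)
  h <- graphics::hist(pmin(pmax(onsets, 0), 1), breaks = breaks,
                      plot = FALSE)
  centers <- h$mids
  x <- seq(centers[1], centers[length(centers)],
           length.out = (length(centers) - 1) * interp_points + 1)
  dens <- stats::approx(centers, h$counts, xout = x)$y
  dens <- gaussian_smooth(dens, smooth_width)
  dens[dens < 0] <- 0
  area <- sum(dens) * (x[2] - x[1])
  if (area > 0) dens <- dens / area
  list(breaks = breaks, counts = h$counts, x = x, density = dens,
       mean_onset = mean(onsets), peak = x[which.max(dens)])
}

#' Fraction of trials with the canonical coding-state ordering
#'
#' Restricts to trials containing at least two distinct coding classes
#' and checks, pairwise among the classes present, that every Quality
#' onset precedes every Cue onset, and every Cue onset precedes every
#' Action onset. Returns the fraction of such trials that are properly
#' ordered.
#'
#' @param onsets A data frame from [warp_onsets()].
#' @return A list with `fraction`, `n_proper`, `n_eligible`.
#' @export
ordering_fraction <- function(onsets) {
  if (!nrow(onsets))
    return(list(fraction = NA_real_, n_proper = 0L, n_eligible = 0L))
  rank3 <- c(Quality = 1, Cue = 2, Action = 3)
  eligible <- 0L
  proper <- 0L
  for (tr in unique(onsets$trial)) {
    sub <- onsets[onsets$trial == tr, ]
    present <- unique(sub$class)
    if (length(present) < 2) next
    eligible <- eligible + 1L
    ok <- TRUE
    for (a in present) for (b in present) {
      if (rank3[a] < rank3[b] &&
          max(sub$onset[sub$class == a]) > min(sub$onset[sub$class == b]))
        ok <- FALSE
    }
    proper <- proper + ok
  }
  list(fraction = if (eligible) proper / eligible else NA_real_,
       n_proper = proper, n_eligible = eligible)
}

# Per-bin admissible state labels for fixed-duration trials: an
# n_trials x n_bins integer matrix, 0 where no state is admissible.
state_label_matrix <- function(decoded, n_bins) {
  lab <- matrix(0L, decoded$n_trials, n_bins)
  iv <- decoded$intervals
  if (nrow(iv))
    for (r in seq_len(nrow(iv))) {
      b1 <- iv$start_bin[r]
      b2 <- min(iv$end_bin[r], n_bins)
      if (b1 > b2) next             # interval lies beyond the window
      lab[iv$trial[r], b1:b2] <- iv$state[r]
    }
  lab
}

#' Time-resolved state-sequence similarity between two conditions
#'
#' For each 2 ms bin and each stimulus, the decoded (admissible) state
#' labels of the condition's trials form a vector `x^k` of length
#' `trials_per_stimulus` (0 where no state was admissible), and likewise
#' `x_0` for the control condition. The raw similarity in a bin is the
#' fraction of matching pairs over all `25 x 25` cross-condition trial
#' pairs, averaged over the four stimuli; it is normalized by the
#' control's similarity with itself, and the resulting trace is smoothed
#' with a Gaussian filter (150-bin width). Both conditions must be
#' decoded with the same fitted model for state labels to be
#' comparable.
#'
#' @param decoded_k A `decoded_states` for the comparison condition.
#' @param decoded_0 A `decoded_states` for the control condition.
#' @param stimulus_k,stimulus_0 Stimulus label per trial of each
#'   condition.
#' @param trials_per_stimulus Trials per stimulus per condition
#'   (default 25; the pairing structure is definitional).
#' @param n_bins Number of 2 ms bins per trial (default: the shortest
#'   trial across both conditions).
#' @param smooth_width Gaussian filter width in bins (default 150).
#' @return A list with `raw` (per-bin raw similarity of `x^k` vs
#'   `x_0`), `self` (control vs itself), `rho` (normalized), `rho_smooth`
#'   and `time` (bin centres, seconds relative to window start).
#' @export
sequence_similarity <- function(decoded_k, decoded_0, stimulus_k,
                                stimulus_0, trials_per_stimulus = 25,
                                n_bins = NULL, smooth_width = 150) {
  stopifnot(inherits(decoded_k, "decoded_states"),
            inherits(decoded_0, "decoded_states"))
  for (st in STIMULI) {
    if (sum(stimulus_k == st) != trials_per_stimulus ||
        sum(stimulus_0 == st) != trials_per_stimulus)
      abort_field("both conditions need exactly %d trials of stimulus %s",
                  trials_per_stimulus, st)
  }
  n_bins <- n_bins %||% min(
    vapply(decoded_k$posteriors, ncol, 1L),
    vapply(decoded_0$posteriors, ncol, 1L))
  lab_k <- state_label_matrix(decoded_k, n_bins)
  lab_0 <- state_label_matrix(decoded_0, n_bins)
  raw <- numeric(n_bins)
  self <- numeric(n_bins)
  for (st in STIMULI) {
    xk <- lab_k[stimulus_k == st, , drop = FALSE]
    x0 <- lab_0[stimulus_0 == st, , drop = FALSE]
    for (b in seq_len(n_bins)) {
      tk <- tabulate(xk[, b] + 1L, nbins = decoded_k$M + 1L)
      t0 <- tabulate(x0[, b] + 1L, nbins = decoded_k$M + 1L)
      raw[b] <- raw[b] + sum(tk * t0)
      self[b] <- self[b] + sum(t0 * t0)
    }
  }
  denom <- 4 * trials_per_stimulus^2
  raw <- raw / denom
  self <- self / denom
  rho <- ifelse(self > 0, raw / self, NA_real_)
  list(raw = raw, self = self, rho = rho,
       rho_smooth = gaussian_smooth(rho, smooth_width),
       time = decoded_k$window_start + (seq_len(n_bins) - 0.5) *
         decoded_k$bin)
}
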
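#' Per-cluster firing-rate time series
#'
#' Bins the spikes of each cluster's E neurons (50 ms bins by default)
#' and converts to a per-neuron rate in Hz, i.e. spikes / (bin width x
#' cluster size), so thresholds are independent of cluster size.
#'
#' @param spikes A `spike_data` object from [simulate_trial()].
#' @param net The `synaptic_matrix` the spikes came from.
#' @param roles Which roles/clusters to compute (default: all 14 E
#'   clusters, named by role or `cluster<k>`).
#' @param bin Bin width in seconds (default 0.05).
#' @return A matrix (clusters x bins) of rates in Hz, with attribute
#'   `bin`.
#' @export
cluster_rate_series <- function(spikes, net, roles = NULL, bin = 0.05) {
  n_bins <- ceiling(spikes$duration / bin)
  breaks <- seq(0, n_bins * bin, by = bin)
  if (is.null(roles)) {
    roles <- ifelse(net$role_of_cluster == "generic",
                    paste0("cluster", seq_along(net$role_of_cluster)),
                    net$role_of_cluster)
    cls <- seq_along(net$role_of_cluster)
  } else {
    cls <- vapply(roles, function(r)
      if (is.character(r)) which(net$role_of_cluster == r)
      else as.integer(r), integer(1))
  }
  out <- matrix(0, length(cls), n_bins,
                dimnames = list(roles, NULL))
  for (k in seq_along(cls)) {
    mem <- which(net$cluster == cls[k] & !net$is_inh)
    sel <- spikes$neuron %in% mem
    if (any(sel)) {
      h <- graphics::hist(spikes$time[sel], breaks = breaks,
                          plot = FALSE)$counts
      out[k, ] <- h / (bin * length(mem))
    }
  }
  attr(out, "bin") <- bin
  out
}

#' On/off intervals of a cluster-rate series
#'
#' A cluster is "on" wherever its rate reaches the threshold: either a
#' fraction (default 40%) of its maximum rate across the whole session
#' (`mode = "relative"`; the session maximum must be supplied), or an
#' absolute rate (default 34 Hz, `mode = "absolute"`). Contiguous
#' above-threshold bins merge into intervals; a cluster whose session
#' maximum is 0 is never on.
#'
#' @param rates Numeric vector: one cluster's rate per bin (Hz).
#' @param session_max The cluster's maximum rate over the session (Hz);
#'   required for `mode = "relative"`.
#' @param mode `"relative"` or `"absolute"`.
#' @param threshold Fraction of the session max (relative mode) or
#'   absolute rate in Hz (absolute mode).
#' @param bin Bin width in seconds.
#' @return A data frame with columns `start`, `end` (seconds; onset at
#'   the first bin's left edge) — zero rows if never on.
#' @export
cluster_on_intervals <- function(rates, session_max = NULL,
                                 mode = c("relative", "absolute"),
                                 threshold = if (mode == "relative") 0.40
                                 else 34,
                                 bin = 0.05) {
  mode <- match.arg(mode)
  thr <- if (mode == "relative") {
    if (is.null(session_max))
      abort_field("relative mode needs the session maximum rate")
    if (session_max <= 0) return(data.frame(start = numeric(),
                                            end = numeric()))
    threshold * session_max
  } else threshold
  on <- rates >= thr
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = (starts[keep] - 1L) * bin, end = ends[keep] * bin)
}

#' Score a trial from its action-cluster on-intervals
#'
#' The trial is correct if the action cluster of the cued direction
#' comes on inside the decision window (default 0.5-3 s after stimulus
#' onset) and the other action cluster does not; incorrect in the
#' mirrored case; ambiguous if neither or both come on, in which case a
#' decision is assigned at random (expected accuracy 0.5) and the trial
#' is flagged for exclusion from coding analyses. "Comes on" means an
#' on-interval overlapping the window; set `strict_onset = TRUE` to
#' require the onset itself inside the window.
#'
#' @param on_left,on_right On-interval data frames (from
#'   [cluster_on_intervals()]) for the left / right action cluster.
#' @param correct_direction `"left"` or `"right"` (the cued direction).
#' @param window Decision window in seconds.
#' @param strict_onset Require interval onset inside the window.
#' @param seed Seed for the random decision on ambiguous trials.
#' @return A list with `decision`, `scored` (`"correct"`/
#'   `"incorrect"`), `ambiguous` and `excluded_from_coding`.
#' @export
score_trial <- function(on_left, on_right, correct_direction,
                        window = c(0.5, 3.0), strict_onset = FALSE,
                        seed = 1) {
  stopifnot(correct_direction %in% c("left", "right"))
  came_on <- function(iv) {
    if (!nrow(iv)) return(FALSE)
    if (strict_onset) any(iv$start >= window[1] & iv$start < window[2])
    else any(iv$start < window[2] & iv$end > window[1])
  }
  l_on <- came_on(on_left)
  r_on <- came_on(on_right)
  if (xor(l_on, r_on)) {
    decision <- if (l_on) "left" else "right"
    list(decision = decision,
         scored = if (decision == correct_direction) "correct"
         else "incorrect",
         ambiguous = FALSE, excluded_from_coding = FALSE)
  } else {
    decision <- with_seed(seed, sample(c("left", "right"), 1))
    list(decision = decision,
         scored = if (decision == correct_direction) "correct"
         else "incorrect",
         ambiguous = TRUE, excluded_from_coding = TRUE)
  }
}

#' Earliest cue-cluster onset of a trial
#'
#' Thresholds the two cue clusters' rates exactly as done for action
#' clusters and returns the earliest on-interval start across them, or
#' `NA` if neither cue cluster ever comes on.
#'
#' @param on_cue_left,on_cue_right On-interval data frames for the two
#'   cue clusters.
#' @return Onset time in seconds, or `NA_real_`.
#' @export
detect_cue_onset <- function(on_cue_left, on_cue_right) {
  starts <- c(on_cue_left$start, on_cue_right$start)
  if (!length(starts)) NA_real_ else min(starts)
}
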
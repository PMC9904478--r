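#' Construct an ensemble spike-train session
#'
#' A session holds per-trial spike times for a set of simultaneously
#' recorded neurons together with the behavioural events and labels of a
#' four-taste two-alternative choice task. Spike times are in seconds on
#' a common session clock; each trial records the taste event (first lick
#' to the central spout) and the decision event (first lick to a lateral
#' spout).
#'
#' @param session_id Character scalar identifying the session.
#' @param neuron_ids Integer vector of neuron identifiers.
#' @param trials A list of trial records. Each element is a list with
#'   fields `trial_id` (integer), `stimulus` (one of `"S","Q","M","O"`),
#'   `outcome` (`"correct"` or `"incorrect"`), `taste_time` and
#'   `decision_time` (seconds, `decision_time > taste_time`), and
#'   `spikes`: a list with one numeric vector of spike times per neuron,
#'   in the order of `neuron_ids`.
#' @param subject Optional subject identifier.
#' @param padding Padding in seconds kept around the taste and decision
#'   events when windowing trials (default 0.1).
#' @return An object of class `spike_session`.
#' @seealso [load_session()], [preprocess_session()]
#' @export
spike_session <- function(session_id, neuron_ids, trials,
                          subject = "unknown", padding = 0.1) {
  neuron_ids <- as.integer(neuron_ids)
  if (length(trials) < 1L) abort_field("a session needs at least one trial")
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    for (f in c("trial_id", "stimulus", "outcome", "taste_time",
                "decision_time", "spikes"))
      if (is.null(tr[[f]]))
        abort_field("trial %d is missing field '%s'", k, f)
    if (!tr$stimulus %in% STIMULI)
      abort_field("trial %s: unknown stimulus '%s'", tr$trial_id, tr$stimulus)
    if (!tr$outcome %in% c("correct", "incorrect"))
      abort_field("trial %s: unknown outcome '%s'", tr$trial_id, tr$outcome)
    if (!(tr$decision_time > tr$taste_time))
      abort_field(
        "trial %s: decision_time (%g) must exceed taste_time (%g)",
        tr$trial_id, tr$decision_time, tr$taste_time)
    if (length(tr$spikes) != length(neuron_ids))
      abort_field("trial %s: expected %d spike lists, got %d",
                  tr$trial_id, length(neuron_ids), length(tr$spikes))
    trials[[k]]$spikes <- lapply(tr$spikes, function(s) sort(as.numeric(s)))
    trials[[k]]$trial_id <- as.integer(tr$trial_id)
  }
  structure(
    list(session_id = as.character(session_id), neuron_ids = neuron_ids,
         trials = trials, subject = as.character(subject),
         padding = as.numeric(padding)),
    class = "spike_session")
}

#' @exportS3Method base::print
print.spike_session <- function(x, ...) {
  cat(sprintf("<spike_session '%s'> %d neurons, %d trials\n",
              x$session_id, length(x$neuron_ids), length(x$trials)))
  iei <- session_iei(x)
  cat(sprintf("  IEI mean %.2f s (range %.2f-%.2f); padding %g s\n",
              mean(iei), min(iei), max(iei), x$padding))
  invisible(x)
}

#' Per-trial inter-event intervals of a session
#'
#' The inter-event interval (IEI) of a trial is the time from the taste
#' event to the decision event, in seconds.
#'
#' @param session A `spike_session`.
#' @return Numeric vector, one IEI per trial.
#' @export
session_iei <- function(session) {
  vapply(session$trials, function(tr) tr$decision_time - tr$taste_time,
         numeric(1))
}

#' Trial labels of a session as a data frame
#'
#' @param session A `spike_session`.
#' @return A data frame with columns `trial_id`, `stimulus`, `outcome`,
#'   `taste_time`, `decision_time`, `iei`, `direction` (cued direction)
#'   and `quality` (taste quality).
#' @export
session_trials <- function(session) {
  stim <- vapply(session$trials, `[[`, character(1), "stimulus")
  data.frame(
    trial_id = vapply(session$trials, `[[`, integer(1), "trial_id"),
    stimulus = stim,
    outcome = vapply(session$trials, `[[`, character(1), "outcome"),
    taste_time = vapply(session$trials, `[[`, numeric(1), "taste_time"),
    decision_time = vapply(session$trials, `[[`, numeric(1), "decision_time"),
    iei = session_iei(session),
    direction = stimulus_direction(stim),
    quality = stimulus_quality(stim),
    stringsAsFactors = FALSE)
}

#' Write a session to a plain-text file
#'
#' The format is a single TSV file with three sections introduced by
#' marker lines: `#%meta` (key: value pairs), `#%trials` (columns
#' `trial_id`, `stimulus`, `outcome`, `taste_time_s`, `decision_time_s`)
#' and `#%spikes` (columns `trial_id`, `neuron_id`, `spike_time_s`).
#' Times are written with 17 significant digits so that a save/load
#' round trip is bitwise exact.
#'
#' @param session A `spike_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c("#%spikestates-session", "#%meta",
               paste0("session_id: ", session$session_id),
               paste0("subject: ", session$subject),
               paste0("padding: ", num(session$padding)),
               paste0("neuron_ids: ",
                      paste(session$neuron_ids, collapse = ","))), con)
  writeLines("#%trials", con)
  writeLines("trial_id\tstimulus\toutcome\ttaste_time_s\tdecision_time_s", con)
  for (tr in session$trials)
    writeLines(paste(tr$trial_id, tr$stimulus, tr$outcome,
                     num(tr$taste_time), num(tr$decision_time),
                     sep = "\t"), con)
  writeLines("#%spikes", con)
  writeLines("trial_id\tneuron_id\tspike_time_s", con)
  for (tr in session$trials)
    for (j in seq_along(session$neuron_ids)) {
      sp <- tr$spikes[[j]]
      if (length(sp))
        writeLines(paste(tr$trial_id, session$neuron_ids[j], num(sp),
                         sep = "\t"), con)
    }
  invisible(path)
}

#' Read a session from a plain-text file
#'
#' Parses the format written by [save_session()] and validates it; a
#' malformed file raises an error naming the offending section or trial.
#'
#' @param path File path.
#' @return A `spike_session`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) abort_field("no such session file: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "#%spikestates-session")
    abort_field("%s: missing '#%%spikestates-session' header (line 1)", path)
  sec <- function(name) {
    i <- which(lines == paste0("#%", name))
    if (length(i) != 1) abort_field("%s: missing '#%%%s' section", path, name)
    i
  }
  i_meta <- sec("meta"); i_tr <- sec("trials"); i_sp <- sec("spikes")
  meta_lines <- lines[(i_meta + 1):(i_tr - 1)]
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^([a-z_]+):[ ]?(.*)$", ln))[[1]]
    if (length(kv) != 3) abort_field("%s: bad meta line '%s'", path, ln)
    meta[[kv[2]]] <- kv[3]
  }
  for (f in c("session_id", "padding", "neuron_ids"))
    if (is.null(meta[[f]])) abort_field("%s: meta field '%s' missing", path, f)
  neuron_ids <- as.integer(strsplit(meta$neuron_ids, ",")[[1]])

  trials_df <- read.delim(
    textConnection(lines[(i_tr + 1):(i_sp - 1)]), stringsAsFactors = FALSE,
    colClasses = c(taste_time_s = "numeric", decision_time_s = "numeric"))
  need <- c("trial_id", "stimulus", "outcome", "taste_time_s",
            "decision_time_s")
  if (!all(need %in% names(trials_df)))
    abort_field("%s: trials table must have columns %s", path,
                paste(need, collapse = ", "))
  sp_lines <- lines[(i_sp + 1):length(lines)]
  spikes_df <- if (length(sp_lines) > 1)
    read.delim(textConnection(sp_lines), stringsAsFactors = FALSE,
               colClasses = c(spike_time_s = "numeric"))
  else data.frame(trial_id = integer(), neuron_id = integer(),
                  spike_time_s = numeric())

  trials <- vector("list", nrow(trials_df))
  for (k in seq_len(nrow(trials_df))) {
    row <- trials_df[k, ]
    if (!(row$decision_time_s > row$taste_time_s))
      abort_field(
        "%s: trial %d: decision_time (%g) not after taste_time (%g)",
        path, row$trial_id, row$decision_time_s, row$taste_time_s)
    sub <- spikes_df[spikes_df$trial_id == row$trial_id, ]
    spikes <- lapply(neuron_ids, function(nid)
      sort(sub$spike_time_s[sub$neuron_id == nid]))
    trials[[k]] <- list(trial_id = row$trial_id, stimulus = row$stimulus,
                        outcome = row$outcome, taste_time = row$taste_time_s,
                        decision_time = row$decision_time_s, spikes = spikes)
  }
  bad <- setdiff(unique(spikes_df$neuron_id), neuron_ids)
  if (length(bad))
    abort_field("%s: spikes table names unknown neuron_id(s): %s", path,
                paste(bad, collapse = ","))
  spike_session(meta$session_id, neuron_ids, trials,
                subject = meta$subject %||% "unknown",
                padding = as.numeric(meta$padding))
}

#' Window, filter and rate-screen a session
#'
#' Applies the standard preprocessing for HMM analysis: spikes are
#' clipped per trial to the padded analysis window
#' `[taste_time - padding, decision_time + padding]`; each neuron's mean
#' firing rate is computed over the concatenation of these windows;
#' neurons firing below `min_rate` are excluded; the session is rejected
#' if fewer than `min_neurons` neurons survive.
#'
#' @param session A `spike_session`.
#' @param min_rate Minimum mean firing rate in Hz (default 2).
#' @param min_neurons Minimum number of surviving neurons (default 3).
#' @param padding Padding in seconds around the events (default: the
#'   session's own padding).
#' @return A `preprocessed_session` (a `spike_session` with extra fields
#'   `mean_rates`, `iei` and `dropped_neurons`), or an object of class
#'   `session_rejection` if too few neurons survive.
#' @export
preprocess_session <- function(session, min_rate = 2, min_neurons = 3,
                               padding = NULL) {
  stopifnot(inherits(session, "spike_session"))
  if (length(session$trials) == 0) abort_field("empty session")
  padding <- padding %||% session$padding
  n <- length(session$neuron_ids)
  total_window <- 0
  counts <- numeric(n)
  trials <- session$trials
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    lo <- tr$taste_time - padding
    hi <- tr$decision_time + padding
    total_window <- total_window + (hi - lo)
    for (j in seq_len(n)) {
      sp <- tr$spikes[[j]]
      sp <- sp[sp >= lo & sp <= hi]
      trials[[k]]$spikes[[j]] <- sp
      counts[j] <- counts[j] + length(sp)
    }
  }
  rates <- counts / total_window
  keep <- rates >= min_rate
  if (sum(keep) < min_neurons) {
    return(structure(
      list(session_id = session$session_id,
           reason = sprintf("only %d neurons with rate >= %g Hz (need %d)",
                            sum(keep), min_rate, min_neurons),
           mean_rates = stats::setNames(rates,
                                        as.character(session$neuron_ids))),
      class = "session_rejection"))
  }
  for (k in seq_along(trials)) trials[[k]]$spikes <- trials[[k]]$spikes[keep]
  out <- session
  out$neuron_ids <- session$neuron_ids[keep]
  out$trials <- trials
  out$padding <- padding
  out$mean_rates <- stats::setNames(rates[keep],
                                    as.character(out$neuron_ids))
  out$dropped_neurons <- session$neuron_ids[!keep]
  out$iei <- session_iei(out)
  class(out) <- c("preprocessed_session", "spike_session")
  out
}

#' @exportS3Method base::print
print.session_rejection <- function(x, ...) {
  cat(sprintf("<session_rejection '%s'> %s\n", x$session_id, x$reason))
  invisible(x)
}
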
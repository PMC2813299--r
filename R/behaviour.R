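# Error taxonomy, structure-consistency scoring, learning curves and
# smoothing, and the error-free reanalysis.

#' Classify the errors of a session
#'
#' Two kinds of forgetting-related error are tagged on every incorrect trial,
#' evaluated against the session prefix: `repeat_wrong` - the same wrong
#' response was already given to this stimulus before; `forgot_correct` - the
#' stimulus was answered correctly at some earlier trial. A trial may carry
#' both tags (both are reported separately). An ideal Bayesian actor commits
#' neither kind.
#'
#' @param session An `sl_session`.
#' @return Data frame with one row per incorrect trial: `index`, `stimulus`,
#'   `action`, `repeat_wrong`, `forgot_correct`.
#' @export
classify_errors <- function(session) {
  tr <- session$trials
  errs <- which(!tr$correct)
  out <- data.frame(index = tr$index[errs], stimulus = tr$stimulus[errs],
                    action = tr$action[errs],
                    repeat_wrong = logical(length(errs)),
                    forgot_correct = logical(length(errs)))
  for (j in seq_along(errs)) {
    i <- errs[j]
    prev <- seq_len(i - 1L)
    same_stim <- prev[tr$stimulus[prev] == tr$stimulus[i]]
    out$repeat_wrong[j] <- any(!tr$correct[same_stim] &
                                 tr$action[same_stim] == tr$action[i])
    out$forgot_correct[j] <- any(tr$correct[same_stim])
  }
  out
}

#' Structure consistency of an error
#'
#' An erroneous response is consistent with a previously learned structure if
#' it equals `g(stimulus)` for some member `g` of that structure's member
#' set (e.g. either shift mapping for the shift structure). Undefined for the
#' unstructured class and for the first mapping of a protocol.
#'
#' @param stimulus,action The erroneous trial's indices.
#' @param previous_structure A structure id (`"S1_identity"`, `"S2_shift"`,
#'   `"S3_mirror"`) or a mapping label whose structure is used.
#' @return Logical.
#' @export
structure_consistency <- function(stimulus, action, previous_structure) {
  if (previous_structure %in% MAPPING_LABELS)
    previous_structure <- structure_of(previous_structure)
  if (previous_structure == "S4_random")
    stop("structure consistency is undefined for the unstructured class",
         call. = FALSE)
  members <- structure_classes()[[previous_structure]]$members
  any(vapply(members, function(img) img[stimulus] == action, logical(1)))
}

#' Fraction of sessions answering correctly at each aligned trial
#'
#' Sessions are aligned at their first trial; for each trial index the
#' fraction of sessions with a correct response is returned. By default the
#' series is truncated at the shortest session; with `pad = TRUE` it extends
#' to the longest session with the per-trial number of contributing sessions
#' reported (missingness explicit, never imputed).
#'
#' @param sessions List of `sl_session` objects.
#' @param pad Extend beyond the shortest session?
#' @return Data frame with `trial`, `fraction_correct`, `n_sessions`.
#' @export
correct_action_frequency <- function(sessions, pad = FALSE) {
  stopifnot(length(sessions) > 0)
  lens <- vapply(sessions, function(s) nrow(s$trials), integer(1))
  upto <- if (pad) max(lens) else min(lens)
  frac <- numeric(upto); nses <- integer(upto)
  for (t in seq_len(upto)) {
    have <- lens >= t
    nses[t] <- sum(have)
    frac[t] <- mean(vapply(sessions[have],
                           function(s) s$trials$correct[t], logical(1)))
  }
  data.frame(trial = seq_len(upto), fraction_correct = frac,
             n_sessions = nses)
}

#' Savitzky-Golay smoothing of a learning curve
#'
#' Local least-squares polynomial smoothing (default order 1, window 11, the
#' setting used for trial-by-trial curves). For order 1 the interior points
#' equal the centered moving average of the window; linear series are fixed
#' points. Series shorter than the window are returned unchanged with a
#' warning.
#'
#' @param series Numeric vector.
#' @param order Polynomial order.
#' @param window Odd window length, greater than `order`.
#' @return Smoothed series of the same length.
#' @export
savgol_smooth <- function(series, order = 1L, window = 11L) {
  stopifnot(window %% 2L == 1L, order < window)
  if (length(series) < window) {
    warning("series shorter than the smoothing window; returned unsmoothed")
    return(series)
  }
  as.numeric(signal::sgolayfilt(series, p = order, n = window))
}

#' Centered moving average with truncated edges
#'
#' @param series Numeric vector.
#' @param window Window length (>= 1); near the edges the window is truncated
#'   to the available points.
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(series, window = 50L) {
  stopifnot(window >= 1L)
  n <- length(series)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - left):min(n, i + right)])
  }, numeric(1))
}

#' Trials to criterion when disregarding error trials
#'
#' The session's trial count minus its number of incorrect trials - the
#' "error-free" reanalysis used to check that facilitation is not an artifact
#' of differential error rates.
#'
#' @param session An `sl_session`.
#' @return Adjusted count, or `NA` for a censored session.
#' @export
errorfree_trial_counts <- function(session) {
  if (!session$learned) return(NA_integer_)
  session$trials_to_criterion - sum(!session$trials$correct)
}
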
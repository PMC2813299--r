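# Trial loop for one mapping: stimuli presented in shuffled blocks of nine
# (or iid-uniform), boolean feedback, stop at the learning criterion.

#' Learning criterion on a trial sequence
#'
#' A mapping counts as learned once the subject has given the correct response
#' to each of the nine stimuli without any intervening mistake, i.e. the
#' maximal error-free suffix of the trial sequence covers all nine stimuli.
#'
#' @param trials Data frame with columns `stimulus` and `correct` (ordered).
#' @param n_items Number of distinct stimuli (default 9).
#' @return `TRUE` iff the criterion holds at the final trial.
#' @export
is_learned <- function(trials, n_items = 9L) {
  stopifnot(nrow(trials) > 0L)
  correct <- as.logical(trials$correct)
  errs <- which(!correct)
  from <- if (length(errs)) max(errs) + 1L else 1L
  if (from > nrow(trials)) return(FALSE)
  length(unique(trials$stimulus[from:nrow(trials)])) == n_items
}

#' Run one learning session
#'
#' Presents stimuli to an agent until the learning criterion ([is_learned()])
#' holds or `max_trials` is reached. Stimuli are drawn either in shuffled
#' blocks of nine (default; every block is a fresh uniform permutation of the
#' stimuli, which guarantees the criterion is reachable within 18 trials of
#' the last error) or iid-uniform.
#'
#' @param agent An agent: a list with `act(stimulus) -> action` and
#'   `observe(stimulus, action, correct)`; see [agent_sl_bayes()] etc.
#' @param mapping An [sl_mapping()].
#' @param max_trials Trial budget; sessions that do not reach criterion are
#'   returned with `learned = FALSE` (censored).
#' @param schedule `"blocks"` or `"iid"`.
#' @param subject_id,group Metadata copied into the session.
#' @return An object of class `sl_session`: list with `subject_id`, `group`,
#'   `mapping`, `trials` (data frame `index`, `stimulus`, `action`,
#'   `correct`), `learned`, and `trials_to_criterion` (`NA` if censored).
#' @export
run_session <- function(agent, mapping, max_trials = 2000L,
                        schedule = c("blocks", "iid"),
                        subject_id = NA_character_, group = NA_integer_) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(mapping, "sl_mapping"), max_trials >= 9L)
  image <- mapping$image
  stim <- integer(max_trials); act <- integer(max_trials)
  corr <- logical(max_trials)
  covered <- logical(9L)   # stimuli answered correctly since the last error
  block <- integer(0)
  n <- 0L
  learned <- FALSE
  while (n < max_trials) {
    if (schedule == "blocks") {
      if (!length(block)) block <- sample.int(9L)
      s <- block[1L]; block <- block[-1L]
    } else {
      s <- sample.int(9L, 1L)
    }
    a <- agent$act(s)
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 1 || a > 9 ||
        a != round(a))
      stop("agent returned an action outside 1..9", call. = FALSE)
    a <- as.integer(a)
    ok <- (a == image[s])
    n <- n + 1L
    stim[n] <- s; act[n] <- a; corr[n] <- ok
    agent$observe(s, a, ok)
    if (ok) covered[s] <- TRUE else covered[] <- FALSE
    if (all(covered)) { learned <- TRUE; break }
  }
  trials <- data.frame(index = seq_len(n), stimulus = stim[seq_len(n)],
                       action = act[seq_len(n)], correct = corr[seq_len(n)])
  structure(list(subject_id = subject_id, group = group, mapping = mapping,
                 trials = trials, learned = learned,
                 trials_to_criterion = if (learned) n else NA_integer_),
            class = "sl_session")
}

#' @export
print.sl_session <- function(x, ...) {
  cat("<sl_session> subject=", x$subject_id, " group=", x$group,
      " mapping=", x$mapping$label,
      " trials=", nrow(x$trials),
      if (x$learned) " (learned)" else " (censored)", "\n", sep = "")
  invisible(x)
}

#' Oracle agent (always answers correctly)
#' @param mapping The [sl_mapping()] it knows.
#' @return An agent list.
#' @export
agent_oracle <- function(mapping) {
  image <- mapping$image
  list(name = "oracle",
       act = function(s) image[s],
       observe = function(s, a, correct) invisible(NULL))
}

#' Uniform-random agent (never learns)
#' @return An agent list.
#' @export
agent_random <- function() {
  list(name = "random",
       act = function(s) sample.int(9L, 1L),
       observe = function(s, a, correct) invisible(NULL))
}
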
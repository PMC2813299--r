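# Synthetic behavioural cohorts: structure-learning Bayesian agents degraded
# by lapses (uniformly random actions) and forgetting (deletion of stored
# evidence constraints). This stands in for a human cohort - the degradation
# mechanism is a synthetic device, chosen because it preserves the exact
# inference machinery while producing both kinds of forgetting error and
# slower-than-ideal learning.

#' Generate a synthetic two-group cohort
#'
#' Simulates `n_per_group` subjects per protocol group, each learning the six
#' mappings of its group's order with a structure-learning (or flat) Bayesian
#' agent subject to lapse and forgetting. Per-subject seeds are derived from
#' the master seed, so a fixed seed reproduces the cohort exactly.
#'
#' @param n_per_group Subjects per group (default 10, i.e. 20 in total).
#' @param lapse Per-trial probability of a uniformly random action
#'   (default 0.05).
#' @param forget Per-trial probability of deleting one stored evidence
#'   constraint (default 0.02).
#' @param base_model `"hierarchical"` (default) or `"flat"`.
#' @param seed Optional master seed.
#' @param elevation Prior elevation factor for a previously experienced
#'   structure (or mapping, for the flat model).
#' @param max_trials,schedule Passed to [run_session()].
#' @return A list of `sl_session` objects (class `sl_cohort`), six per
#'   subject, in protocol order.
#' @export
generate_cohort <- function(n_per_group = 10L, lapse = 0.05, forget = 0.02,
                            base_model = c("hierarchical", "flat"),
                            seed = NULL, elevation = 10,
                            max_trials = 2000L, schedule = "blocks") {
  base_model <- match.arg(base_model)
  if (!is.null(seed)) set.seed(seed)
  n_total <- 2L * n_per_group
  subject_seeds <- sample.int(.Machine$integer.max, n_total)
  sessions <- vector("list", n_total * 6L)
  idx <- 0L
  subj <- 0L
  for (group in 1:2) {
    order <- protocol_order(group)
    for (i in seq_len(n_per_group)) {
      subj <- subj + 1L
      sid <- sprintf("g%d_s%02d", group, i)
      set.seed(subject_seeds[subj])
      random_map <- sample_random_mapping()
      for (k in seq_along(order)) {
        lab <- order[k]
        map <- if (lab == "random") random_map else build_mapping(lab)
        seen <- order[seq_len(k - 1L)]
        agent <- if (base_model == "hierarchical")
          agent_sl_bayes(sl_stage_prior(lab, seen, elevation),
                         lapse = lapse, forget = forget)
        else
          agent_flat_bayes(flat_stage_prior(lab, seen, elevation),
                           lapse = lapse, forget = forget)
        idx <- idx + 1L
        sessions[[idx]] <- run_session(agent, map, max_trials = max_trials,
                                       schedule = schedule,
                                       subject_id = sid, group = group)
      }
    }
  }
  structure(sessions, class = "sl_cohort")
}

#' @export
print.sl_cohort <- function(x, ...) {
  subs <- unique(vapply(x, function(s) s$subject_id, character(1)))
  cat("<sl_cohort> ", length(subs), " subjects, ", length(x),
      " sessions\n", sep = "")
  invisible(x)
}

#' Trials-to-criterion table of a cohort
#'
#' @param sessions An `sl_cohort` (list of `sl_session`), six sessions per
#'   subject.
#' @param counts `"raw"` for trials to criterion, `"errorfree"` for the
#'   error-trial-discarded counts ([errorfree_trial_counts()]).
#' @return An `sl_cohort_table` (subjects x six mapping labels, `NA` =
#'   censored) with per-row `group` attribute.
#' @export
cohort_to_table <- function(sessions, counts = c("raw", "errorfree")) {
  counts <- match.arg(counts)
  sids <- vapply(sessions, function(s) s$subject_id, character(1))
  subs <- unique(sids)
  tab <- matrix(NA_integer_, length(subs), 6L,
                dimnames = list(subs, MAPPING_LABELS))
  grp <- integer(length(subs))
  for (j in seq_along(subs)) {
    ses <- sessions[sids == subs[j]]
    labs <- vapply(ses, function(s) s$mapping$label, character(1))
    if (!setequal(labs, MAPPING_LABELS) || length(ses) != 6L)
      stop("subject ", subs[j], " is missing mapping slots", call. = FALSE)
    grp[j] <- ses[[1L]]$group
    for (s in ses) {
      n <- if (counts == "raw") s$trials_to_criterion
           else errorfree_trial_counts(s)
      tab[j, s$mapping$label] <- n
    }
  }
  structure(tab, group = grp, model = "cohort",
            class = c("sl_cohort_table", "matrix"))
}
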
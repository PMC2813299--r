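# Exact Bayesian learners over the permutation hypothesis space.
#
# Flat model: one prior weight per hypothesis, specified as a weight for each
# of the five structured mappings plus a shared weight for every unstructured
# permutation. Hierarchical model: a prior over the four structure classes
# with a uniform conditional over each class's members. Both use the binary
# likelihood (a hypothesis is either compatible with all feedback so far or
# ruled out), so posteriors are ratios of weighted compatible counts,
# evaluated with forced-assignment permanents - never by dense enumeration
# in production.

#' Prior for the flat (non-hierarchical) Bayesian model
#'
#' Structured mappings get `structured` times the weight of any single
#' unstructured permutation; the default 1000:1 follows the design in which
#' structured mappings are a priori a thousand times more probable than
#' random ones. Individual structured weights can be overridden, e.g. to
#' elevate the previously learned mapping.
#'
#' @param structured Either a single weight applied to all five structured
#'   mappings or a named vector over their labels.
#' @param random Weight of each unstructured permutation.
#' @return An object of class `sl_flat_prior`.
#' @export
flat_prior <- function(structured = 1000, random = 1) {
  if (length(structured) == 1L && is.null(names(structured)))
    structured <- setNames(rep(structured, 5L), STRUCTURED_LABELS)
  stopifnot(all(STRUCTURED_LABELS %in% names(structured)),
            all(structured > 0), random > 0)
  structure(list(structured = structured[STRUCTURED_LABELS], random = random),
            class = "sl_flat_prior")
}

#' Prior for the hierarchical (structure-learning) Bayesian model
#'
#' Probabilities over the four structure classes; members within a class are
#' uniform. The default gives the identity, shift and mirror structures equal
#' mass and the unstructured class a thousand times less.
#'
#' @param S Positive weights, named `S1_identity`, `S2_shift`, `S3_mirror`,
#'   `S4_random`; normalized internally.
#' @return An object of class `sl_structure_prior`.
#' @export
structure_prior <- function(S = c(S1_identity = 1, S2_shift = 1,
                                  S3_mirror = 1, S4_random = 0.001)) {
  nm <- c("S1_identity", "S2_shift", "S3_mirror", "S4_random")
  stopifnot(all(nm %in% names(S)), all(S > 0))
  S <- S[nm] / sum(S[nm])
  structure(list(S = S), class = "sl_structure_prior")
}

# Which of the five structured mappings remain compatible with the evidence.
structured_compat <- function(ev) {
  vapply(STRUCTURED_LABELS,
         function(k) image_compatible(build_mapping(k)$image, ev),
         logical(1))
}

#' Posterior action distribution of the flat Bayesian model
#'
#' `p(a | s, D)` is the posterior mass of the compatible hypotheses mapping
#' stimulus `s` to action `a`, computed per weight class: the shared-weight
#' unstructured mass comes from forced-assignment permanents and the five
#' structured mappings contribute their individual excess weights by direct
#' constraint checking.
#'
#' @param prior An [flat_prior()].
#' @param ev An `sl_evidence` object (must be consistent).
#' @param stimulus Stimulus in 1..9.
#' @return Probability vector over the 9 actions.
#' @export
flat_action_distribution <- function(prior, ev, stimulus) {
  s <- as.integer(stimulus)
  counts <- compatible_action_counts(ev, s)   # includes structured survivors
  w <- prior$random * counts
  comp <- structured_compat(ev)
  for (k in STRUCTURED_LABELS[comp]) {
    a <- build_mapping(k)$image[s]
    w[a] <- w[a] + (prior$structured[[k]] - prior$random)
  }
  tot <- sum(w)
  if (tot <= 0) stop("inconsistent evidence: no compatible hypothesis",
                     call. = FALSE)
  unname(w / tot)
}

#' Posterior of the hierarchical (structure-learning) Bayesian model
#'
#' Computes the posterior over the four structure classes,
#' `P(S | D) \eqn{\propto} P(S) \eqn{\sum_{h \in S}} P(D | h) P(h | S)`,
#' and the predictive action distribution per stimulus, a mixture of the
#' within-structure predictive distributions weighted by `P(S | D)`. With the
#' binary likelihood the class likelihood reduces to (compatible members) /
#' (class size).
#'
#' @param prior An [structure_prior()].
#' @param ev An `sl_evidence` object.
#' @param stimuli Stimuli for which to return action distributions
#'   (default all nine).
#' @return List with `structures` (probabilities over the four classes) and
#'   `actions` (matrix, one row per requested stimulus, columns = actions).
#' @export
hierarchical_posterior <- function(prior, ev, stimuli = 1:9) {
  comp <- structured_compat(ev)
  n_tot <- count_compatible(ev)
  if (n_tot <= 0) stop("inconsistent evidence: no compatible hypothesis",
                       call. = FALSE)
  n4 <- n_tot - sum(comp)
  cls <- structure_classes()
  lik <- c(S1_identity = as.numeric(comp[["identity"]]),
           S2_shift    = sum(comp[c("right_shift", "left_shift")]) / 2,
           S3_mirror   = sum(comp[c("horizontal_mirror", "vertical_mirror")]) / 2,
           S4_random   = n4 / cls$S4_random$size)
  post <- prior$S * lik
  post <- post / sum(post)

  images <- lapply(STRUCTURED_LABELS, function(k) build_mapping(k)$image)
  names(images) <- STRUCTURED_LABELS
  actions <- matrix(0, length(stimuli), 9L,
                    dimnames = list(paste0("s", stimuli), NULL))
  for (i in seq_along(stimuli)) {
    s <- stimuli[i]
    p <- numeric(9L)
    counts <- compatible_action_counts(ev, s)
    # unstructured class: remove the structured survivors from the counts
    if (post[["S4_random"]] > 0 && n4 > 0) {
      c4 <- counts
      for (k in STRUCTURED_LABELS[comp]) {
        a <- images[[k]][s]
        c4[a] <- c4[a] - 1
      }
      p <- p + post[["S4_random"]] * c4 / n4
    }
    if (post[["S1_identity"]] > 0 && comp[["identity"]])
      p[images$identity[s]] <- p[images$identity[s]] + post[["S1_identity"]]
    for (cl in c("S2_shift", "S3_mirror")) {
      if (post[[cl]] <= 0) next
      labs <- cls[[cl]]$labels
      alive <- labs[comp[labs]]
      for (k in alive) {
        a <- images[[k]][s]
        p[a] <- p[a] + post[[cl]] / length(alive)
      }
    }
    actions[i, ] <- p
  }
  list(structures = post, actions = actions)
}

#' Thompson-sampling action choice
#'
#' Samples a hypothesis from the posterior and executes that hypothesis's
#' response for the stimulus; marginally this is a draw from the posterior
#' action distribution, which is how it is implemented.
#'
#' @param action_probs Probability vector over the 9 actions (from
#'   [flat_action_distribution()] or [hierarchical_posterior()]).
#' @return Sampled action in 1..9.
#' @export
thompson_act <- function(action_probs) {
  stopifnot(length(action_probs) == 9L, all(action_probs >= 0))
  sample.int(9L, 1L, prob = action_probs)
}

# Shared closure machinery for the two Bayesian agents. `lapse` replaces the
# chosen action by a uniform one; `forget` deletes one uniformly chosen
# stored constraint per trial (evaluated before acting). Both default to 0
# (the ideal learner).
bayes_agent <- function(dist_fun, name, lapse = 0, forget = 0) {
  stopifnot(lapse >= 0, lapse < 1, forget >= 0, forget < 1)
  ev <- evidence_new()
  maybe_forget <- function() {
    if (forget <= 0 || runif(1) >= forget) return(invisible(NULL))
    np <- which(!is.na(ev$pos))
    nn <- which(ev$neg)
    tot <- length(np) + length(nn)
    if (tot == 0L) return(invisible(NULL))
    k <- sample.int(tot, 1L)
    if (k <= length(np)) {
      ev$pos[np[k]] <<- NA_integer_
    } else {
      ev$neg[nn[k - length(np)]] <<- FALSE
    }
    invisible(NULL)
  }
  list(
    name = name,
    act = function(s) {
      maybe_forget()
      if (lapse > 0 && runif(1) < lapse) return(sample.int(9L, 1L))
      thompson_act(dist_fun(ev, s))
    },
    observe = function(s, a, correct) {
      ev <<- update_evidence(ev, s, a, correct)
      invisible(NULL)
    },
    evidence = function() ev
  )
}

#' Flat Bayesian agent
#'
#' Thompson-sampling learner over all 9! mappings under a [flat_prior()].
#'
#' @param prior An [flat_prior()].
#' @param lapse Per-trial probability of a uniformly random action.
#' @param forget Per-trial probability of deleting one stored evidence
#'   constraint (a synthetic degradation device; the ideal learner has 0).
#' @return An agent list with `act`, `observe` and an `evidence` accessor.
#' @export
agent_flat_bayes <- function(prior = flat_prior(), lapse = 0, forget = 0) {
  bayes_agent(function(ev, s) flat_action_distribution(prior, ev, s),
              "flat_bayes", lapse, forget)
}

#' Hierarchical (structure-learning) Bayesian agent
#'
#' Thompson-sampling learner that maintains a posterior over the four
#' structure classes as well as over individual mappings.
#'
#' @inheritParams agent_flat_bayes
#' @param prior An [structure_prior()].
#' @return An agent list with `act`, `observe` and an `evidence` accessor.
#' @export
agent_sl_bayes <- function(prior = structure_prior(), lapse = 0, forget = 0) {
  bayes_agent(function(ev, s)
    hierarchical_posterior(prior, ev, stimuli = s)$actions[1L, ],
    "sl_bayes", lapse, forget)
}

#' Trial-by-trial predictive probability of the correct action
#'
#' Replays a behavioural stream through a Bayesian model: at each trial the
#' model's probability of the *correct* action is computed given the evidence
#' from the preceding trials (the model conditions on the subject's actions
#' and feedback, not on its own choices).
#'
#' @param session An `sl_session`.
#' @param model `"flat"` or `"hierarchical"`.
#' @param prior A matching prior object (defaults: [flat_prior()] /
#'   [structure_prior()]).
#' @return Numeric vector, one probability per trial.
#' @export
predictive_correct_probability <- function(session,
                                           model = c("flat", "hierarchical"),
                                           prior = NULL) {
  model <- match.arg(model)
  if (is.null(prior))
    prior <- if (model == "flat") flat_prior() else structure_prior()
  image <- session$mapping$image
  ev <- evidence_new()
  tr <- session$trials
  out <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    s <- tr$stimulus[i]
    p <- if (model == "flat") flat_action_distribution(prior, ev, s)
         else hierarchical_posterior(prior, ev, stimuli = s)$actions[1L, ]
    out[i] <- p[image[s]]
    ev <- update_evidence(ev, s, tr$action[i], tr$correct[i])
  }
  out
}
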
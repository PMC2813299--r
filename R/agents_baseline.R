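# Associative baselines: a linear network trained by the delta rule
# (supervised - the task's correct response serves as the target), and a
# Rescorla-Wagner reinforcement learner with softmax action selection that
# learns from binary reward only.

one_hot_matrix <- function(image) {
  W <- matrix(0, 9L, 9L)
  W[cbind(image, 1:9)] <- 1
  W
}

#' Delta-rule weight update of the linear network
#'
#' With one-hot input `x` (stimulus) and one-hot target `t` (correct
#' response), the update `W' = W + eta (t - W x) x^T` changes only the
#' presented stimulus's column.
#'
#' @param W 9x9 weight matrix (output `y = W x`).
#' @param stimulus,target Indices in 1..9.
#' @param eta Learning rate (> 0).
#' @return Updated weight matrix.
#' @export
nn_update <- function(W, stimulus, target, eta = 0.1) {
  s <- as.integer(stimulus); t <- as.integer(target)
  stopifnot(s >= 1L, s <= 9L, t >= 1L, t <= 9L, eta > 0)
  tvec <- numeric(9L); tvec[t] <- 1
  W[, s] <- W[, s] + eta * (tvec - W[, s])
  W
}

# Mean squared error of the network over all nine stimuli:
# mean_s || t_s - W x_s ||^2.
nn_mse <- function(W, image) {
  Tm <- one_hot_matrix(image)
  mean(colSums((Tm - W)^2))
}

#' Trials for the linear network to reach the error threshold
#'
#' Initializes the weights to the one-hot matrix of `init_mapping` (a network
#' pre-trained to that mapping), then trains on `target_mapping` with
#' supervised targets under the standard stimulus schedule. Performance is
#' the number of stimulus presentations until the mean squared error over all
#' nine stimuli first falls below `epsilon` (0 if already below at start).
#'
#' @param target_mapping,init_mapping [sl_mapping()] objects.
#' @param eta Learning rate.
#' @param epsilon Error threshold on the mean squared output error.
#' @param max_trials Budget; `NA` (censored) if not reached.
#' @param schedule `"blocks"` or `"iid"`.
#' @return List with `trials` (integer or `NA`) and `learned`.
#' @export
nn_trials_to_threshold <- function(target_mapping, init_mapping,
                                   eta = 0.1, epsilon = 0.01,
                                   max_trials = 2000L,
                                   schedule = c("blocks", "iid")) {
  schedule <- match.arg(schedule)
  stopifnot(eta > 0, epsilon > 0)
  image <- target_mapping$image
  W <- one_hot_matrix(init_mapping$image)
  if (nn_mse(W, image) < epsilon)
    return(list(trials = 0L, learned = TRUE))
  block <- integer(0)
  for (n in seq_len(max_trials)) {
    if (schedule == "blocks") {
      if (!length(block)) block <- sample.int(9L)
      s <- block[1L]; block <- block[-1L]
    } else s <- sample.int(9L, 1L)
    W <- nn_update(W, s, image[s], eta)
    if (nn_mse(W, image) < epsilon)
      return(list(trials = n, learned = TRUE))
  }
  list(trials = NA_integer_, learned = FALSE)
}

#' Softmax action probabilities
#'
#' `p(a) \eqn{\propto} exp(Q[s, a] / tau)`; computed with the shift-by-max
#' trick so it is overflow-safe for any finite values.
#'
#' @param q_row Numeric vector of 9 action values for the current stimulus.
#' @param tau Temperature (> 0); small values concentrate on the argmax.
#' @return Probability vector over the 9 actions.
#' @export
rl_policy <- function(q_row, tau = 0.15) {
  stopifnot(length(q_row) == 9L, tau > 0, all(is.finite(q_row)))
  z <- q_row / tau
  e <- exp(z - max(z))
  e / sum(e)
}

#' Rescorla-Wagner value update
#'
#' `q' = q + alpha (r - q)` - the prediction-error (delta) rule on the value
#' of the taken stimulus-action pair.
#'
#' @param q Current value.
#' @param r Reward (0 or 1).
#' @param alpha Learning rate in (0, 1].
#' @return Updated value.
#' @export
rl_update <- function(q, r, alpha = 0.3) {
  stopifnot(alpha >= 0, alpha <= 1)
  q + alpha * (r - q)
}

#' Rescorla-Wagner/softmax agent
#'
#' Q is initialized to the one-hot table of `init_mapping` (value 1 on its
#' stimulus-response pairs, 0 elsewhere); actions are sampled by
#' [rl_policy()] and the taken pair's value updated by [rl_update()] with
#' binary reward.
#'
#' @param init_mapping [sl_mapping()] used to initialize Q.
#' @param alpha,tau Learning rate and softmax temperature.
#' @return An agent list with `act`, `observe` and a `values` accessor.
#' @export
agent_rl <- function(init_mapping, alpha = 0.3, tau = 0.15) {
  Q <- t(one_hot_matrix(init_mapping$image))  # Q[s, a]
  list(
    name = "rl",
    act = function(s) sample.int(9L, 1L, prob = rl_policy(Q[s, ], tau)),
    observe = function(s, a, correct) {
      Q[s, a] <<- rl_update(Q[s, a], as.numeric(correct), alpha)
      invisible(NULL)
    },
    values = function() Q
  )
}

#' Trials to criterion for the reinforcement learner
#'
#' Runs [agent_rl()] on `target_mapping` under the behavioural learning
#' criterion (all nine stimuli correct with no intervening mistakes),
#' mirroring the two distinct performance definitions of the network
#' (error threshold) and the acting learner (behavioural criterion).
#'
#' @inheritParams nn_trials_to_threshold
#' @param alpha,tau RL parameters.
#' @return List with `trials` (integer or `NA`) and `learned`.
#' @export
rl_trials_to_criterion <- function(target_mapping, init_mapping,
                                   alpha = 0.3, tau = 0.15,
                                   max_trials = 2000L,
                                   schedule = c("blocks", "iid")) {
  schedule <- match.arg(schedule)
  agent <- agent_rl(init_mapping, alpha = alpha, tau = tau)
  ses <- run_session(agent, target_mapping, max_trials = max_trials,
                     schedule = schedule)
  list(trials = ses$trials_to_criterion, learned = ses$learned)
}
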
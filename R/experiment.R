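# Two-group serial-learning protocol and the facilitation analyses.
#
# Every subject (or simulated run) learns six mappings in a group-specific
# order; facilitation is quantified per subject as trial-count ratios, with
# the random mapping as normalising factor (ratio < 1 means faster learning
# of the structured mapping) and second/first ratios within the shift and
# mirror structures.

#' Mapping order of the two protocol groups
#'
#' Group 1: identity, right shift, left shift, horizontal mirror, vertical
#' mirror, random. Group 2 reverses the within-structure order: identity,
#' left shift, right shift, vertical mirror, horizontal mirror, random.
#'
#' @param group 1 or 2.
#' @return Character vector of six mapping labels.
#' @export
protocol_order <- function(group) {
  stopifnot(group %in% c(1L, 2L))
  if (group == 1)
    c("identity", "right_shift", "left_shift",
      "horizontal_mirror", "vertical_mirror", "random")
  else
    c("identity", "left_shift", "right_shift",
      "vertical_mirror", "horizontal_mirror", "random")
}

# Per-stage prior preset for the hierarchical model: when the current
# mapping's structure has already been experienced at an earlier stage, the
# prior weight of that structure is elevated (factor 10 by default).
sl_stage_prior <- function(stage_label, seen_labels, elevation = 10) {
  w <- c(S1_identity = 1, S2_shift = 1, S3_mirror = 1, S4_random = 0.001)
  cur <- structure_of(stage_label)
  seen <- vapply(seen_labels, structure_of, character(1))
  if (cur %in% seen && cur != "S4_random")
    w[cur] <- w[cur] * elevation
  structure_prior(w)
}

# Per-stage preset for the flat model: structured mappings keep their
# 1000:1 advantage over random permutations; when the current structure was
# experienced before, the prior of the *previously learned* mapping (not the
# current target) is elevated - e.g. mostly on the right shift when learning
# the left shift. The flat model has no structure variable, so this is the
# only way prior knowledge can be injected.
flat_stage_prior <- function(stage_label, seen_labels, elevation = 10,
                             structured = 1000, random = 1) {
  w <- setNames(rep(structured, 5L), STRUCTURED_LABELS)
  cur <- structure_of(stage_label)
  for (m in seen_labels) {
    if (m != stage_label && structure_of(m) == cur && cur != "S4_random")
      w[m] <- w[m] * elevation
  }
  flat_prior(structured = w, random = random)
}

#' Run the six-mapping protocol repeatedly for one model
#'
#' Each run learns the six mappings of the group's order. Bayesian agents
#' start each stage with fresh evidence and the stage's manual prior preset
#' (the prior of a previously experienced structure, or previously learned
#' mapping for the flat model, is elevated by `elevation`). The associative
#' baselines carry knowledge as initialization: stage k starts from the
#' mapping learned at stage k-1 (stage 1 starts from the identity).
#'
#' @param model `"nn"`, `"rl"`, `"flatbayes"` or `"slbayes"`; alternatively a
#'   factory `function(mapping, seen_labels)` returning an agent for
#'   [run_session()] (e.g. `function(m, seen) agent_oracle(m)`).
#' @param group Protocol group, 1 or 2.
#' @param n_runs Number of independent runs.
#' @param seed Optional integer seed.
#' @param params Optional list overriding model parameters: `eta`, `epsilon`
#'   (nn), `alpha`, `tau` (rl), `lapse`, `forget` (Bayes), `elevation`,
#'   `max_trials`, `schedule`.
#' @return An `sl_cohort_table`: matrix of trials-to-criterion (runs x six
#'   mapping labels, `NA` = censored), with attributes `group` (per row) and
#'   `model`.
#' @export
run_protocol <- function(model = c("nn", "rl", "flatbayes", "slbayes"),
                         group = 1L, n_runs = 100L, seed = NULL,
                         params = list()) {
  factory <- NULL
  if (is.function(model)) {
    factory <- model
    model <- "custom"
  } else {
    model <- match.arg(model)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- modifyList(list(eta = 0.1, epsilon = 0.01, alpha = 0.3, tau = 0.15,
                       lapse = 0, forget = 0, elevation = 10,
                       max_trials = 2000L, schedule = "blocks"), params)
  order <- protocol_order(group)
  tab <- matrix(NA_integer_, n_runs, 6L,
                dimnames = list(NULL, MAPPING_LABELS))
  for (run in seq_len(n_runs)) {
    random_map <- sample_random_mapping()
    maps <- lapply(order, function(l)
      if (l == "random") random_map else build_mapping(l))
    for (k in seq_along(order)) {
      lab <- order[k]
      seen <- order[seq_len(k - 1L)]
      count <- switch(model,
        custom = {
          run_session(factory(maps[[k]], seen), max_trials = p$max_trials,
                      mapping = maps[[k]],
                      schedule = p$schedule)$trials_to_criterion
        },
        nn = {
          init <- if (k == 1L) build_mapping("identity") else maps[[k - 1L]]
          nn_trials_to_threshold(maps[[k]], init, eta = p$eta,
                                 epsilon = p$epsilon,
                                 max_trials = p$max_trials,
                                 schedule = p$schedule)$trials
        },
        rl = {
          init <- if (k == 1L) build_mapping("identity") else maps[[k - 1L]]
          rl_trials_to_criterion(maps[[k]], init, alpha = p$alpha,
                                 tau = p$tau, max_trials = p$max_trials,
                                 schedule = p$schedule)$trials
        },
        flatbayes = {
          ag <- agent_flat_bayes(flat_stage_prior(lab, seen, p$elevation),
                                 lapse = p$lapse, forget = p$forget)
          run_session(ag, maps[[k]], max_trials = p$max_trials,
                      schedule = p$schedule)$trials_to_criterion
        },
        slbayes = {
          ag <- agent_sl_bayes(sl_stage_prior(lab, seen, p$elevation),
                               lapse = p$lapse, forget = p$forget)
          run_session(ag, maps[[k]], max_trials = p$max_trials,
                      schedule = p$schedule)$trials_to_criterion
        })
      tab[run, lab] <- count
    }
  }
  structure(tab, group = rep(as.integer(group), n_runs), model = model,
            class = c("sl_cohort_table", "matrix"))
}

#' @export
print.sl_cohort_table <- function(x, ...) {
  cat("<sl_cohort_table> ", nrow(x), " runs",
      if (!is.null(attr(x, "model"))) paste0(", model = ", attr(x, "model")),
      "\n", sep = "")
  cat("median trials-to-criterion per mapping:\n")
  print(apply(unclass(x), 2, median, na.rm = TRUE))
  ncens <- sum(is.na(x))
  if (ncens) cat(ncens, "censored entries\n")
  invisible(x)
}

#' @export
summary.sl_cohort_table <- function(object, ...) {
  m <- unclass(object)
  data.frame(mapping = colnames(m),
             median = apply(m, 2, median, na.rm = TRUE),
             q25 = apply(m, 2, quantile, 0.25, na.rm = TRUE),
             q75 = apply(m, 2, quantile, 0.75, na.rm = TRUE),
             censored = colSums(is.na(m)),
             row.names = NULL)
}

#' Per-run facilitation ratios
#'
#' For each run/subject: first structured mapping over random (separately for
#' the first shift and the first mirror), second over first shift, and second
#' over first mirror, with "first"/"second" resolved by the row's group
#' order. Facilitation corresponds to ratios below unity.
#'
#' @param table An `sl_cohort_table` (or matrix with the six mapping-label
#'   columns and a `group` attribute).
#' @return Data frame with columns `group`, `first_shift_over_random`,
#'   `first_mirror_over_random`, `shift2_over_shift1`, `mirror2_over_mirror1`.
#' @export
facilitation_ratios <- function(table) {
  m <- unclass(table)
  grp <- attr(table, "group")
  if (is.null(grp)) stop("table lacks a 'group' attribute", call. = FALSE)
  used <- m[, c("right_shift", "left_shift", "horizontal_mirror",
                "vertical_mirror", "random")]
  if (anyNA(used) || any(used == 0, na.rm = TRUE))
    stop("censored or zero trial counts in slots used for ratios",
         call. = FALSE)
  shift1 <- ifelse(grp == 1, m[, "right_shift"], m[, "left_shift"])
  shift2 <- ifelse(grp == 1, m[, "left_shift"], m[, "right_shift"])
  mirror1 <- ifelse(grp == 1, m[, "horizontal_mirror"], m[, "vertical_mirror"])
  mirror2 <- ifelse(grp == 1, m[, "vertical_mirror"], m[, "horizontal_mirror"])
  data.frame(group = grp,
             first_shift_over_random = shift1 / m[, "random"],
             first_mirror_over_random = mirror1 / m[, "random"],
             shift2_over_shift1 = shift2 / shift1,
             mirror2_over_mirror1 = mirror2 / mirror1)
}

#' Paired Wilcoxon signed-rank test against a null location
#'
#' Two-sided by default; exact null distribution for small samples without
#' ties, normal approximation otherwise (base R's convention, with zero
#' differences discarded).
#'
#' @param values Numeric sample (e.g. per-subject ratios).
#' @param null Null location (default 1, the no-facilitation value).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return The p-value.
#' @export
wilcoxon_signed_rank <- function(values, null = 1,
                                 alternative = "two.sided") {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values", call. = FALSE)
  if (all(values == null)) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(values, mu = null, alternative = alternative)$p.value)
}

#' Wilcoxon rank-sum test between two samples
#'
#' Two-sided by default; exact for small samples without ties, mid-ranks and
#' normal approximation with ties.
#'
#' @param sample_a,sample_b Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return The p-value.
#' @export
wilcoxon_ranksum <- function(sample_a, sample_b,
                             alternative = "two.sided") {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = alternative)$p.value)
}

#' One-sided sign test for a median below a null value
#'
#' Counts values strictly below vs strictly above `null` (ties discarded) and
#' tests whether "below" predominates. Used to assess the presence/absence of
#' facilitation in ratio medians.
#'
#' @param values Numeric sample.
#' @param null Null location (default 1).
#' @return The one-sided p-value.
#' @export
sign_test_below <- function(values, null = 1) {
  nb <- sum(values < null)
  na_ <- sum(values > null)
  if (nb + na_ == 0L) return(1)
  stats::binom.test(nb, nb + na_, p = 0.5,
                    alternative = "greater")$p.value
}

#' Facilitation significance tests on a cohort
#'
#' Signed-rank p-values (vs unity) for the pooled structured/random ratios
#' (first shift and first mirror pooled across subjects) and for the
#' second/first shift and mirror ratios.
#'
#' @param ratios Output of [facilitation_ratios()].
#' @param alternative Passed to [wilcoxon_signed_rank()].
#' @return Named list of p-values: `structured_vs_random`, `shift2_vs_shift1`,
#'   `mirror2_vs_mirror1`.
#' @export
facilitation_tests <- function(ratios, alternative = "two.sided") {
  list(
    structured_vs_random = wilcoxon_signed_rank(
      c(ratios$first_shift_over_random, ratios$first_mirror_over_random),
      null = 1, alternative = alternative),
    shift2_vs_shift1 = wilcoxon_signed_rank(
      ratios$shift2_over_shift1, null = 1, alternative = alternative),
    mirror2_vs_mirror1 = wilcoxon_signed_rank(
      ratios$mirror2_over_mirror1, null = 1, alternative = alternative)
  )
}
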
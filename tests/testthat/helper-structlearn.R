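# Shared test utilities.

# Build an sl_session from explicit trial triples (stimulus, action) against
# a mapping; correctness is derived from the mapping.
make_session <- function(stimuli, actions, mapping,
                         subject_id = "t", group = 1L) {
  correct <- actions == mapping$image[stimuli]
  trials <- data.frame(index = seq_along(stimuli), stimulus = stimuli,
                       action = actions, correct = correct)
  learned <- structlearn::is_learned(trials)
  structure(list(subject_id = subject_id, group = group, mapping = mapping,
                 trials = trials, learned = learned,
                 trials_to_criterion = if (learned) length(stimuli)
                                       else NA_integer_),
            class = "sl_session")
}

# Evidence object built from a list of (stimulus, action, correct) triples.
make_evidence <- function(triples) {
  ev <- evidence_new()
  for (tr in triples) ev <- update_evidence(ev, tr[[1]], tr[[2]], tr[[3]])
  ev
}

# Random consistent evidence: replay a few random probes against a random
# true permutation (feedback from the truth guarantees consistency).
random_evidence <- function(n_trials = 12L) {
  truth <- sample.int(9L)
  ev <- evidence_new()
  for (i in seq_len(n_trials)) {
    s <- sample.int(9L, 1L)
    a <- sample.int(9L, 1L)
    ok <- a == truth[s]
    # skip probes that would contradict what is already stored
    if (!ok && !is.na(ev$pos[s]) && ev$pos[s] == a) next
    ev <- update_evidence(ev, s, a, ok)
  }
  ev
}

# Dense-enumeration oracle over all 9! permutations (via e1071), independent
# of the permanent-based production path. Returns p(a | s) under a flat
# prior with per-structured-mapping weights.
dense_flat_action_oracle <- function(prior, ev, stimulus) {
  P <- e1071::permutations(9)
  ok <- rep(TRUE, nrow(P))
  for (s in 1:9) {
    if (!is.na(ev$pos[s])) ok <- ok & P[, s] == ev$pos[s]
    ok <- ok & !ev$neg[cbind(s, P[, s])]
  }
  w <- rep(prior$random, nrow(P))
  for (k in names(prior$structured)) {
    img <- build_mapping(k)$image
    hit <- colSums(t(P) == img) == 9L
    w[hit] <- prior$structured[[k]]
  }
  vapply(1:9, function(a) sum(w[ok & P[, stimulus] == a]), numeric(1)) /
    sum(w[ok])
}
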
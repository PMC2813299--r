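# Evidence about a mapping accrued from binary feedback. A correct trial
# pins the response for its stimulus (ruling out the other 8); an incorrect
# trial forbids one stimulus-response pair. The number of permutations
# compatible with the evidence is the permanent of the 9x9 0/1 allowance
# matrix, computed exactly by Ryser's algorithm.

#' Empty evidence
#' @return An object of class `sl_evidence`: `pos` (integer vector, `pos[s]`
#'   the known-correct response for stimulus `s` or `NA`) and `neg` (9x9
#'   logical matrix of known-incorrect pairs).
#' @export
evidence_new <- function() {
  structure(list(pos = rep(NA_integer_, 9L),
                 neg = matrix(FALSE, 9L, 9L)),
            class = "sl_evidence")
}

#' Update evidence with one trial's feedback
#'
#' Idempotent for repeated observations. Raises an error on contradiction
#' (feedback that conflicts with a stored constraint), which cannot occur
#' when replaying a stream against its true mapping.
#'
#' @param ev An [evidence_new()] object.
#' @param stimulus,action Trial indices in 1..9.
#' @param correct Logical feedback.
#' @return The updated `sl_evidence`.
#' @export
update_evidence <- function(ev, stimulus, action, correct) {
  s <- as.integer(stimulus); a <- as.integer(action)
  stopifnot(s >= 1L, s <= 9L, a >= 1L, a <= 9L)
  if (correct) {
    if (ev$neg[s, a] || (!is.na(ev$pos[s]) && ev$pos[s] != a))
      stop("contradictory evidence: (", s, ",", a, ") observed correct",
           call. = FALSE)
    ev$pos[s] <- a
  } else {
    if (!is.na(ev$pos[s]) && ev$pos[s] == a)
      stop("contradictory evidence: (", s, ",", a, ") observed incorrect",
           call. = FALSE)
    ev$neg[s, a] <- TRUE
  }
  ev
}

# 0/1 allowance matrix: entry (s, a) = 1 iff stimulus s may map to action a.
compatibility_matrix <- function(ev) {
  A <- matrix(1, 9L, 9L)
  A[ev$neg] <- 0
  pinned <- which(!is.na(ev$pos))
  for (s in pinned) {
    A[s, ] <- 0
    A[s, ev$pos[s]] <- 1
  }
  A
}

#' Count permutations compatible with evidence
#'
#' Exact count of the bijective mappings satisfying all stored constraints,
#' via the permanent of the compatibility matrix (Ryser's formula,
#' O(2^9 * 9)). Empty evidence gives 9! = 362,880.
#'
#' @param ev An `sl_evidence` object.
#' @param brute If `TRUE`, count by explicit enumeration of all 9!
#'   permutations instead (the independent oracle used in tests).
#' @return Non-negative count.
#' @export
count_compatible <- function(ev, brute = FALSE) {
  A <- compatibility_matrix(ev)
  if (brute) .count_compatible_brute(A) else round(.perm_ryser(A))
}

# Per-action compatible counts for one stimulus: n[a] = number of compatible
# permutations with image[stimulus] = a.
compatible_action_counts <- function(ev, stimulus) {
  A <- compatibility_matrix(ev)
  .perm_cofactors(A, as.integer(stimulus))
}

# Is a fixed permutation image compatible with the evidence?
image_compatible <- function(image, ev) {
  pinned <- which(!is.na(ev$pos))
  if (any(image[pinned] != ev$pos[pinned])) return(FALSE)
  !any(ev$neg[cbind(1:9, image)])
}
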
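# Stimuli and responses live on a 3x3 grid, indexed row-major:
#   1 2 3
#   4 5 6
#   7 8 9
# A mapping is a bijection image: stimulus i -> response image[i].

MAPPING_LABELS <- c("identity", "right_shift", "left_shift",
                    "horizontal_mirror", "vertical_mirror", "random")
STRUCTURED_LABELS <- MAPPING_LABELS[1:5]

#' Construct a mapping object
#'
#' A mapping assigns to each of the nine grid stimuli exactly one of the nine
#' grid responses (a permutation of 1..9, row-major indexing with 1 at the
#' top-left).
#'
#' @param image Integer vector of length 9; `image[i]` is the response for
#'   stimulus `i`. Must be a permutation of 1..9.
#' @param label One of `"identity"`, `"right_shift"`, `"left_shift"`,
#'   `"horizontal_mirror"`, `"vertical_mirror"`, `"random"`.
#' @return An object of class `sl_mapping` with fields `image` and `label`.
#' @export
sl_mapping <- function(image, label) {
  image <- as.integer(image)
  if (length(image) != 9L || !identical(sort(image), 1:9))
    stop("`image` must be a permutation of 1..9", call. = FALSE)
  label <- match.arg(label, MAPPING_LABELS)
  if (label == "identity" && !identical(image, 1:9))
    stop("label 'identity' requires image 1..9", call. = FALSE)
  structure(list(image = image, label = label), class = "sl_mapping")
}

#' @export
print.sl_mapping <- function(x, ...) {
  cat("<sl_mapping> ", x$label, ": ", paste(x$image, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Canonical structured mappings on the 3x3 grid
#'
#' Builds one of the five structured mappings. Shifts are circular within each
#' row (the right-most response of a row wraps to the left-most). The
#' horizontal mirror reflects across the horizontal axis (top and bottom rows
#' swap); the vertical mirror reflects across the vertical axis (left and
#' right columns swap).
#'
#' @param kind One of `"identity"`, `"right_shift"`, `"left_shift"`,
#'   `"horizontal_mirror"`, `"vertical_mirror"`.
#' @return An [sl_mapping()] object.
#' @examples
#' build_mapping("right_shift")$image  # 2 3 1 5 6 4 8 9 7
#' @export
build_mapping <- function(kind) {
  if (length(kind) != 1L || !kind %in% STRUCTURED_LABELS)
    stop("unknown mapping kind: ", deparse(substitute(kind)),
         " (must be one of ", paste(STRUCTURED_LABELS, collapse = ", "), ")",
         call. = FALSE)
  row <- (0:8) %/% 3L   # 0-based row of each stimulus
  col <- (0:8) %% 3L    # 0-based column
  image <- switch(kind,
    identity          = 1:9,
    right_shift       = row * 3L + (col + 1L) %% 3L + 1L,
    left_shift        = row * 3L + (col + 2L) %% 3L + 1L,
    horizontal_mirror = (2L - row) * 3L + col + 1L,
    vertical_mirror   = row * 3L + (2L - col) + 1L)
  sl_mapping(image, kind)
}

#' Sample a random (unstructured) mapping
#'
#' Draws a permutation uniformly from the permutations not in `excluded`;
#' by default the five structured mappings are excluded, so the result carries
#' no shift, mirror or identity rule. Uses the current RNG state; call
#' `set.seed()` for reproducibility.
#'
#' @param excluded List of length-9 integer images to exclude (default: the
#'   five structured mappings).
#' @param n_items Grid size for testing analogues (default 9).
#' @return An [sl_mapping()] with label `"random"` (for `n_items = 9`), or a
#'   bare permutation for other sizes.
#' @export
sample_random_mapping <- function(excluded = lapply(STRUCTURED_LABELS,
                                                    function(k) build_mapping(k)$image),
                                  n_items = 9L) {
  n_items <- as.integer(n_items)
  if (length(excluded) >= factorial(n_items))
    stop("excluded set covers all permutations", call. = FALSE)
  repeat {
    img <- sample.int(n_items)
    hit <- any(vapply(excluded, function(e) identical(as.integer(e), img),
                      logical(1)))
    if (!hit) break
  }
  if (n_items == 9L) sl_mapping(img, "random") else img
}

#' Structure classes over the mapping space
#'
#' The 9! mappings are partitioned into four structure classes: S1 (identity,
#' 1 member), S2 (shift, right and left circular shifts), S3 (mirror,
#' horizontal and vertical reflections), and S4 (the remaining 9! - 5
#' unstructured permutations).
#'
#' @return Named list with, per class, the member labels (`NULL` for S4),
#'   the member images, and the class size.
#' @export
structure_classes <- function() {
  mk <- function(labels) lapply(labels, function(k) build_mapping(k)$image)
  list(
    S1_identity = list(labels = "identity",
                       members = mk("identity"), size = 1),
    S2_shift    = list(labels = c("right_shift", "left_shift"),
                       members = mk(c("right_shift", "left_shift")), size = 2),
    S3_mirror   = list(labels = c("horizontal_mirror", "vertical_mirror"),
                       members = mk(c("horizontal_mirror", "vertical_mirror")),
                       size = 2),
    S4_random   = list(labels = NULL, members = NULL,
                       size = factorial(9) - 5)
  )
}

#' Structure class of a mapping label
#' @param label A mapping label.
#' @return One of `"S1_identity"`, `"S2_shift"`, `"S3_mirror"`, `"S4_random"`.
#' @export
structure_of <- function(label) {
  label <- match.arg(label, MAPPING_LABELS)
  switch(label,
         identity = "S1_identity",
         right_shift = , left_shift = "S2_shift",
         horizontal_mirror = , vertical_mirror = "S3_mirror",
         random = "S4_random")
}
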
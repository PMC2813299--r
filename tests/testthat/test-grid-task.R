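test_that("canonical structured mappings follow the grid geometry", {
  expect_identical(build_mapping("identity")$image, 1:9)
  expect_identical(build_mapping("right_shift")$image,
                   c(2L, 3L, 1L, 5L, 6L, 4L, 8L, 9L, 7L))
  expect_identical(build_mapping("left_shift")$image,
                   c(3L, 1L, 2L, 6L, 4L, 5L, 9L, 7L, 8L))
  expect_identical(build_mapping("horizontal_mirror")$image,
                   c(7L, 8L, 9L, 4L, 5L, 6L, 1L, 2L, 3L))
  expect_identical(build_mapping("vertical_mirror")$image,
                   c(3L, 2L, 1L, 6L, 5L, 4L, 9L, 8L, 7L))
  expect_error(build_mapping("diagonal"), "unknown mapping kind")
})

test_that("mapping compositions recover the identity", {
  rs <- build_mapping("right_shift")$image
  ls <- build_mapping("left_shift")$image
  expect_identical(rs[ls], 1:9)  # right after left
  expect_identical(ls[rs], 1:9)
  for (m in c("horizontal_mirror", "vertical_mirror")) {
    img <- build_mapping(m)$image
    expect_identical(img[img], 1:9)  # involution
  }
  imgs <- lapply(c("identity", "right_shift", "left_shift",
                   "horizontal_mirror", "vertical_mirror"),
                 function(k) build_mapping(k)$image)
  expect_equal(length(unique(imgs)), 5L)  # pairwise distinct
})

test_that("random mappings avoid the excluded set and are seed-reproducible", {
  structured <- lapply(c("identity", "right_shift", "left_shift",
                         "horizontal_mirror", "vertical_mirror"),
                       function(k) build_mapping(k)$image)
  set.seed(4)
  for (i in 1:25) {
    m <- sample_random_mapping()
    expect_false(any(vapply(structured, identical, logical(1),
                            y = m$image)))
    expect_identical(m$label, "random")
  }
  set.seed(99); a <- sample_random_mapping()
  set.seed(99); b <- sample_random_mapping()
  expect_identical(a$image, b$image)
  expect_error(
    sample_random_mapping(excluded = as.list(1:6), n_items = 3L),
    "covers all permutations")
})

test_that("random sampling is uniform (3-element analogue)", {
  set.seed(10)
  draws <- replicate(60000, paste(sample_random_mapping(excluded = list(),
                                                        n_items = 3L),
                                  collapse = ""))
  freq <- table(draws)
  expect_equal(length(freq), 6L)
  # binomial 3-sigma band around 1/6
  band <- 3 * sqrt((1 / 6) * (5 / 6) / 60000)
  expect_true(all(abs(freq / 60000 - 1 / 6) < band))
})

test_that("learning criterion demands an error-free suffix covering all stimuli", {
  full <- data.frame(stimulus = 1:9, correct = TRUE)
  expect_true(is_learned(full))
  # error at trial 5, suffix covers only 5 distinct stimuli
  t2 <- data.frame(stimulus = c(1:4, 5, 1:5),
                   correct = c(rep(TRUE, 4), FALSE, rep(TRUE, 5)))
  expect_false(is_learned(t2))
  # error-free suffix covering 8 distinct stimuli (one repeated)
  t3 <- data.frame(stimulus = c(1:8, 8), correct = TRUE)
  expect_false(is_learned(t3))
  # appending correct trials never un-learns
  for (extra in 1:5) {
    t4 <- rbind(full, data.frame(stimulus = sample.int(9, extra,
                                                       replace = TRUE),
                                 correct = TRUE))
    expect_true(is_learned(t4))
  }
})

test_that("sessions stop at first criterion satisfaction and store faithful flags", {
  map <- build_mapping("left_shift")
  set.seed(21)
  ses <- run_session(agent_oracle(map), map)
  expect_true(ses$learned)
  expect_identical(ses$trials_to_criterion, 9L)

  wrong <- list(act = function(s) (s %% 9L) + 1L,
                observe = function(s, a, correct) NULL)
  map_id <- build_mapping("identity")
  ses2 <- run_session(wrong, map_id, max_trials = 30L)
  expect_false(ses2$learned)
  expect_identical(nrow(ses2$trials), 30L)
  expect_true(is.na(ses2$trials_to_criterion))

  bad <- list(act = function(s) 10L, observe = function(s, a, correct) NULL)
  expect_error(run_session(bad, map_id), "outside 1..9")

  # stored correctness flags match recomputation, and the criterion holds
  # at the final trial only
  set.seed(8)
  ses3 <- run_session(agent_sl_bayes(), sample_random_mapping())
  expect_identical(ses3$trials$correct,
                   ses3$trials$action == ses3$mapping$image[ses3$trials$stimulus])
  expect_true(is_learned(ses3$trials))
  for (n in 9:(nrow(ses3$trials) - 1L))
    expect_false(is_learned(ses3$trials[1:n, ]))
})

test_that("block scheduling reaches criterion within 18 trials once errors stop", {
  # an agent that errs for its first k acts, then answers perfectly
  map <- build_mapping("horizontal_mirror")
  set.seed(31)
  for (k in c(0L, 5L, 13L)) {
    n_acted <- 0L
    agent <- list(
      act = function(s) {
        n_acted <<- n_acted + 1L
        if (n_acted <= k) ((map$image[s]) %% 9L) + 1L else map$image[s]
      },
      observe = function(s, a, correct) NULL)
    ses <- run_session(agent, map)
    expect_true(ses$learned)
    expect_lte(ses$trials_to_criterion, k + 18L)
  }
})
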
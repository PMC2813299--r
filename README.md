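# structlearn

Simulation and analysis of **structure learning in a sensorimotor
association task**: nine stimuli on a 3x3 grid, nine responses on a matching
grid, and a bijective stimulus–response mapping to be learned from binary
feedback. With 9! = 362,880 candidate mappings, six target mappings drawn
from four structure classes — identity (S1), circular row shifts (S2), axis
mirrors (S3), and an unstructured remainder (S4) — and two subject groups
that learn the within-structure instances in opposite orders, the design
asks whether learners acquire abstract structural invariants ("shift-ness")
that transfer to new instances, beyond the specific stimulus–response pairs.

The package is aimed at computational cognitive scientists who want to
simulate, analyse, or extend this serial-learning paradigm. It provides:

* **Task machinery** — canonical mappings, the trial loop with shuffled
  9-stimulus blocks, and the learning criterion (every stimulus answered
  correctly with no intervening mistake).
* **Four learning agents** — a linear network trained by the delta rule
  `W <- W + η (t − W x) xᵀ`; a Rescorla–Wagner learner
  `q <- q + α (r − q)` with softmax `p(a) ∝ exp(Q[s,a]/τ)`; a flat Bayesian
  learner over all 9! mappings with binary likelihood and 1000:1 structured
  priors; and a hierarchical Bayesian learner that also infers the structure
  class, `P(S|D) ∝ P(S) Σ_{h∈S} P(D|h) P(h|S)`. Bayesian action selection is
  Thompson sampling from the exact posterior, computed with matrix
  permanents (Ryser's algorithm in C++) — never dense enumeration.
* **Protocol and analyses** — the two-group six-mapping protocol,
  per-subject facilitation ratios (structured/random and second/first
  instance; values < 1 mean facilitation), Wilcoxon signed-rank and rank-sum
  tests, a forgetting-error taxonomy (`repeat_wrong` / `forgot_correct`)
  with structure-consistency scoring, trial-by-trial learning curves with
  Savitzky–Golay smoothing, and the error-free reanalysis.
* **A synthetic-subject generator** — hierarchical-Bayes agents degraded by
  per-trial lapses and forgetting (deletion of stored evidence constraints),
  standing in for a human cohort, with session logs in a documented CSV /
  JSON-lines schema.

## Worked example

Run the hierarchical (structure-learning) Bayes model through the group-1
protocol 100 times and test for facilitation:

```r
library(structlearn)
tab <- run_protocol("slbayes", group = 1, n_runs = 100, seed = 7)
summary(tab)
#>             mapping median   q25 q75 censored
#> 1          identity   15.0 10.00  17        0
#> 2       right_shift   16.0 12.00  17        0
#> 3        left_shift   13.0  9.00  16        0
#> 4 horizontal_mirror   15.0 10.75  17        0
#> 5   vertical_mirror   12.5  9.00  17        0
#> 6            random   45.0 38.00  53        0

r <- facilitation_ratios(tab)
round(sapply(r[, -1], median), 3)
#>  first_shift_over_random first_mirror_over_random       shift2_over_shift1
#>                    0.333                    0.315                    0.903
#>     mirror2_over_mirror1
#>                    0.938

signif(unlist(facilitation_tests(r)), 3)
#> structured_vs_random     shift2_vs_shift1   mirror2_vs_mirror1
#>             1.40e-34             1.67e-02             1.52e-02
```

Structured mappings are learned in roughly a third of the trials the random
mapping needs, and the second instance of a structure is learned faster than
the first (both second/first ratio medians below unity) — the signature of
structure transfer. Running the same protocol with `"nn"`, `"rl"` or
`"flatbayes"` shows that neither associative baseline produces either
effect, and the flat Bayesian model produces only the structured-vs-random
effect: the within-structure transfer requires the hierarchical structure
posterior.

A synthetic 20-subject cohort with lapses and forgetting, and its error
taxonomy:

```r
cohort <- generate_cohort(n_per_group = 10, lapse = 0.05, forget = 0.02,
                          seed = 42)
tab <- cohort_to_table(cohort)
errs <- do.call(rbind, lapply(cohort, classify_errors))
colSums(errs[, c("repeat_wrong", "forgot_correct")])
write_sessions(cohort, "cohort.csv")   # one row per trial, documented schema
```

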
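test_that("counts normalise to maximum-likelihood probabilities", {
  counts <- transition_counts(matrix(c(8, 2, 5, 0), 2, 2, byrow = TRUE,
                                     dimnames = rep(list(c("a", "b")), 2)))
  p <- counts_to_probabilities(counts, absorbing = "b")
  expect_equal(p["a", ], c(a = 0.8, b = 0.2))
  expect_equal(p["b", ], c(a = 1, b = 0))
  expect_equal(unname(rowSums(p)), c(1, 1))
  zero_row <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                     dimnames = rep(list(c("a", "b")), 2))
  expect_error(counts_to_probabilities(transition_counts(zero_row),
                                       absorbing = character()),
               "zero observed transitions")
  # an absorbing state with no observed exits becomes an identity row
  p2 <- counts_to_probabilities(transition_counts(
    matrix(c(3, 1, 0, 0), 2, 2, byrow = TRUE,
           dimnames = rep(list(c("alive", "death")), 2))))
  expect_equal(p2["death", "death"], 1)
})

test_that("model construction enforces stochastic rows and absorbing death", {
  expect_s3_class(markov_model(colnames(three_state_matrix()),
                               three_state_matrix()), "markov_model")
  bad <- three_state_matrix()
  bad[1, 1] <- 0.5
  expect_error(markov_model(colnames(bad), bad), "sum to 1")
  nonabs <- three_state_matrix()
  nonabs["death", ] <- c(0.1, 0, 0.9)
  expect_error(markov_model(colnames(nonabs), nonabs), "identity")
})

test_that("cohort traces match brute-force matrix powers to 1e-12", {
  tm <- three_state_matrix()
  model <- markov_model(colnames(tm), tm)
  initial <- c(1000, 0, 0)
  trace <- run_cohort(model, initial, 5)
  pow <- diag(3)
  for (t in 0:5) {
    expect_equal(unname(trace[t + 1, ]), unname(drop(initial %*% pow)),
                 tolerance = 1e-12)
    pow <- pow %*% tm
  }
  expect_error(run_cohort(model, c(1, 0), 3), "does not match")
})

test_that("identity and all-to-death chains behave at the boundaries", {
  states <- c("home", "care_home", "death")
  ident <- markov_model(states, diag(3), absorbing = states)
  trace <- run_cohort(ident, c(5, 3, 2), 4)
  expect_true(all(apply(trace, 1, function(r) all(r == c(5, 3, 2)))))
  all_death <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE,
                      dimnames = list(states, states))
  tr2 <- run_cohort(markov_model(states, all_death), c(7, 2, 0), 1)
  expect_equal(unname(tr2[2, ]), c(0, 0, 9))
})

test_that("cohort mass is conserved and death occupancy never decreases", {
  set.seed(42)
  for (rep in 1:5) {
    raw <- matrix(stats::runif(9), 3, 3)
    raw[3, ] <- c(0, 0, 1)
    tm <- raw / rowSums(raw)
    dimnames(tm) <- rep(list(c("home", "care_home", "death")), 2)
    model <- markov_model(colnames(tm), tm)
    trace <- run_cohort(model, c(100, 50, 0), 20)
    expect_true(all(abs(rowSums(trace) - 150) < 1e-9))
    expect_true(all(diff(trace[, "death"]) >= -1e-12))
  }
})

test_that("care-home person-years accrue at cycle start", {
  tm <- three_state_matrix()
  model <- markov_model(colnames(tm), tm)
  # constant occupancy: identity rows for the care states
  const <- run_cohort(markov_model(c("home", "care_home", "death"), diag(3),
                                   absorbing = c("home", "care_home",
                                                 "death")),
                      c(0, 100, 0), 3)
  expect_equal(care_home_person_years(const, "care_home"), 300)
  zero <- run_cohort(model, c(0, 0, 0), 4)
  expect_equal(care_home_person_years(zero, "care_home"), 0)
  # linear-decay occupancy equals the hand-summed series
  trace <- run_cohort(model, c(1000, 0, 0), 6)
  expect_equal(care_home_person_years(trace, "care_home"),
               sum(trace[1:6, "care_home"]))
  expect_error(care_home_person_years(trace, "hospice"), "unknown state")
})

test_that("long-term-care costs are simple products with guarded shares", {
  expect_equal(stroke_ltc_cost(0, 40000), 0)
  expect_equal(stroke_ltc_cost(1000, 40000), 40e6)
  expect_equal(vad_ltc_cost(1000, 0.17), 170)
  expect_equal(vad_ltc_cost(1000, 0), 0)
  expect_error(vad_ltc_cost(1000, 1.2), "\\[0, 1\\]")
})

test_that("the vascular-dementia share back-solves the fixture cells", {
  led <- load_fixtures()$ledger
  vad <- aggregate_costs(led, "ltc_vad", "England", "2021/22")$amount
  implied_total <- vad / 0.17
  expect_equal(vad_ltc_cost(implied_total, 0.17), vad, tolerance = 1e-12)
})

test_that("Dirichlet transition sampling is seeded, unbiased and consistent", {
  counts <- transition_counts(matrix(
    c(800, 120, 80, 50, 700, 250, 0, 0, 0), 3, 3, byrow = TRUE,
    dimnames = rep(list(c("home", "care_home", "death")), 2)))
  mle <- counts_to_probabilities(counts)
  set.seed(9); m1 <- sample_transition_matrix(counts)
  set.seed(9); m2 <- sample_transition_matrix(counts)
  expect_identical(m1, m2)
  expect_equal(unname(rowSums(m1)), rep(1, 3))
  # huge counts concentrate on the MLE
  set.seed(10)
  big <- sample_transition_matrix(transition_counts(
    matrix(as.integer(unclass(counts) * 1e3), 3, 3,
           dimnames = dimnames(counts))))
  expect_lt(max(abs(big[1:2, ] - mle[1:2, ])), 1e-2)
  # the mean over many draws approaches the MLE (Dirichlet mean)
  set.seed(11)
  draws <- replicate(10000, sample_transition_matrix(counts)["home", ])
  mc_se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - mle["home", ]) <= 3 * mc_se + 1e-12))
  zero_row <- transition_counts(matrix(
    c(0L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
    dimnames = rep(list(c("a", "b")), 2)))
  expect_error(sample_transition_matrix(zero_row, absorbing = "b"),
               "zero observed transitions")
})

test_that("stroke LTC PSA summaries are ordered and seed-stable", {
  counts <- gen_stroke_counts(2000, four_state_matrix(), seed = 3)
  p1 <- psa_stroke_ltc(counts, c(10000, 0, 0, 0), 8, 42000,
                       n_trials = 100, seed = 21)
  p2 <- psa_stroke_ltc(counts, c(10000, 0, 0, 0), 8, 42000,
                       n_trials = 100, seed = 21)
  expect_identical(p1$trials, p2$trials)
  expect_true(p1$minimum <= p1$q25 && p1$q25 <= p1$median &&
                p1$median <= p1$q75 && p1$q75 <= p1$maximum)
  expect_error(psa_stroke_ltc(counts, c(1, 0, 0, 0), 2, 1, n_trials = 1),
               "at least 2")
})
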
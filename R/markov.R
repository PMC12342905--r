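#' Transition counts from an audit database
#'
#' Observed post-stroke pathway transitions (SSNAP-like): a square matrix
#' of non-negative integer counts indexed by (from state, to state).
#'
#' @param counts Square numeric matrix with identical row/column names.
#' @return The validated matrix, class `transition_counts`.
#' @export
transition_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts matrix must be square")
  if (is.null(rownames(counts)) || is.null(colnames(counts)) ||
      !identical(rownames(counts), colnames(counts))) {
    stop("counts must carry identical row and column state names")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(counts, class = c("transition_counts", class(counts)))
}

#' Maximum-likelihood transition probabilities from counts
#'
#' Row-normalises observed transition counts. Absorbing states (death by
#' default) may have an all-zero observed row and become identity rows;
#' any other all-zero row is an error because its probabilities are
#' unidentified.
#'
#' @param counts A [transition_counts()] matrix.
#' @param absorbing Character vector of absorbing state names.
#' @return Row-stochastic matrix of the same dimension.
#' @export
counts_to_probabilities <- function(counts, absorbing = "death") {
  counts <- transition_counts(unclass(counts))
  p <- matrix(0, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  totals <- rowSums(counts)
  for (i in seq_len(nrow(counts))) {
    st <- rownames(counts)[i]
    if (totals[i] == 0) {
      if (!st %in% absorbing) {
        stop("state '", st, "' has zero observed transitions and is not absorbing")
      }
      p[i, i] <- 1
    } else {
      p[i, ] <- counts[i, ] / totals[i]
    }
  }
  p
}

#' Markov cohort model of the post-stroke care pathway
#'
#' Discrete-time state-transition model with annual cycles by default.
#' The state set must contain an absorbing death state whose row is the
#' identity; every row must sum to one.
#'
#' @param states Ordered character vector of state names.
#' @param transitions Row-stochastic matrix over `states`.
#' @param cycle_length Cycle length in years (default annual).
#' @param absorbing Name(s) of absorbing state(s); default `"death"`.
#' @return Object of class `markov_model`.
#' @export
markov_model <- function(states, transitions, cycle_length = 1,
                         absorbing = "death") {
  transitions <- as.matrix(transitions)
  stopifnot(length(states) == nrow(transitions),
            nrow(transitions) == ncol(transitions), cycle_length > 0)
  dimnames(transitions) <- list(states, states)
  if (any(transitions < 0) || any(transitions > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(transitions) - 1) > 1e-9)) {
    stop("every transition row must sum to 1 (tolerance 1e-9)")
  }
  for (st in intersect(absorbing, states)) {
    row <- transitions[st, ]
    if (abs(row[st] - 1) > 1e-9) {
      stop("absorbing state '", st, "' must have an identity transition row")
    }
  }
  structure(list(states = states, transitions = transitions,
                 cycle_length = cycle_length, absorbing = absorbing),
            class = "markov_model")
}

#' Propagate a cohort through the Markov model
#'
#' Returns the occupancy trace: row `t + 1` is the state occupancy after
#' `t` cycles (row 1 is the initial cohort). Total cohort mass is conserved
#' at every cycle.
#'
#' @param model A [markov_model()].
#' @param initial Non-negative occupancy vector over the model's states.
#' @param n_cycles Number of cycles to run.
#' @return Matrix `(n_cycles + 1) x states` of occupancies.
#' @export
run_cohort <- function(model, initial, n_cycles) {
  stopifnot(inherits(model, "markov_model"), n_cycles >= 0)
  if (length(initial) != length(model$states)) {
    stop("initial occupancy length (", length(initial),
         ") does not match state count (", length(model$states), ")")
  }
  if (any(initial < 0)) stop("occupancies must be non-negative")
  trace <- matrix(0, n_cycles + 1L, length(model$states),
                  dimnames = list(0:n_cycles, model$states))
  trace[1L, ] <- initial
  v <- initial
  for (t in seq_len(n_cycles)) {
    v <- as.numeric(v %*% model$transitions)
    trace[t + 1L, ] <- v
  }
  if (abs(sum(trace[n_cycles + 1L, ]) - sum(initial)) > 1e-9 * max(1, sum(initial))) {
    stop("cohort mass not conserved; transition matrix is not stochastic")
  }
  trace
}

#' Person-years spent in a state across the trace
#'
#' Costs accrue at cycle start with no half-cycle correction, so the final
#' row of the trace (occupancy after the last cycle) is not costed: with
#' `n` cycles the person-years are the sum of the first `n` rows times the
#' cycle length.
#'
#' @param trace Occupancy trace from [run_cohort()].
#' @param state State name to accumulate.
#' @param cycle_length Cycle length in years.
#' @return Person-years (numeric).
#' @export
care_home_person_years <- function(trace, state, cycle_length = 1) {
  if (!state %in% colnames(trace)) {
    stop("unknown state '", state, "'; trace has: ",
         paste(colnames(trace), collapse = ", "))
  }
  if (nrow(trace) < 2L) return(0)
  sum(trace[-nrow(trace), state]) * cycle_length
}

#' Long-term-care cost of the modelled stroke cohort
#'
#' @param person_years Care-home person-years from the cohort trace.
#' @param unit_cost Cost per person-year (numeric GBP or [money()]).
#' @return Same type as `unit_cost`.
#' @export
stroke_ltc_cost <- function(person_years, unit_cost) {
  stopifnot(person_years >= 0, amount_of(unit_cost) >= 0)
  rewrap(unit_cost, person_years * amount_of(unit_cost))
}

#' Vascular-dementia share of dementia social-care costs
#'
#' Long-term-care costs of vascular dementia are the share of all dementia
#' attributed to vascular dementia (17%) applied to the modelled total
#' dementia social-care cost.
#'
#' @param dementia_social_care_cost Total dementia social-care cost.
#' @param vad_share Proportion of dementia attributed to vascular dementia.
#' @return Same type as `dementia_social_care_cost`.
#' @export
vad_ltc_cost <- function(dementia_social_care_cost, vad_share = 0.17) {
  if (vad_share < 0 || vad_share > 1) stop("vad_share must lie in [0, 1]")
  rewrap(dementia_social_care_cost,
         amount_of(dementia_social_care_cost) * vad_share)
}

#' Sample a transition matrix from its posterior under the observed counts
#'
#' Each non-absorbing row is drawn from a Dirichlet distribution with the
#' row's observed counts as concentration parameters (the conjugate
#' posterior under a flat-zero prior for multinomial transitions) —
#' standard practice for probabilistic sensitivity analysis of Markov
#' cohort models. Absorbing rows stay identity.
#'
#' @param counts A [transition_counts()] matrix.
#' @param absorbing Absorbing state names (identity rows).
#' @return A row-stochastic matrix draw.
#' @export
sample_transition_matrix <- function(counts, absorbing = "death") {
  counts <- transition_counts(unclass(counts))
  p <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    st <- rownames(counts)[i]
    if (st %in% absorbing && sum(counts[i, ]) == 0) {
      p[i, i] <- 1
      next
    }
    if (sum(counts[i, ]) == 0) {
      stop("state '", st, "' has zero observed transitions and is not absorbing")
    }
    g <- stats::rgamma(ncol(counts), shape = counts[i, ], rate = 1)
    # rgamma(shape = 0) is exactly 0, so unobserved transitions stay 0
    p[i, ] <- g / sum(g)
  }
  p
}

#' Probabilistic sensitivity analysis of the stroke long-term-care cost
#'
#' Propagates transition-probability uncertainty (Dirichlet rows) through
#' the cohort model to the care-home cost.
#'
#' @param counts Observed [transition_counts()].
#' @param initial Initial cohort occupancy.
#' @param n_cycles Number of annual cycles.
#' @param unit_cost Cost per care-home person-year (numeric GBP).
#' @param care_state Name of the care-home state.
#' @param n_trials Number of Monte Carlo trials (default 1000).
#' @param seed Integer seed.
#' @param absorbing Absorbing state names.
#' @param cycle_length Cycle length in years.
#' @return A [psa_result()].
#' @export
psa_stroke_ltc <- function(counts, initial, n_cycles, unit_cost,
                           care_state = "care_home", n_trials = 1000,
                           seed = 1, absorbing = "death", cycle_length = 1) {
  if (n_trials < 2) stop("n_trials must be at least 2")
  states <- rownames(counts)
  set.seed(seed)
  trials <- vapply(seq_len(n_trials), function(i) {
    tm <- sample_transition_matrix(counts, absorbing = absorbing)
    model <- markov_model(states, tm, cycle_length = cycle_length,
                          absorbing = absorbing)
    trace <- run_cohort(model, initial, n_cycles)
    stroke_ltc_cost(care_home_person_years(trace, care_state, cycle_length),
                    unit_cost)
  }, numeric(1))
  psa_result(trials, seed = seed)
}
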
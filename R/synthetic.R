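#' Configuration for the synthetic survey generator
#'
#' The generator emulates the structure of European ageing-survey
#' microdata: respondents over 50 with demographics, a cardiovascular
#' disease flag, binary disability/help outcomes following logistic
#' models, ordered carer contact-frequency outcomes following
#' proportional-odds models per carer slot, and hours of care per carer.
#' Default coefficients put the CVD marginal effects near the magnitudes
#' estimated on the real survey (severe-disability AME around 0.145), and
#' covariate effects are weak, consistent with the low pseudo-R squared
#' of the published fits.
#'
#' @param n Number of respondents.
#' @param cvd_prevalence Probability of the CVD flag (drawn independently
#'   of the other covariates).
#' @param disability,help_in,help_out Named coefficient vectors
#'   (`intercept`, `cvd`, `age` (centred at 70), `gender`,
#'   `comorbidities`, and for help models `household`).
#' @param carer_beta Named latent-scale coefficients shared by the carer
#'   frequency models (`cvd`, `age`, `gender`, `comorbidities`,
#'   `household`).
#' @param carer_cutpoints List of three increasing cutpoint vectors
#'   (length 4: none|annually|monthly|weekly|daily).
#' @param hours_shape,hours_scale Gamma parameters for hours per contact.
#' @param seed Default seed for [gen_survey()].
#' @return List of class `survey_config`.
#' @export
survey_config <- function(n = 20000,
                          cvd_prevalence = 0.5,
                          disability = c(intercept = -2.0, cvd = 0.85,
                                         age = 0.015, gender = 0.10,
                                         comorbidities = 0.20),
                          help_in = c(intercept = -2.4, cvd = 0.75,
                                      age = 0.020, gender = 0.05,
                                      comorbidities = 0.15,
                                      household = 0.15),
                          help_out = c(intercept = -1.6, cvd = 0.90,
                                       age = 0.025, gender = 0.05,
                                       comorbidities = 0.15,
                                       household = -0.10),
                          carer_beta = c(cvd = 1.30, age = 0.020,
                                         gender = 0.05,
                                         comorbidities = 0.15,
                                         household = -0.05),
                          carer_cutpoints = list(
                            c(1.1, 1.6, 2.1, 3.0),
                            c(1.9, 2.4, 2.9, 3.8),
                            c(2.7, 3.2, 3.7, 4.6)),
                          hours_shape = 2, hours_scale = 2,
                          seed = 20260921) {
  stopifnot(n > 0, cvd_prevalence >= 0, cvd_prevalence <= 1,
            length(carer_cutpoints) == 3L,
            all(vapply(carer_cutpoints,
                       function(z) all(diff(z) > 0), logical(1))))
  structure(list(n = n, cvd_prevalence = cvd_prevalence,
                 disability = disability, help_in = help_in,
                 help_out = help_out, carer_beta = carer_beta,
                 carer_cutpoints = carer_cutpoints,
                 hours_shape = hours_shape, hours_scale = hours_scale,
                 seed = seed),
            class = "survey_config")
}

binary_linpred <- function(coefs, cvd, age, gender, comorb, household = NULL) {
  eta <- coefs[["intercept"]] + coefs[["cvd"]] * cvd +
    coefs[["age"]] * (age - 70) + coefs[["gender"]] * gender +
    coefs[["comorbidities"]] * comorb
  if (!is.null(household) && "household" %in% names(coefs)) {
    eta <- eta + coefs[["household"]] * household
  }
  eta
}

#' Generate synthetic survey microdata with its ground truth
#'
#' Draws respondents (ages uniform on 51-90) and their outcomes from the
#' configured logistic / ordered-logistic models, enforcing the carer-slot
#' structure (no second carer without a first). The return value carries
#' both the data and the analytic average marginal effects implied by the
#' generating coefficients, computed over the generated covariates — the
#' exact estimand the regression fitters target, used as the oracle in
#' parameter-recovery tests.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return List with elements `data` (data frame, one row per respondent,
#'   carer slots flattened) and `truth` (true AMEs and coefficients).
#' @export
gen_survey <- function(config = survey_config(), seed = config$seed) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(seed)
  n <- config$n
  age <- stats::runif(n, 51, 90)
  gender <- stats::rbinom(n, 1, 0.55)
  comorb <- stats::rpois(n, 1.5)
  household <- 1L + stats::rpois(n, 0.8)
  cvd <- stats::rbinom(n, 1, config$cvd_prevalence)

  draw_binary <- function(coefs, use_household) {
    hh <- if (use_household) household else NULL
    stats::rbinom(n, 1, stats::plogis(
      binary_linpred(coefs, cvd, age, gender, comorb, hh)))
  }
  true_binary_ame <- function(coefs, use_household) {
    hh <- if (use_household) household else NULL
    mean(stats::plogis(binary_linpred(coefs, 1, age, gender, comorb, hh)) -
         stats::plogis(binary_linpred(coefs, 0, age, gender, comorb, hh)))
  }

  severely_disabled <- draw_binary(config$disability, FALSE)
  in_help <- draw_binary(config$help_in, TRUE)
  out_help <- draw_binary(config$help_out, TRUE)

  carer_eta <- function(cvd_val) {
    b <- config$carer_beta
    b[["cvd"]] * cvd_val + b[["age"]] * (age - 70) +
      b[["gender"]] * gender + b[["comorbidities"]] * comorb +
      b[["household"]] * household
  }
  levels_ <- carer_freq_levels()
  draw_ordered <- function(zeta) {
    probs <- ordered_category_probs(carer_eta(cvd), zeta)
    idx <- vapply(seq_len(n), function(i) {
      sample.int(5L, 1L, prob = probs[i, ])
    }, integer(1))
    factor(levels_[idx], levels = levels_, ordered = TRUE)
  }
  true_ordered_ame <- function(zeta) {
    p1 <- ordered_category_probs(carer_eta(1), zeta)
    p0 <- ordered_category_probs(carer_eta(0), zeta)
    stats::setNames(colMeans(p1 - p0), levels_)
  }

  freq <- lapply(config$carer_cutpoints, draw_ordered)
  # carer slots are ordered 1..3 with no gaps
  freq[[2]][freq[[1]] == "none"] <- "none"
  freq[[3]][freq[[2]] == "none"] <- "none"

  relationships <- c("spouse", "child", "sibling", "friend", "neighbour",
                     "parent")
  data <- data.frame(age = age, gender = gender, n_comorbidities = comorb,
                     household_size = household, has_cvd = cvd,
                     severely_disabled = severely_disabled,
                     in_household_help = in_help,
                     out_household_help = out_help)
  for (k in 1:3) {
    present <- freq[[k]] != "none"
    hours <- ifelse(present,
                    stats::rgamma(n, config$hours_shape,
                                  scale = config$hours_scale), NA_real_)
    data[[paste0("carer", k, "_freq")]] <- freq[[k]]
    data[[paste0("carer", k, "_hours")]] <- hours
    data[[paste0("carer", k, "_relationship")]] <-
      ifelse(present, sample(relationships, n, replace = TRUE), NA_character_)
    data[[paste0("carer", k, "_employed")]] <-
      ifelse(present, stats::rbinom(n, 1, 0.6), NA_integer_)
  }
  truth <- list(
    ame_disability = true_binary_ame(config$disability, FALSE),
    ame_help_in = true_binary_ame(config$help_in, TRUE),
    ame_help_out = true_binary_ame(config$help_out, TRUE),
    ame_carer_freq = lapply(config$carer_cutpoints, true_ordered_ame),
    coefficients = config[c("disability", "help_in", "help_out",
                            "carer_beta", "carer_cutpoints")],
    cvd_prevalence = config$cvd_prevalence)
  list(data = data, truth = truth)
}

#' Generate synthetic post-stroke transition counts
#'
#' Multinomial draws per from-state around a known transition matrix,
#' emulating audit-derived pathway counts. Large counts make
#' [counts_to_probabilities()] recover the true matrix.
#'
#' @param n_patients Patients observed per non-absorbing from-state
#'   (scalar or per-state vector).
#' @param true_matrix Row-stochastic matrix with state names.
#' @param seed Integer seed.
#' @param absorbing Absorbing state names (no transitions drawn).
#' @return A [transition_counts()] matrix.
#' @export
gen_stroke_counts <- function(n_patients, true_matrix, seed = 1,
                              absorbing = "death") {
  true_matrix <- as.matrix(true_matrix)
  if (any(abs(rowSums(true_matrix) - 1) > 1e-9)) {
    stop("true_matrix rows must sum to 1")
  }
  states <- rownames(true_matrix)
  if (is.null(states)) stop("true_matrix must carry state names")
  n_patients <- rep(n_patients, length.out = nrow(true_matrix))
  set.seed(seed)
  counts <- matrix(0L, nrow(true_matrix), ncol(true_matrix),
                   dimnames = dimnames(true_matrix))
  for (i in seq_len(nrow(true_matrix))) {
    if (states[i] %in% absorbing) next
    counts[i, ] <- as.integer(stats::rmultinom(1, n_patients[i],
                                               true_matrix[i, ]))
  }
  transition_counts(counts)
}

#' Generate synthetic cardiovascular deaths and a labour-market table
#'
#' Emulates national statistics: deaths by five-year age band and sex
#' rising with age, employment rates peaking mid-career, and hump-shaped
#' wages. Deterministic under seed. `config` entries `flat_employment`
#' and `flat_wage` produce a constant-profile table (used against the
#' closed-form annuity oracle); `min_death_age` suppresses younger
#' deaths; `death_scale` scales counts (0 gives a zero-death dataset).
#'
#' @param config Optional list of overrides.
#' @param seed Integer seed.
#' @return List with `deaths` (data frame: nation, fiscal_year, sex,
#'   age_low, age_high, deaths) and `labor` (a [labor_market_table()]).
#' @export
gen_labor_and_deaths <- function(config = list(), seed = 1) {
  set.seed(seed)
  sexes <- c("female", "male")
  lows <- seq(15, 85, by = 5)
  bands <- data.frame(age_low = lows, age_high = lows + 5)
  mk_labor <- function(sex) {
    mid <- (bands$age_low + bands$age_high) / 2
    keep <- bands$age_low < 65
    emp <- if (!is.null(config$flat_employment)) {
      rep(config$flat_employment, sum(keep))
    } else {
      # hump peaking around age 42, lower entry and pre-retirement rates
      pmin(0.9, pmax(0.2, 0.85 - ((mid[keep] - 42) / 38)^2)) *
        (if (sex == "male") 1 else 0.93)
    }
    wage <- if (!is.null(config$flat_wage)) {
      rep(config$flat_wage, sum(keep))
    } else {
      (22000 + 14000 * exp(-((mid[keep] - 47) / 16)^2)) *
        (if (sex == "male") 1.08 else 0.92)
    }
    data.frame(sex = sex, age_low = bands$age_low[keep],
               age_high = bands$age_high[keep],
               employment_rate = emp, annual_wage_gbp = wage)
  }
  labor <- labor_market_table(do.call(rbind, lapply(sexes, mk_labor)))

  death_scale <- config$death_scale %||% 1
  min_death_age <- config$min_death_age %||% 15
  mk_deaths <- function(sex) {
    mid <- (bands$age_low + bands$age_high) / 2
    lambda <- death_scale * 300 * exp(0.085 * (mid - 40)) *
      (if (sex == "male") 1.35 else 1)
    lambda[bands$age_low < min_death_age |
             bands$age_high <= min_death_age] <- 0
    data.frame(nation = "England", fiscal_year = "2021/22", sex = sex,
               age_low = bands$age_low, age_high = bands$age_high,
               deaths = if (death_scale == 0) 0 else stats::rpois(
                 nrow(bands), lambda))
  }
  deaths <- do.call(rbind, lapply(sexes, mk_deaths))
  deaths$deaths[deaths$age_low < min_death_age] <- 0
  list(deaths = deaths, labor = labor)
}

fixture_checksums <- c(
  "uk_cvd_costs_by_nation.csv" = "b598713449a66bc29c5050a501eaf341",
  "uk_cvd_costs_uk_totals.csv" = "e7644b63c702045a0013e27d8e298ab1",
  "informal_care_margins.csv" = "d3cafcf801b271b8f61cb160ce9db358",
  "apportionment_rules.yaml" = "d03e5b454f86bf12fe7453fcae1c1198")

#' Load the packaged published-cost fixtures
#'
#' Reads the packaged national cost tables (direct and indirect
#' components by nation and fiscal year, plus UK totals including the
#' 2015 comparator estimates), the informal-care margin table, and the
#' apportionment-rule registry. Files are checksummed at load so a
#' corrupted installation fails loudly rather than silently shifting
#' totals.
#'
#' @return List with `ledger` (a [cost_ledger()] of nation-level rows),
#'   `uk_totals` (data frame of printed UK totals incl. the 2015
#'   estimates under fiscal_year `"2015"`), `margins` (marginal-effect
#'   table) and `rules` (apportionment registry).
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "cvdcoi", mustWork = TRUE)
  for (f in names(fixture_checksums)) {
    path <- file.path(dir, f)
    sum <- unname(tools::md5sum(path))
    if (is.na(sum) || sum != fixture_checksums[[f]]) {
      stop("fixture checksum mismatch for ", f,
           "; packaged data are corrupted")
    }
  }
  list(
    ledger = read_cost_ledger(file.path(dir, "uk_cvd_costs_by_nation.csv")),
    uk_totals = utils::read.csv(file.path(dir, "uk_cvd_costs_uk_totals.csv")),
    margins = utils::read.csv(file.path(dir, "informal_care_margins.csv")),
    rules = load_apportionment_rules(file.path(dir,
                                               "apportionment_rules.yaml")))
}
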
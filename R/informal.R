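#' Carer contact-frequency categories and annualisation
#'
#' Survey respondents report how often each carer helps: daily, weekly,
#' monthly or annually. Costing annualises these as 365, 52, 12 and 1
#' contacts per year respectively (the survey gives only the category
#' names).
#'
#' @return Named numeric vector of contacts per year.
#' @export
annual_contacts <- function() {
  c(daily = 365, weekly = 52, monthly = 12, annually = 1)
}

carer_freq_levels <- function() c("none", "annually", "monthly", "weekly", "daily")

#' Marginal-effect estimate
#'
#' Point estimate, delta-method standard error and 95% normal confidence
#' interval for an average marginal effect (AME) of cardiovascular disease
#' on a modelled outcome probability.
#'
#' @param margin AME point estimate.
#' @param se Standard error (non-negative).
#' @param level Confidence level.
#' @param pseudo_r2 Optional McFadden pseudo-R squared of the fitted model.
#' @param n Optional sample size.
#' @return Object of class `marginal_effect`.
#' @export
marginal_effect <- function(margin, se, level = 0.95, pseudo_r2 = NA_real_,
                            n = NA_integer_) {
  stopifnot(is.finite(margin), is.finite(se), se >= 0)
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  structure(list(margin = margin, se = se,
                 ci_low = margin - z * se, ci_high = margin + z * se,
                 level = level, pseudo_r2 = pseudo_r2, n = n),
            class = "marginal_effect")
}

#' @export
print.marginal_effect <- function(x, ...) {
  cat(sprintf("AME %.4f (SE %.6f, %g%% CI %.4f to %.4f)\n",
              x$margin, x$se, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Normal confidence interval for a reported margin
#'
#' Reporting convention for margin tables: `margin +/- z * se` with
#' `z = 1.96` exactly at the 95% level, rounded half-up to 4 decimal
#' places.
#'
#' @param margin Point estimate.
#' @param se Standard error (non-negative).
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector `c(low, high)`, rounded to 4 dp.
#' @export
margin_ci <- function(margin, se, level = 0.95) {
  stopifnot(se >= 0)
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  round_half_up(c(margin - z * se, margin + z * se), 4)
}

mcfadden_r2 <- function(fit, null_formula, data) {
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::update(fit, null_formula)))
  1 - ll / ll0
}

#' Average marginal effect of CVD from a logistic regression
#'
#' Fits `outcome ~ has_cvd + covariates` by logistic regression and
#' computes the AME of the binary CVD flag as the mean over the sample of
#' the discrete change in predicted probability when the flag is switched
#' from 0 to 1 with all other covariates at their observed values. The
#' standard error is by the delta method; the 95% CI uses z = 1.96.
#'
#' @param data Data frame of survey respondents.
#' @param outcome Name of a binary outcome column (e.g.
#'   `"severely_disabled"`, `"in_household_help"`).
#' @param covariates Adjustment covariates; disability models control for
#'   age, gender and comorbidity count, help models additionally for
#'   household size.
#' @param exposure Name of the binary exposure column (default `has_cvd`).
#' @return A [marginal_effect()].
#' @export
fit_binary_margin <- function(data, outcome,
                              covariates = c("age", "gender",
                                             "n_comorbidities"),
                              exposure = "has_cvd") {
  stopifnot(all(c(outcome, covariates, exposure) %in% names(data)))
  y <- data[[outcome]]
  if (length(unique(y)) < 2L) {
    stop("outcome '", outcome, "' has a single observed class; ",
         "the logistic model is degenerate")
  }
  if (nrow(data) < 10L * (length(covariates) + 1L)) {
    stop("too few observations (", nrow(data), ") for ",
         length(covariates) + 1L, " predictors")
  }
  f <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- withCallingHandlers(
    stats::glm(f, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("(quasi-)complete separation detected in outcome '", outcome, "'",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || any(abs(stats::coef(fit)) > 20)) {
    stop("logistic fit for '", outcome, "' did not converge cleanly; ",
         "check for separation")
  }
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  d1 <- d0 <- data
  d1[[exposure]] <- 1
  d0[[exposure]] <- 0
  X1 <- stats::model.matrix(f, d1)
  X0 <- stats::model.matrix(f, d0)
  p1 <- stats::plogis(drop(X1 %*% beta))
  p0 <- stats::plogis(drop(X0 %*% beta))
  ame <- mean(p1 - p0)
  grad <- colMeans(p1 * (1 - p1) * X1 - p0 * (1 - p0) * X0)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  r2 <- mcfadden_r2(fit, stats::reformulate("1", response = outcome), data)
  marginal_effect(ame, se, pseudo_r2 = r2, n = nrow(data))
}

ordered_category_probs <- function(eta, zeta) {
  # P(Y = k) for ordered logit with cutpoints zeta; columns are categories
  K <- length(zeta) + 1L
  cum <- cbind(0, stats::plogis(outer(-eta, zeta, `+`)), 1)
  cum[, -1, drop = FALSE] - cum[, -(K + 1L), drop = FALSE]
}

#' Per-category average marginal effects from an ordered logistic regression
#'
#' Fits a proportional-odds model (via [MASS::polr()]) of an ordered
#' outcome — carer contact frequency including the "none" category — and
#' computes the AME of the CVD flag on every category probability. The
#' AMEs across the full category set sum to zero by construction.
#' Standard errors are by the delta method with a numerically
#' differentiated Jacobian over the stacked (coefficients, cutpoints)
#' parameter.
#'
#' @param data Data frame of survey respondents.
#' @param outcome Name of an ordered-factor column with at least two
#'   observed categories (levels ordered none < annually < monthly <
#'   weekly < daily).
#' @param covariates Adjustment covariates.
#' @param exposure Binary exposure column name.
#' @return Named list of [marginal_effect()], one per category, with
#'   attribute `"ame_sum"` (should be ~0).
#' @export
fit_ordered_margins <- function(data, outcome,
                                covariates = c("age", "gender",
                                               "n_comorbidities",
                                               "household_size"),
                                exposure = "has_cvd") {
  stopifnot(all(c(outcome, covariates, exposure) %in% names(data)))
  y <- data[[outcome]]
  if (!is.ordered(y)) {
    if (is.factor(y) || is.character(y)) {
      known <- carer_freq_levels()
      bad <- setdiff(unique(as.character(y)), known)
      if (length(bad)) stop("unknown frequency categories: ",
                            paste(bad, collapse = ", "))
      y <- factor(as.character(y), levels = known, ordered = TRUE)
      data[[outcome]] <- y
    } else {
      stop("outcome '", outcome, "' must be an ordered factor")
    }
  }
  data[[outcome]] <- droplevels(data[[outcome]])
  if (nlevels(data[[outcome]]) < 2L) {
    stop("outcome '", outcome, "' has a single observed category")
  }
  f <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- MASS::polr(f, data = data, method = "logistic", Hess = TRUE)
  beta <- stats::coef(fit)
  zeta <- fit$zeta
  V <- stats::vcov(fit)  # ordered: coefficients then cutpoints
  d1 <- d0 <- data
  d1[[exposure]] <- 1
  d0[[exposure]] <- 0
  X1 <- stats::model.matrix(f, d1)[, -1, drop = FALSE]  # polr has no intercept
  X0 <- stats::model.matrix(f, d0)[, -1, drop = FALSE]
  ames_at <- function(theta) {
    b <- theta[seq_along(beta)]
    z <- theta[-seq_along(beta)]
    p1 <- ordered_category_probs(drop(X1 %*% b), z)
    p0 <- ordered_category_probs(drop(X0 %*% b), z)
    colMeans(p1 - p0)
  }
  theta <- c(beta, zeta)
  ame <- ames_at(theta)
  # central-difference Jacobian of the K category AMEs wrt theta
  h <- pmax(abs(theta), 1) * 1e-6
  J <- vapply(seq_along(theta), function(j) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    (ames_at(tp) - ames_at(tm)) / (2 * h[j])
  }, numeric(length(ame)))
  ses <- sqrt(pmax(0, diag(J %*% V %*% t(J))))
  r2 <- 1 - as.numeric(stats::logLik(fit)) /
    as.numeric(stats::logLik(MASS::polr(
      stats::reformulate("1", response = outcome), data = data,
      method = "logistic")))
  out <- Map(function(m, s) marginal_effect(m, s, pseudo_r2 = r2,
                                            n = nrow(data)),
             ame, ses)
  names(out) <- levels(data[[outcome]])
  attr(out, "ame_sum") <- sum(ame)
  out
}

#' Wage policy for valuing informal care hours
#'
#' Carer time is valued at the national average hourly wage for employed
#' carers and the national minimum wage otherwise.
#'
#' @param minimum_wage,average_wage Hourly wages in GBP (> 0).
#' @param retirement_age Retirement age used for the over-65 rule.
#' @return Object of class `wage_policy`.
#' @export
wage_policy <- function(minimum_wage, average_wage, retirement_age = 65) {
  stopifnot(minimum_wage > 0, average_wage > 0)
  structure(list(minimum_wage = minimum_wage, average_wage = average_wage,
                 retirement_age = retirement_age), class = "wage_policy")
}

#' Hourly wage imputed to a carer
#'
#' Unemployed carers are valued at the minimum wage. For respondents over
#' the retirement age, siblings, spouses, friends and parents are assumed
#' to be over retirement age themselves and are likewise valued at the
#' minimum wage. All other carers get the average wage.
#'
#' @param relationship Carer's relationship to the respondent (free text;
#'   `"sibling"`, `"spouse"`, `"friend"`, `"parent"` trigger the
#'   retirement rule).
#' @param employed Logical; is the carer employed?
#' @param respondent_age Respondent's age in years.
#' @param policy A [wage_policy()].
#' @return Hourly wage in GBP.
#' @export
carer_wage <- function(relationship, employed, respondent_age, policy) {
  stopifnot(inherits(policy, "wage_policy"))
  retired_peer <- respondent_age > policy$retirement_age &&
    tolower(relationship) %in% c("sibling", "spouse", "friend", "parent")
  if (!employed || retired_peer) policy$minimum_wage else policy$average_wage
}

#' Inputs to the aggregate informal-care cost model
#'
#' The informal-care burden is a product of: the population over 50, the
#' survey prevalence of cardiovascular disease, the marginal effect of CVD
#' on severe disability, the marginal effect on requiring help, and — per
#' carer slot and contact frequency — the marginal effect on that carer
#' frequency, the annualised contact count, the hours per contact, and the
#' carer's hourly wage.
#'
#' @param population_over_50 Population count over 50 years of age.
#' @param cvd_prevalence Survey prevalence of CVD (heart attack,
#'   hypertension or stroke), a proportion.
#' @param disability_margin AME of CVD on severe disability (proportion).
#' @param help_margin AME of CVD on requiring help (in-household and
#'   out-of-household margins combined additively; must stay in \[0, 1\]).
#' @param freq_margins 3 x 4 matrix of AMEs: rows carers 1-3, columns
#'   `daily`, `weekly`, `monthly`, `annually`.
#' @param hours_per_contact Length-3 vector of hours per contact by carer.
#' @param wage_per_hour Length-3 vector of imputed hourly wages by carer.
#' @return Object of class `informal_care_inputs`.
#' @export
informal_care_inputs <- function(population_over_50, cvd_prevalence,
                                 disability_margin, help_margin,
                                 freq_margins, hours_per_contact,
                                 wage_per_hour) {
  freq_margins <- as.matrix(freq_margins)
  stopifnot(population_over_50 >= 0,
            nrow(freq_margins) == 3L, ncol(freq_margins) == 4L,
            length(hours_per_contact) == 3L, length(wage_per_hour) == 3L,
            all(hours_per_contact >= 0), all(wage_per_hour >= 0))
  colnames(freq_margins) <- c("daily", "weekly", "monthly", "annually")
  rownames(freq_margins) <- paste0("carer", 1:3)
  props <- c(cvd_prevalence = cvd_prevalence,
             disability_margin = disability_margin,
             help_margin = help_margin, freq = c(freq_margins))
  if (any(props < 0 | props > 1)) {
    stop("all prevalence and margin inputs must be proportions in [0, 1]; ",
         "offending: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  structure(list(population_over_50 = population_over_50,
                 cvd_prevalence = cvd_prevalence,
                 disability_margin = disability_margin,
                 help_margin = help_margin,
                 freq_margins = freq_margins,
                 hours_per_contact = as.numeric(hours_per_contact),
                 wage_per_hour = as.numeric(wage_per_hour)),
            class = "informal_care_inputs")
}

#' Aggregate informal-care cost
#'
#' Multiplicative composition of the inputs (see
#' [informal_care_inputs()]):
#' `population x prevalence x disability margin x help margin x`
#' `sum over carers and frequencies of (frequency margin x contacts/year x`
#' `hours x wage)`. The per-term composition is attached as attribute
#' `"terms"` so every factor is auditable.
#'
#' @param inputs An [informal_care_inputs()].
#' @return Annual cost in GBP (numeric) with a `"terms"` attribute.
#' @export
informal_care_cost <- function(inputs) {
  stopifnot(inherits(inputs, "informal_care_inputs"))
  contacts <- annual_contacts()[c("daily", "weekly", "monthly", "annually")]
  fm <- matrix(as.numeric(inputs$freq_margins), 3, 4,
               dimnames = list(paste0("carer", 1:3),
                               c("daily", "weekly", "monthly", "annually")))
  per_cf <- fm *
    matrix(contacts, 3, 4, byrow = TRUE) *
    inputs$hours_per_contact * inputs$wage_per_hour
  head_factor <- inputs$population_over_50 * inputs$cvd_prevalence *
    inputs$disability_margin * inputs$help_margin
  total <- head_factor * sum(per_cf)
  terms <- data.frame(
    carer = rep(rownames(per_cf), 4),
    frequency = rep(colnames(per_cf), each = 3),
    margin = c(fm),
    contacts_per_year = rep(contacts, each = 3),
    hours = rep(inputs$hours_per_contact, 4),
    wage = rep(inputs$wage_per_hour, 4),
    cost = head_factor * c(per_cf))
  structure(total, terms = terms)
}

#' Probabilistic sensitivity analysis of the informal-care cost
#'
#' Samples each margin independently from a normal distribution centred
#' on its point estimate with the supplied standard error, truncated to
#' \[0, 1\], and re-evaluates the aggregate cost per trial.
#'
#' @param inputs An [informal_care_inputs()] (base case).
#' @param ses List with `disability_se`, `help_se` (scalars) and
#'   `freq_ses` (3 x 4 matrix) of standard errors.
#' @param n_trials Number of Monte Carlo trials (default 1000).
#' @param seed Integer seed.
#' @return A [psa_result()].
#' @export
psa_informal <- function(inputs, ses, n_trials = 1000, seed = 1) {
  stopifnot(inherits(inputs, "informal_care_inputs"))
  if (n_trials < 2) stop("n_trials must be at least 2")
  stopifnot(all(c("disability_se", "help_se", "freq_ses") %in% names(ses)))
  freq_ses <- as.matrix(ses$freq_ses)
  stopifnot(nrow(freq_ses) == 3L, ncol(freq_ses) == 4L)
  rtrunc01 <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < 0 | x > 1)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(x < 0 | x > 1)
      tries <- tries + 1L
    }
    pmin(pmax(x, 0), 1)
  }
  set.seed(seed)
  dis <- rtrunc01(n_trials, inputs$disability_margin, ses$disability_se)
  hlp <- rtrunc01(n_trials, inputs$help_margin, ses$help_se)
  freq <- array(NA_real_, c(3, 4, n_trials))
  for (i in 1:3) for (j in 1:4) {
    freq[i, j, ] <- rtrunc01(n_trials, inputs$freq_margins[i, j],
                             freq_ses[i, j])
  }
  trials <- vapply(seq_len(n_trials), function(t) {
    trial_inputs <- inputs
    trial_inputs$disability_margin <- dis[t]
    trial_inputs$help_margin <- hlp[t]
    trial_inputs$freq_margins[] <- freq[, , t]
    as.numeric(informal_care_cost(trial_inputs))
  }, numeric(1))
  psa_result(trials, seed = seed)
}
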
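#' Labour-market table by age band and sex
#'
#' Employment rates and average annual wages per (age band, sex), used by
#' the human-capital valuation of premature mortality. Bands are
#' half-open `[age_low, age_high)` and must not overlap within a sex.
#'
#' @param df Data frame with columns `sex`, `age_low`, `age_high`,
#'   `employment_rate`, `annual_wage_gbp`.
#' @return Validated data frame with class `labor_market_table`.
#' @export
labor_market_table <- function(df) {
  need <- c("sex", "age_low", "age_high", "employment_rate", "annual_wage_gbp")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(df$employment_rate >= 0 & df$employment_rate <= 1),
            all(df$annual_wage_gbp >= 0), all(df$age_low < df$age_high))
  for (s in unique(df$sex)) {
    b <- df[df$sex == s, ]
    b <- b[order(b$age_low), ]
    if (nrow(b) > 1L && any(b$age_high[-nrow(b)] > b$age_low[-1L])) {
      stop("overlapping age bands for sex '", s, "'")
    }
  }
  class(df) <- c("labor_market_table", "data.frame")
  df
}

labor_lookup <- function(table, age, sex) {
  hit <- table$sex == sex & table$age_low <= age & age < table$age_high
  if (!any(hit)) {
    stop("no labour-market band covers age ", age, " for sex '", sex, "'")
  }
  table[which(hit)[1L], ]
}

#' Present value of expected future earnings lost to a death
#'
#' Human-capital approach: expected earnings (employment rate times
#' average wage for the age and sex reached in each future year) are
#' summed from the age at death (floored at the working-age minimum of
#' 15) to the year before retirement at 65, serially discounted at 3.5%
#' per annum. Earnings in the year of death are counted undiscounted;
#' discounting starts the following year. Zero at or after retirement.
#'
#' @param age_at_death Age in whole years.
#' @param sex Sex category matching the table.
#' @param table A [labor_market_table()].
#' @param rate Annual discount rate (default 0.035).
#' @param retirement Retirement age (default 65).
#' @param working_age_min Minimum working age (default 15).
#' @return Present value in GBP (numeric).
#' @export
present_value_earnings <- function(age_at_death, sex, table, rate = 0.035,
                                   retirement = 65, working_age_min = 15) {
  stopifnot(age_at_death >= 0)
  if (age_at_death >= retirement) return(0)
  years <- seq(max(age_at_death, working_age_min), retirement - 1L)
  pv <- 0
  for (y in years) {
    band <- labor_lookup(table, y, sex)
    pv <- pv + band$employment_rate * band$annual_wage_gbp *
      discount_factor(y - age_at_death, rate)
  }
  pv
}

#' Production losses from premature cardiovascular mortality
#'
#' Deaths arrive banded by age and sex; each band is valued at the
#' present value of earnings for its integer midpoint age (band-edge
#' deaths belong to the band containing the age) and the losses are
#' additive over records.
#'
#' @param deaths Data frame with columns `sex`, `age_low`, `age_high`,
#'   `deaths` (and optionally `nation`, `fiscal_year`).
#' @param table A [labor_market_table()].
#' @inheritParams present_value_earnings
#' @return Total loss in GBP (numeric).
#' @export
mortality_loss <- function(deaths, table, rate = 0.035, retirement = 65,
                           working_age_min = 15) {
  stopifnot(all(c("sex", "age_low", "age_high", "deaths") %in% names(deaths)),
            all(deaths$deaths >= 0))
  total <- 0
  for (i in seq_len(nrow(deaths))) {
    mid <- floor((deaths$age_low[i] + deaths$age_high[i]) / 2)
    if (mid >= retirement) next
    total <- total + deaths$deaths[i] *
      present_value_earnings(mid, deaths$sex[i], table, rate, retirement,
                             working_age_min)
  }
  total
}

#' Production losses from sickness absence
#'
#' Recorded sickness days attributable to circulatory disease times the
#' average daily wage for the year.
#'
#' @param days Sickness-day count.
#' @param daily_wage Average daily wage in GBP.
#' @return Loss in GBP.
#' @export
sickness_loss <- function(days, daily_wage) {
  stopifnot(days >= 0, daily_wage >= 0)
  days * daily_wage
}

#' Benefit payments attributable to cardiovascular claims
#'
#' Average weekly payment times claimants, adjusted for how much of the
#' year the claim runs (`weeks_remaining` in \[0, 52\]).
#'
#' @param claims Data frame with columns `scheme` (`"ESA"` or `"DLA"`),
#'   `claimants`, `weekly_amount_gbp`, `weeks_remaining`, and optionally
#'   `condition`.
#' @return Total benefit cost in GBP.
#' @export
benefit_cost <- function(claims) {
  need <- c("scheme", "claimants", "weekly_amount_gbp", "weeks_remaining")
  stopifnot(all(need %in% names(claims)))
  if (any(claims$weeks_remaining < 0 | claims$weeks_remaining > 52)) {
    stop("weeks_remaining must lie in [0, 52]")
  }
  stopifnot(all(claims$claimants >= 0), all(claims$weekly_amount_gbp >= 0))
  sum(claims$claimants * claims$weekly_amount_gbp * claims$weeks_remaining)
}

#' Morbidity cost: sickness absence plus benefit claims
#'
#' Assembles the morbidity component. Disability-allowance claims whose
#' condition is dementia are scaled by the vascular-dementia share (17%)
#' before costing, since only that fraction of dementia is attributed to
#' cardiovascular disease.
#'
#' @param sickness_days Sickness-day count.
#' @param daily_wage Average daily wage in GBP.
#' @param claims Benefit claims data frame (see [benefit_cost()]); rows
#'   with `condition == "dementia"` are scaled.
#' @param vad_share Vascular-dementia share of dementia.
#' @return Total morbidity cost in GBP.
#' @export
morbidity_cost <- function(sickness_days, daily_wage, claims,
                           vad_share = 0.17) {
  if (vad_share < 0 || vad_share > 1) stop("vad_share must lie in [0, 1]")
  if ("condition" %in% names(claims)) {
    dem <- !is.na(claims$condition) & claims$condition == "dementia"
    claims$claimants[dem] <- claims$claimants[dem] * vad_share
  }
  sickness_loss(sickness_days, daily_wage) + benefit_cost(claims)
}

#' Probabilistic sensitivity analysis of the mortality loss
#'
#' Samples band-level wages (normal around the table values, truncated at
#' zero, standard deviation expressed as a coefficient of variation) and
#' re-evaluates the mortality loss per trial.
#'
#' @param deaths Deaths data frame (see [mortality_loss()]).
#' @param table A [labor_market_table()].
#' @param wage_cv Coefficient of variation of band wages.
#' @param n Number of trials (default 1000).
#' @param seed Integer seed.
#' @inheritParams present_value_earnings
#' @return A [psa_result()].
#' @export
psa_mortality <- function(deaths, table, wage_cv = 0.05, n = 1000, seed = 1,
                          rate = 0.035, retirement = 65,
                          working_age_min = 15) {
  if (n < 2) stop("need at least 2 trials")
  stopifnot(wage_cv >= 0)
  set.seed(seed)
  base_wages <- table$annual_wage_gbp
  trials <- vapply(seq_len(n), function(i) {
    t2 <- table
    if (wage_cv > 0) {
      t2$annual_wage_gbp <- pmax(0, stats::rnorm(length(base_wages),
                                                 base_wages,
                                                 wage_cv * base_wages))
    }
    mortality_loss(deaths, t2, rate, retirement, working_age_min)
  }, numeric(1))
  psa_result(trials, seed = seed)
}
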
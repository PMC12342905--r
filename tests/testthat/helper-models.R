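# Shared builders for small in-code fixtures.

tiny_ledger <- function(price_year = 2022) {
  cost_ledger(data.frame(
    component = c("inpatient", "inpatient", "medications", "informal_care"),
    nation = c("England", "Scotland", "England", "Wales"),
    fiscal_year = "2021/22",
    amount_gbp = c(100, 50, 30, 20),
    price_year = price_year))
}

three_state_matrix <- function() {
  states <- c("home", "care_home", "death")
  matrix(c(0.80, 0.12, 0.08,
           0.05, 0.75, 0.20,
           0.00, 0.00, 1.00),
         3, 3, byrow = TRUE, dimnames = list(states, states))
}

four_state_matrix <- function() {
  states <- c("home", "community", "care_home", "death")
  matrix(c(0.86, 0.04, 0.03, 0.07,
           0.25, 0.60, 0.08, 0.07,
           0.00, 0.02, 0.78, 0.20,
           0.00, 0.00, 0.00, 1.00),
         4, 4, byrow = TRUE, dimnames = list(states, states))
}

flat_labor_table <- function(rate = 0.8, wage = 30000) {
  labor_market_table(data.frame(
    sex = "female", age_low = 15, age_high = 65,
    employment_rate = rate, annual_wage_gbp = wage))
}

# Closed-form annuity for flat employment/wage with the year-of-death
# term undiscounted: sum_{k=0}^{m-1} e*w*(1+r)^-k
flat_pv <- function(age, rate_e, wage, r = 0.035, retirement = 65) {
  m <- retirement - age
  if (m <= 0) return(0)
  x <- 1 / (1 + r)
  rate_e * wage * (1 - x^m) / (1 - x)
}
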
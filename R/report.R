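#' Assemble a cost report from a ledger
#'
#' Produces the published-table layout: a direct-cost table and an
#' indirect-cost table (component by nation, with a UK column formed by
#' aggregation), component totals, and a headline summary in billions of
#' pounds to 3 decimal places (half-up). Direct + indirect must equal the
#' grand total to the penny before any rounding.
#'
#' @param ledger A [cost_ledger()].
#' @param year Fiscal-year label to report.
#' @return Object of class `cost_report`.
#' @export
cost_report <- function(ledger, year) {
  stopifnot(inherits(ledger, "cost_ledger"))
  sub <- ledger[ledger$fiscal_year == year, , drop = FALSE]
  if (!nrow(sub)) stop("no ledger entries for fiscal year ", year)
  tab <- function(components) {
    components <- intersect(components, unique(sub$component))
    rows <- lapply(components, function(comp) {
      amounts <- vapply(uk_nations(), function(nat) {
        sum(sub$amount_gbp[sub$component == comp & sub$nation == nat])
      }, numeric(1))
      data.frame(component = comp, t(amounts), UK = sum(amounts),
                 check.names = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  direct <- tab(direct_components())
  indirect <- tab(indirect_components())
  direct_total <- aggregate_costs(sub, components = direct_components())
  indirect_total <- aggregate_costs(sub, components = indirect_components())
  total <- direct_total + indirect_total
  # report identity: tables and totals must agree to the penny
  stopifnot(abs(sum(direct$UK) - direct_total$amount) < 0.005,
            abs(sum(indirect$UK) - indirect_total$amount) < 0.005)
  structure(list(
    year = year,
    price_year = sub$price_year[1],
    direct = direct,
    indirect = indirect,
    totals = list(direct = direct_total, indirect = indirect_total,
                  total = total),
    headline = c(total_bn = round_half_up(total$amount / 1e9, 3),
                 direct_bn = round_half_up(direct_total$amount / 1e9, 3),
                 indirect_bn = round_half_up(indirect_total$amount / 1e9, 3))),
    class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Cost-of-illness report,", x$year,
      sprintf("(GBP, %d real terms)\n", x$price_year))
  cat(sprintf("  total £%.3f bn = direct £%.3f bn + indirect £%.3f bn\n",
              x$headline["total_bn"], x$headline["direct_bn"],
              x$headline["indirect_bn"]))
  invisible(x)
}

#' Flatten a cost report to one row per component and nation
#'
#' The long-format view used for both the CSV and JSON renderings, so the
#' two exports are value-identical by construction.
#'
#' @param report A [cost_report()].
#' @return Data frame with columns `component`, `nation`, `amount_gbp`.
#' @export
report_as_table <- function(report) {
  stopifnot(inherits(report, "cost_report"))
  flatten <- function(tab) {
    cols <- c(uk_nations(), "UK")
    do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      data.frame(component = tab$component[i], nation = cols,
                 amount_gbp = as.numeric(tab[i, cols]))
    }))
  }
  out <- rbind(flatten(report$direct), flatten(report$indirect))
  rownames(out) <- NULL
  out
}

#' Write a cost report as CSV and JSON
#'
#' @param report A [cost_report()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the flattened table.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  tab <- report_as_table(report)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(year = report$year,
                              headline = as.list(report$headline),
                              entries = tab),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}

#' Tornado-diagram rendering data
#'
#' @param entries A `tornado` data frame from [one_way()] or
#'   [combine_extremes()].
#' @param path Optional CSV path.
#' @return The entries sorted by swing, largest first.
#' @export
render_tornado <- function(entries, path = NULL) {
  if (is.null(entries) || !nrow(entries)) stop("no tornado entries to render")
  stopifnot(all(c("name", "pct_change_low", "pct_change_high",
                  "swing") %in% names(entries)))
  out <- entries[order(-entries$swing), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Box-plot rendering data for PSA results
#'
#' Five-number summaries (minimum, lower quartile, median, upper
#' quartile, maximum) per labelled PSA run, as drawn in box-plot figures
#' where whiskers are the minimum and maximum.
#'
#' @param results Named list of [psa_result()] objects (e.g. one per
#'   nation).
#' @param path Optional CSV path.
#' @return Data frame of five-number summaries.
#' @export
render_psa_box <- function(results, path = NULL) {
  if (is.null(results) || !length(results)) stop("no PSA results to render")
  stopifnot(all(vapply(results, inherits, logical(1), "psa_result")))
  out <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(label = nm, minimum = r$minimum, q25 = r$q25,
               median = r$median, q75 = r$q75, maximum = r$maximum, n = r$n)
  }))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

default_nation_shares <- function() {
  c("England" = 0.843, "Scotland" = 0.082, "Wales" = 0.047,
    "Northern Ireland" = 0.028)
}

#' Run the cost-of-illness pipeline
#'
#' Two modes. `"fixtures"` reports the packaged published cost tables
#' as-is (pass-through ledger, no modelling). `"simulate"` keeps the
#' fixture direct-cost entries but replaces the three modelled indirect
#' components with a full synthetic run: survey generation, logistic /
#' ordered-logistic marginal effects and the informal-care product model;
#' a Markov post-stroke cohort for context; synthetic deaths and
#' labour-market tables through the human-capital mortality model; and
#' sickness days plus benefit claims for morbidity. Indirect UK totals
#' are split across nations by population share. Deterministic under
#' `seed`.
#'
#' @param config List: `mode` ("fixtures" or "simulate"), `year`
#'   (fiscal-year label, default "2021/22"), `seed`, `exclude`
#'   (components to drop), `survey_n`, `population_over_50`,
#'   `ltc_unit_cost`, `sickness_days`, `daily_wage`, `wage_policy`.
#' @return A [cost_report()] with attribute `"log"` recording every
#'   constant and seed used.
#' @export
run_pipeline <- function(config = list()) {
  mode <- config$mode %||% "fixtures"
  year <- config$year %||% "2021/22"
  seed <- config$seed %||% 1L
  fixtures <- load_fixtures()
  ledger_df <- as.data.frame(fixtures$ledger)
  log <- list(mode = mode, year = year, seed = seed,
              rules = vapply(fixtures$rules, `[[`, numeric(1), "share"))

  if (mode == "simulate") {
    shares <- config$nation_shares %||% default_nation_shares()
    stopifnot(abs(sum(shares) - 1) < 1e-9)

    # --- informal care from synthetic survey ---
    survey <- gen_survey(survey_config(n = config$survey_n %||% 4000),
                         seed = seed)
    dat <- survey$data
    dis <- fit_binary_margin(dat, "severely_disabled")
    hin <- fit_binary_margin(dat, "in_household_help",
                             covariates = c("age", "gender",
                                            "n_comorbidities",
                                            "household_size"))
    hout <- fit_binary_margin(dat, "out_household_help",
                              covariates = c("age", "gender",
                                             "n_comorbidities",
                                             "household_size"))
    policy <- config$wage_policy %||% wage_policy(9.50, 16.00)
    freq_m <- matrix(0, 3, 4)
    hours <- numeric(3)
    wages <- numeric(3)
    for (k in 1:3) {
      om <- fit_ordered_margins(dat, paste0("carer", k, "_freq"))
      freq_m[k, ] <- vapply(c("daily", "weekly", "monthly", "annually"),
                            function(cat) om[[cat]]$margin, numeric(1))
      hours[k] <- mean(dat[[paste0("carer", k, "_hours")]], na.rm = TRUE)
      present <- !is.na(dat[[paste0("carer", k, "_hours")]])
      wages[k] <- mean(mapply(
        carer_wage,
        dat[[paste0("carer", k, "_relationship")]][present],
        dat[[paste0("carer", k, "_employed")]][present] == 1,
        dat$age[present],
        MoreArgs = list(policy = policy)))
    }
    inputs <- informal_care_inputs(
      population_over_50 = config$population_over_50 %||% 25.9e6,
      cvd_prevalence = mean(dat$has_cvd),
      disability_margin = dis$margin,
      help_margin = hin$margin + hout$margin,
      freq_margins = freq_m, hours_per_contact = hours,
      wage_per_hour = wages)
    informal_uk <- as.numeric(informal_care_cost(inputs))

    # --- stroke LTC Markov cohort (annual cycles, cycle-start accrual) ---
    states <- c("home", "community", "care_home", "death")
    true_tm <- config$stroke_matrix %||% matrix(c(
      0.86, 0.04, 0.03, 0.07,
      0.25, 0.60, 0.08, 0.07,
      0.00, 0.02, 0.78, 0.20,
      0.00, 0.00, 0.00, 1.00), 4, 4, byrow = TRUE,
      dimnames = list(states, states))
    counts <- gen_stroke_counts(config$ssnap_n %||% 5000, true_tm,
                                seed = seed + 1L)
    tm <- counts_to_probabilities(counts)
    model <- markov_model(states, tm)
    trace <- run_cohort(model, c(config$annual_strokes %||% 90000, 0, 0, 0),
                        config$ltc_cycles %||% 10)
    ltc_py <- care_home_person_years(trace, "care_home")
    stroke_ltc_uk <- stroke_ltc_cost(ltc_py,
                                     config$ltc_unit_cost %||% 42000)
    log$stroke_ltc_uk <- stroke_ltc_uk

    # --- mortality and morbidity ---
    lad <- gen_labor_and_deaths(seed = seed + 2L)
    mortality_uk <- mortality_loss(lad$deaths, lad$labor)
    claims <- config$claims %||% data.frame(
      scheme = c("ESA", "DLA", "DLA"),
      condition = c("heart disease", "cerebrovascular", "dementia"),
      claimants = c(220000, 160000, 180000),
      weekly_amount_gbp = c(115, 82, 82),
      weeks_remaining = c(26, 26, 26))
    morbidity_uk <- morbidity_cost(config$sickness_days %||% 5.8e6,
                                   config$daily_wage %||% 118, claims)

    indirect <- do.call(rbind, lapply(names(shares), function(nat) {
      data.frame(component = c("informal_care", "mortality", "morbidity"),
                 nation = nat, fiscal_year = year,
                 amount_gbp = shares[[nat]] *
                   c(informal_uk, mortality_uk, morbidity_uk),
                 price_year = ledger_df$price_year[1],
                 provenance = "synthetic model run")
    }))
    ledger_df <- rbind(
      ledger_df[ledger_df$component %in% direct_components(), ],
      indirect)
    log$informal_uk <- informal_uk
    log$mortality_uk <- mortality_uk
    log$morbidity_uk <- morbidity_uk
  }

  if (!is.null(config$exclude)) {
    ledger_df <- ledger_df[!ledger_df$component %in% config$exclude, ]
  }
  report <- cost_report(cost_ledger(ledger_df), year)
  attr(report, "log") <- log
  report
}
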
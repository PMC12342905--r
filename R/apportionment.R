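#' Apportionment rules
#'
#' Top-down costing attributes a share of an aggregate budget or activity
#' level to cardiovascular disease. Each rule is a named proportion with a
#' citation; the shares the analysis relies on (17.9% of general-medicine
#' admissions, 30% stroke/TIA-to-neurology ratio, 7.2% vascular-to-general
#' surgery ratio, 12% of GP consultations via the hypertension proxy, 17%
#' of dementia as vascular dementia) live in one versioned registry shipped
#' as YAML, because the sensitivity analysis varies them.
#'
#' @param name Rule name.
#' @param share Proportion in \[0, 1\].
#' @param source Citation text.
#' @return Object of class `apportionment_rule`.
#' @export
apportionment_rule <- function(name, share, source = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(share) || length(share) != 1L || !is.finite(share) ||
      share < 0 || share > 1) {
    stop("share must be a proportion in [0, 1], got: ", share)
  }
  structure(list(name = name, share = as.numeric(share), source = source),
            class = "apportionment_rule")
}

#' Load the apportionment-rule registry
#'
#' @param path YAML path; defaults to the packaged registry.
#' @return Named list of [apportionment_rule()] objects.
#' @export
load_apportionment_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "apportionment_rules.yaml",
                        package = "cvdcoi", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  rules <- lapply(names(raw$rules), function(nm) {
    apportionment_rule(nm, raw$rules[[nm]]$share,
                       raw$rules[[nm]]$source %||% "")
  })
  names(rules) <- names(raw$rules)
  rules
}

`%||%` <- function(a, b) if (is.null(a)) b else a

amount_of <- function(x) if (is_money(x)) x$amount else x
rewrap <- function(template, amount) {
  if (is_money(template)) money(amount, template$price_year) else amount
}

#' Apply a share rule to an amount
#'
#' @param amount Numeric GBP or [money()].
#' @param rule An [apportionment_rule()] (or bare proportion).
#' @return Same type as `amount`.
#' @export
apply_share <- function(amount, rule) {
  share <- if (inherits(rule, "apportionment_rule")) rule$share else {
    apportionment_rule("ad hoc", rule)$share
  }
  rewrap(amount, amount_of(amount) * share)
}

#' Cost of specialist activity, with the generalist share applied
#'
#' Outpatient costs are the product of activity and per-consultation cost.
#' Dedicated cardiovascular specialties count in full; generalist
#' specialties that see cardiovascular disease without it dominating their
#' case-mix are scaled by the generalist share (17.9% by default registry).
#'
#' @param records Data frame with columns `activity`, `unit_cost_gbp` and
#'   `class` (values `"dedicated"` or `"generalist"`).
#' @param cvd_share Proportion applied to generalist records.
#' @return Total cost in GBP (numeric).
#' @export
activity_cost <- function(records, cvd_share) {
  if (nrow(records) == 0L) return(0)
  stopifnot(all(c("activity", "unit_cost_gbp", "class") %in% names(records)))
  if (any(records$activity < 0) || any(records$unit_cost_gbp < 0)) {
    stop("activity counts and unit costs must be non-negative")
  }
  bad <- setdiff(unique(records$class), c("dedicated", "generalist"))
  if (length(bad)) stop("unknown specialty class: ", paste(bad, collapse = ", "))
  share <- ifelse(records$class == "generalist",
                  apportionment_rule("generalist", cvd_share)$share, 1)
  sum(records$activity * records$unit_cost_gbp * share)
}

#' Attribute uncoded consultations proportionally to coded ones
#'
#' Emergency-care consultations without (valid) diagnostic codes receive
#' the CVD share observed among coded consultations. Fractional attributed
#' counts are kept fractional until costing.
#'
#' @param coded_cvd CVD-coded consultation count.
#' @param coded_total All coded consultations (> 0).
#' @param uncoded Uncoded consultation count.
#' @return Attributed (possibly fractional) CVD count among the uncoded.
#' @export
uncoded_attribution <- function(coded_cvd, coded_total, uncoded) {
  stopifnot(coded_cvd >= 0, uncoded >= 0)
  if (coded_total <= 0) stop("coded_total must be positive")
  if (coded_cvd > coded_total) stop("coded_cvd cannot exceed coded_total")
  uncoded * coded_cvd / coded_total
}

#' Welsh inpatient cost as the residual of the circulatory secondary budget
#'
#' Wales records only a gross circulatory-disease secondary-care budget;
#' A&E and outpatient estimates (England unit costs times Welsh activity)
#' are subtracted and the residual is the inpatient estimate.
#'
#' @param budget,ae_est,op_est `money` (shared price year) or numeric GBP.
#' @return Residual inpatient estimate, same type as `budget`.
#' @export
wales_inpatient_residual <- function(budget, ae_est, op_est) {
  if (is_money(budget) && is_money(ae_est)) check_same_price_year(budget, ae_est)
  if (is_money(budget) && is_money(op_est)) check_same_price_year(budget, op_est)
  res <- amount_of(budget) - amount_of(ae_est) - amount_of(op_est)
  if (res < 0) {
    stop("negative Welsh inpatient residual (", res,
         "): A&E + outpatient estimates exceed the secondary budget")
  }
  rewrap(budget, res)
}

#' Welsh outpatient cost via the England outpatient-to-secondary ratio
#'
#' The ratio of England's CVD outpatient cost to England's total CVD
#' secondary-care cost (inpatient + outpatient + A&E) is applied to the
#' Welsh circulatory secondary budget.
#'
#' @param england_outpatient_cvd England CVD outpatient cost.
#' @param england_secondary_cvd_total England CVD secondary-care total (> 0).
#' @param welsh_budget Welsh circulatory secondary budget.
#' @return Estimated Welsh CVD outpatient cost, same type as `welsh_budget`.
#' @export
wales_outpatient_share <- function(england_outpatient_cvd,
                                   england_secondary_cvd_total,
                                   welsh_budget) {
  denom <- amount_of(england_secondary_cvd_total)
  if (denom <= 0) stop("England secondary-care total must be positive")
  rewrap(welsh_budget,
         amount_of(welsh_budget) * amount_of(england_outpatient_cvd) / denom)
}

#' Scale an England cost to another nation by population
#'
#' Used for medical-device expenditure, which only England reports: the
#' other nations receive England's spend scaled by their population ratio.
#'
#' @param england_cost England cost (numeric GBP or `money`).
#' @param nation_pop,england_pop Population counts; `england_pop` > 0.
#' @return Scaled cost, same type as `england_cost`.
#' @export
scale_by_population <- function(england_cost, nation_pop, england_pop) {
  stopifnot(nation_pop >= 0)
  if (england_pop <= 0) stop("england_pop must be positive")
  rewrap(england_cost, amount_of(england_cost) * nation_pop / england_pop)
}
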
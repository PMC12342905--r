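#' Cost components and nations
#'
#' The analysis estimates ten cost components: seven direct (inpatient,
#' outpatient, accident & emergency, primary care, medications, medical
#' devices, and long-term care split into post-stroke and vascular-dementia
#' care) and three indirect (production losses to morbidity and mortality,
#' and informal care). Costing is performed for each of the four UK nations;
#' UK figures only ever arise by aggregation, never as stored entries.
#'
#' @return Character vectors of valid component / nation names.
#' @export
cost_components <- function() {
  c(direct_components(), indirect_components())
}

#' @rdname cost_components
#' @export
direct_components <- function() {
  c("inpatient", "outpatient", "a_and_e", "primary_care",
    "medications", "devices", "ltc_stroke", "ltc_vad")
}

#' @rdname cost_components
#' @export
indirect_components <- function() {
  c("morbidity", "mortality", "informal_care")
}

#' @rdname cost_components
#' @export
uk_nations <- function() {
  c("England", "Scotland", "Wales", "Northern Ireland")
}

#' Cost ledger
#'
#' The backbone container every costing stage writes into: one row per
#' (component, nation, fiscal year), amounts in GBP expressed in a single
#' shared price year. "UK" is deliberately not a valid nation; UK totals are
#' produced by [aggregate_costs()].
#'
#' @param df Data frame with columns `component`, `nation`, `fiscal_year`,
#'   `amount_gbp`, `price_year` and optionally `provenance`.
#' @return The validated data frame with class `cost_ledger`.
#' @export
cost_ledger <- function(df) {
  required <- c("component", "nation", "fiscal_year", "amount_gbp", "price_year")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("ledger is missing columns: ",
                            paste(missing, collapse = ", "))
  if (!"provenance" %in% names(df)) df$provenance <- rep("", nrow(df))
  bad_comp <- setdiff(unique(df$component), cost_components())
  if (length(bad_comp)) stop("unknown cost components: ",
                             paste(bad_comp, collapse = ", "))
  bad_nation <- setdiff(unique(df$nation), uk_nations())
  if (length(bad_nation)) stop("unknown nations (UK is aggregate-only): ",
                               paste(bad_nation, collapse = ", "))
  invisible(lapply(unique(df$fiscal_year), fiscal_year))
  if (any(!is.finite(df$amount_gbp)) || any(df$amount_gbp < 0)) {
    stop("ledger amounts must be finite and non-negative")
  }
  if (length(unique(df$price_year)) > 1L) {
    stop("all ledger entries must share one price_year; found: ",
         paste(unique(df$price_year), collapse = ", "))
  }
  key <- paste(df$component, df$nation, df$fiscal_year)
  if (anyDuplicated(key)) {
    stop("duplicate ledger entries for: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(df) <- c("cost_ledger", "data.frame")
  df
}

#' Read / write a cost ledger CSV
#'
#' Ledger CSVs carry columns component, nation, fiscal_year, amount_gbp,
#' price_year, provenance (UTF-8, header required).
#'
#' @param path CSV path.
#' @export
read_cost_ledger <- function(path) {
  cost_ledger(utils::read.csv(path, check.names = TRUE))
}

#' @rdname read_cost_ledger
#' @param ledger A [cost_ledger()].
#' @export
write_cost_ledger <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}

#' Aggregate ledger entries into a single amount
#'
#' Exact sum of the matched entries; an empty match is zero. This is how
#' nation-level rows roll up to UK totals and components roll up to the
#' direct / indirect / grand totals.
#'
#' @param ledger A [cost_ledger()].
#' @param components Components to include (default: all).
#' @param nations Nations to include (default: all four).
#' @param years Fiscal-year labels to include (default: all present).
#' @return A [money()] in the ledger's price year.
#' @export
aggregate_costs <- function(ledger, components = NULL, nations = NULL,
                            years = NULL) {
  stopifnot(inherits(ledger, "cost_ledger"))
  price_year <- if (nrow(ledger)) ledger$price_year[1] else NA_integer_
  keep <- rep(TRUE, nrow(ledger))
  if (!is.null(components)) keep <- keep & ledger$component %in% components
  if (!is.null(nations)) keep <- keep & ledger$nation %in% nations
  if (!is.null(years)) keep <- keep & ledger$fiscal_year %in% years
  if (is.na(price_year)) price_year <- 2022L  # empty ledger: price year moot
  money(sum(ledger$amount_gbp[keep]), price_year)
}
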
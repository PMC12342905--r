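#' Money tagged with a price year
#'
#' Cost-of-illness arithmetic mixes figures collected in different years;
#' every amount therefore carries the calendar year whose real terms it is
#' expressed in, and arithmetic between amounts is only permitted when the
#' price years agree. Amounts are plain doubles holding GBP to (better than)
#' penny precision; rounding happens only at report time.
#'
#' @param amount Finite numeric scalar, GBP.
#' @param price_year Calendar year the amount is expressed in real terms of.
#' @return An object of class `money`.
#' @examples
#' money(100, 2022) + money(50, 2022)
#' @export
money <- function(amount, price_year) {
  stopifnot(is.numeric(amount), length(amount) == 1L, is.finite(amount))
  stopifnot(is.numeric(price_year), length(price_year) == 1L,
            price_year == as.integer(price_year))
  structure(list(amount = as.numeric(amount),
                 price_year = as.integer(price_year)),
            class = "money")
}

#' @export
print.money <- function(x, ...) {
  cat(sprintf("GBP %s (in %d real terms)\n",
              format(x$amount, big.mark = ",", nsmall = 2, scientific = FALSE),
              x$price_year))
  invisible(x)
}

is_money <- function(x) inherits(x, "money")

check_same_price_year <- function(a, b) {
  if (a$price_year != b$price_year) {
    stop("price_year mismatch: ", a$price_year, " vs ", b$price_year,
         "; inflate() one side first (no silent coercion)", call. = FALSE)
  }
}

#' @export
`+.money` <- function(e1, e2) {
  check_same_price_year(e1, e2)
  money(e1$amount + e2$amount, e1$price_year)
}

#' @export
`-.money` <- function(e1, e2) {
  check_same_price_year(e1, e2)
  money(e1$amount - e2$amount, e1$price_year)
}

#' Fiscal year label
#'
#' UK fiscal years run April to March and are written "2021/22". The label
#' must name two consecutive years.
#'
#' @param label Character like `"2021/22"`.
#' @return Object of class `fiscal_year` with fields `label` and `start_year`.
#' @export
fiscal_year <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^([0-9]{4})/([0-9]{2}|[0-9]{4})$", label))[[1]]
  if (length(m) == 0L) stop("fiscal year label must look like '2021/22': ", label)
  start <- as.integer(m[2])
  second <- as.integer(m[3])
  next_year <- if (nchar(m[3]) == 2L) (start + 1L) %% 100L else start + 1L
  if (second != next_year) {
    stop("fiscal year label must name consecutive years: ", label)
  }
  structure(list(label = label, start_year = start), class = "fiscal_year")
}

#' @export
print.fiscal_year <- function(x, ...) {
  cat("Fiscal year", x$label, "\n")
  invisible(x)
}

#' GDP deflator table
#'
#' Maps calendar years to a base-year-normalised deflator index, used to
#' express nominal amounts in common real terms.
#'
#' @param years Integer vector of calendar years.
#' @param index Positive deflator index per year.
#' @return Object of class `deflator_table`.
#' @export
deflator_table <- function(years, index) {
  stopifnot(length(years) == length(index), all(index > 0),
            !anyDuplicated(years))
  structure(list(years = as.integer(years), index = as.numeric(index)),
            class = "deflator_table")
}

#' Read a deflator table from a two-column CSV (year,index)
#' @param path CSV path.
#' @export
read_deflator_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("year", "index") %in% names(df)))
  deflator_table(df$year, df$index)
}

deflator_index <- function(table, year) {
  i <- match(year, table$years)
  if (is.na(i)) stop("year ", year, " not present in deflator table")
  table$index[i]
}

#' Re-express an amount in another year's real terms
#'
#' Multiplies by the ratio of deflator indices and re-tags the price year.
#'
#' @param x A `money` object.
#' @param to_year Target price year (must be in `table`).
#' @param table A [deflator_table()].
#' @return `money` in `to_year` real terms.
#' @export
inflate <- function(x, to_year, table) {
  stopifnot(is_money(x))
  from <- deflator_index(table, x$price_year)
  to <- deflator_index(table, to_year)
  money(x$amount * to / from, to_year)
}

#' Exchange-rate table (currency, fiscal year) -> GBP per unit
#'
#' @param df Data frame with columns `currency`, `fiscal_year`, `rate`
#'   (GBP per unit of the foreign currency; mid-year floating rates).
#' @export
exchange_rate_table <- function(df) {
  stopifnot(all(c("currency", "fiscal_year", "rate") %in% names(df)),
            all(df$rate > 0))
  structure(df, class = c("exchange_rate_table", "data.frame"))
}

#' Convert a foreign-currency amount to GBP
#'
#' @param amount Numeric amount in `currency`.
#' @param currency Currency code, e.g. "EUR".
#' @param year Fiscal-year label the rate applies to.
#' @param table An [exchange_rate_table()].
#' @param price_year Price year to tag the GBP result with.
#' @return `money` in GBP.
#' @export
convert_currency <- function(amount, currency, year, table, price_year) {
  stopifnot(is.numeric(amount), length(amount) == 1L, is.finite(amount))
  hit <- table$currency == currency & table$fiscal_year == year
  if (!any(hit)) stop("no exchange rate for ", currency, " in ", year)
  money(amount * table$rate[which(hit)[1]], price_year)
}

#' Discount factor for costs accruing a whole number of years ahead
#'
#' HM Treasury's recommended discount rate for future costs is 3.5% per
#' annum; the factor for `y` years ahead is `(1 + rate)^(-y)`.
#'
#' @param years_ahead Non-negative integer(s).
#' @param rate Annual discount rate, default 0.035.
#' @return Numeric vector of factors.
#' @examples
#' discount_factor(0:2)
#' @export
discount_factor <- function(years_ahead, rate = 0.035) {
  stopifnot(is.numeric(years_ahead), all(is.finite(years_ahead)))
  if (any(years_ahead < 0)) stop("years_ahead must be non-negative")
  if (any(years_ahead != floor(years_ahead))) {
    stop("years_ahead must be whole years")
  }
  stopifnot(rate > -1)
  (1 + rate)^(-years_ahead)
}

#' Signed percentage change between two amounts
#'
#' @param old,new `money` objects sharing a price year; `old` positive.
#' @return Unrounded signed percentage. Reports round at 1 decimal place,
#'   half-up (see [round_half_up()]).
#' @export
percent_change <- function(old, new) {
  stopifnot(is_money(old), is_money(new))
  check_same_price_year(old, new)
  if (old$amount <= 0) stop("percent_change needs a positive baseline")
  100 * (new$amount - old$amount) / old$amount
}

#' Round half away from zero
#'
#' Base R rounds half to even; published cost tables round half up, so
#' report-time rounding uses this helper.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
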
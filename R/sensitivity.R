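#' Parameter specification for sensitivity analysis
#'
#' One tunable model input with its base-case value, the low/high limits
#' used by the one-way (tornado) analysis, and optionally a sampling
#' distribution for probabilistic sensitivity analysis. Supported
#' distributions: `normal(mean, sd)`, `beta(shape1, shape2)`,
#' `uniform(min, max)`, `dirichlet(counts)` (for transition rows), each
#' with optional truncation bounds.
#'
#' @param name Parameter name.
#' @param base Base-case value.
#' @param low,high One-way limits; must bracket `base`.
#' @param dist Optional list, e.g. `list(type = "normal", mean = 1, sd = 0.1)`.
#' @param lower,upper Optional truncation bounds for sampled values.
#' @return Object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, base, low = base, high = base, dist = NULL,
                           lower = -Inf, upper = Inf) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(low <= base && base <= high)) {
    stop("parameter '", name, "': need low <= base <= high")
  }
  if (!is.null(dist)) {
    stopifnot(is.list(dist), !is.null(dist$type))
    if (!dist$type %in% c("normal", "beta", "uniform", "dirichlet", "fixed")) {
      stop("unsupported distribution type: ", dist$type)
    }
  }
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, lower = lower, upper = upper),
            class = "parameter_spec")
}

#' Read parameter specs from YAML
#'
#' @param path YAML file: a list of entries with fields name, base, low,
#'   high and optional distribution.
#' @export
read_parameter_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    parameter_spec(e$name, e$base, e$low %||% e$base, e$high %||% e$base,
                   dist = e$dist, lower = e$lower %||% -Inf,
                   upper = e$upper %||% Inf)
  })
}

draw_spec <- function(spec, n) {
  d <- spec$dist
  if (is.null(d)) stop("parameter '", spec$name, "' has no distribution")
  x <- switch(d$type,
    fixed = rep(spec$base, n),
    normal = stats::rnorm(n, d$mean, d$sd),
    beta = stats::rbeta(n, d$shape1, d$shape2),
    uniform = stats::runif(n, d$min, d$max),
    dirichlet = stop("dirichlet parameters are sampled by the Markov PSA"),
    stop("unsupported distribution type: ", d$type))
  # truncation by re-draw; clamp as a last resort for extreme bounds
  bad <- which(x < spec$lower | x > spec$upper)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- switch(d$type,
      fixed = spec$base,
      normal = stats::rnorm(length(bad), d$mean, d$sd),
      beta = stats::rbeta(length(bad), d$shape1, d$shape2),
      uniform = stats::runif(length(bad), d$min, d$max))
    bad <- which(x < spec$lower | x > spec$upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, spec$lower), spec$upper)
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each parameter alone to its low and high limit, holding the rest
#' at base, and reports the signed percentage change of the model output
#' against the base case, sorted by swing (largest first) as a tornado
#' diagram is drawn.
#'
#' @param model Function taking a named list of parameter values and
#'   returning the total cost (numeric scalar).
#' @param specs List of [parameter_spec()].
#' @return Data frame (class `tornado`) with columns `name`,
#'   `pct_change_low`, `pct_change_high`, `swing`.
#' @export
one_way <- function(model, specs) {
  stopifnot(length(specs) >= 1L)
  base_params <- stats::setNames(lapply(specs, `[[`, "base"),
                                 vapply(specs, `[[`, "", "name"))
  base_val <- try(model(base_params), silent = TRUE)
  if (inherits(base_val, "try-error") || !is.finite(base_val)) {
    stop("model failed to evaluate at the base case")
  }
  if (base_val == 0) stop("base-case total is zero; percentage change undefined")
  rows <- lapply(specs, function(sp) {
    eval_at <- function(value) {
      p <- base_params
      p[[sp$name]] <- value
      out <- try(model(p), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out)) {
        stop("model failed while varying parameter '", sp$name, "'")
      }
      out
    }
    lo <- 100 * (eval_at(sp$low) - base_val) / base_val
    hi <- 100 * (eval_at(sp$high) - base_val) / base_val
    data.frame(name = sp$name, pct_change_low = lo, pct_change_high = hi,
               swing = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis result
#'
#' Trial totals from a Monte Carlo run with their five-number summary.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); box-plot whiskers are the minimum and
#' maximum trial values.
#'
#' @param trials Numeric vector of trial totals.
#' @param seed Seed used to generate the trials.
#' @return Object of class `psa_result` with fields `trials`, `median`,
#'   `q25`, `q75`, `minimum`, `maximum`, `n`, `seed`.
#' @export
psa_result <- function(trials, seed = NA_integer_) {
  stopifnot(is.numeric(trials), length(trials) >= 2L, all(is.finite(trials)))
  q <- unname(stats::quantile(trials, c(0.25, 0.5, 0.75), type = 7))
  out <- structure(list(trials = trials, median = q[2], q25 = q[1], q75 = q[3],
                        minimum = min(trials), maximum = max(trials),
                        n = length(trials), seed = seed),
                   class = "psa_result")
  with(out, stopifnot(minimum <= q25, q25 <= median, median <= q75,
                      q75 <= maximum))
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA over %d trials (seed %s): median %.4g, IQR [%.4g, %.4g], range [%.4g, %.4g]\n",
    x$n, as.character(x$seed), x$median, x$q25, x$q75, x$minimum, x$maximum))
  invisible(x)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter sets (one shared seed, one random
#' stream, draw order fixed by spec order) and evaluates the model at
#' each.
#'
#' @inheritParams one_way
#' @param n Number of trials (default 1000, as in standard practice).
#' @param seed Integer seed.
#' @return A [psa_result()].
#' @export
run_psa <- function(model, specs, n = 1000, seed = 1) {
  if (n < 2) stop("need at least 2 trials")
  missing_dist <- vapply(specs, function(s) is.null(s$dist), logical(1))
  if (any(missing_dist)) {
    stop("parameters without a distribution: ",
         paste(vapply(specs[missing_dist], `[[`, "", "name"), collapse = ", "))
  }
  set.seed(seed)
  draws <- lapply(specs, draw_spec, n = n)
  names(draws) <- vapply(specs, `[[`, "", "name")
  trials <- vapply(seq_len(n), function(i) {
    model(lapply(draws, `[[`, i))
  }, numeric(1))
  psa_result(trials, seed = seed)
}

#' Tornado entries from component-wise PSA extremes
#'
#' For an additive total, swap one component at a time to the minimum and
#' maximum of its own PSA trial distribution (others at base) and report
#' the percentage change of the total.
#'
#' @param base_total Base-case total (numeric GBP or [money()]).
#' @param component_bounds Data frame with columns `name`, `base`, `min`,
#'   `max`; bounds must bracket the base values.
#' @return A `tornado` data frame sorted by swing.
#' @export
combine_extremes <- function(base_total, component_bounds) {
  total <- amount_of(base_total)
  stopifnot(all(c("name", "base", "min", "max") %in% names(component_bounds)))
  b <- component_bounds
  if (any(b$min > b$base | b$base > b$max)) {
    stop("component bounds must satisfy min <= base <= max")
  }
  out <- data.frame(
    name = b$name,
    pct_change_low = 100 * (b$min - b$base) / total,
    pct_change_high = 100 * (b$max - b$base) / total)
  out$swing <- abs(out$pct_change_high - out$pct_change_low)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}
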
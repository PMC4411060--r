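#' Assemble a biotransformation time course
#'
#' Long-format product accumulation data: one row per (time, product) with
#' concentration in uM. Peak areas can be supplied instead, with a surrogate
#' extinction coefficient table (`uM = area / response`) for compounds whose
#' own coefficient is unavailable.
#'
#' @param data Data frame with columns `time_min`, `product`, and either
#'   `conc_uM` or `area`.
#' @param substrate_uM Initial substrate concentration, uM.
#' @param response Named numeric vector of per-product area-to-uM response
#'   factors (required when `area` is supplied).
#' @return A tibble of class `timecourse` with attribute `substrate_uM`.
#' @export
timecourse <- function(data, substrate_uM, response = NULL) {
  stopifnot(all(c("time_min", "product") %in% names(data)))
  out <- tibble::as_tibble(data)
  if (!"conc_uM" %in% names(out)) {
    if (!"area" %in% names(out)) stop("need conc_uM or area", call. = FALSE)
    if (is.null(response)) {
      stop("peak areas need a response-factor table", call. = FALSE)
    }
    miss <- setdiff(unique(out$product), names(response))
    if (length(miss) > 0) {
      stop("no response factor for product(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    out$conc_uM <- out$area / unname(response[out$product])
  }
  if (any(out$conc_uM < -1e-9)) stop("concentrations must be >= 0", call. = FALSE)
  if (substrate_uM <= 0) stop("substrate_uM must be > 0", call. = FALSE)
  ok <- dplyr::summarise(dplyr::group_by(out, .data$product),
                         inc = !is.unsorted(.data$time_min, strictly = TRUE))
  if (!all(ok$inc)) stop("times must be strictly increasing per product",
                         call. = FALSE)
  attr(out, "substrate_uM") <- substrate_uM
  class(out) <- c("timecourse", class(out))
  out
}

# Longest initial span still linear: grow the window while (a) the next
# point is predicted by the current fit within 3 residual SDs (so the first
# point leaving the proportional regime stops the growth even when a global
# R^2 would still look fine) and (b) the extended fit keeps R^2 >= r2_min.
linear_window <- function(t, y, r2_min = 0.98) {
  n <- length(t)
  k <- 3L
  while (k < n) {
    f <- stats::lm(y[1:k] ~ t[1:k])
    if (k >= 5) {
      rmse <- sqrt(sum(stats::resid(f)^2) / (k - 2))
      dev <- function(j) {
        pred <- stats::coef(f)[[1]] + stats::coef(f)[[2]] * t[j]
        # residual scale grows with the signal for multiplicative noise
        scale <- max(1, abs(pred) / mean(abs(y[1:k])))
        abs(pred - y[j]) > max(3 * rmse * scale, 1e-7 * max(abs(y[1:k]), 1))
      }
      # a changepoint is persistent; a single noisy point is not
      if (dev(k + 1) && (k + 1 == n || dev(k + 2))) break
    }
    f2 <- stats::lm(y[1:(k + 1)] ~ t[1:(k + 1)])
    # noiseless data fit exactly; the perfect-fit warning is expected here
    r2 <- suppressWarnings(summary(f2)$r.squared)
    if (is.nan(r2)) r2 <- 1  # exactly flat segment
    if (r2 < r2_min) break
    k <- k + 1L
  }
  k
}

#' Initial formation rate of a product
#'
#' Ordinary least-squares slope of concentration against time over the
#' initial linear window. By default the window is the longest initial span
#' whose linear fit keeps R^2 >= 0.98 — the largest time over which product
#' formation is still proportional to incubation time; a fixed window (in
#' minutes) can be forced instead.
#'
#' @param tc A [timecourse()].
#' @param product Product name; defaults to the only product present.
#' @param window Optional fixed window end, minutes.
#' @param r2_min Linearity criterion for the automatic window.
#' @return An object of class `formation_rate_fit`: `rate` (uM/min),
#'   `window_end` (minutes), `r_squared`, `n_points`, `flags`.
#' @export
formation_rate <- function(tc, product = NULL, window = NULL, r2_min = 0.98) {
  product <- product %||% unique(tc$product)[1]
  d <- tc[tc$product == product, ]
  if (nrow(d) < 2) stop("need at least 2 points", call. = FALSE)
  flags <- character()
  if (!is.null(window)) {
    d <- d[d$time_min <= window + 1e-9, ]
    k <- nrow(d)
  } else if (nrow(d) == 2) {
    k <- 2L
  } else {
    k <- linear_window(d$time_min, d$conc_uM, r2_min)
  }
  if (k < 3) {
    flags <- c(flags, "insufficient degrees of freedom for fit diagnostics")
    warning("formation rate from only ", k, " points: no residual degrees ",
            "of freedom", call. = FALSE)
  }
  f <- stats::lm(conc_uM ~ time_min, data = d[1:k, ])
  rate <- unname(stats::coef(f)[["time_min"]])
  se <- tryCatch(
    suppressWarnings(summary(f)$coefficients["time_min", "Std. Error"]),
    error = function(e) NA_real_)
  if (is.finite(se) && rate < -2 * se) {
    flags <- c(flags, "negative fitted slope beyond noise")
    warning("negative formation rate beyond noise for ", product, call. = FALSE)
  }
  r2 <- suppressWarnings(summary(f)$r.squared)
  structure(list(
    product = product, rate = rate, se = se,
    window_end = d$time_min[k], r_squared = if (is.nan(r2)) 1 else r2,
    n_points = k, flags = flags, fit = f
  ), class = "formation_rate_fit")
}

#' @export
print.formation_rate_fit <- function(x, ...) {
  cat(x$product, ": ", signif(x$rate, 4), " uM/min over 0-", x$window_end,
      " min (R^2 = ", round(x$r_squared, 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname formation_rate
#' @param x A `formation_rate_fit`.
#' @param ... Unused.
#' @method tidy formation_rate_fit
#' @export
tidy.formation_rate_fit <- function(x, ...) {
  tibble::tibble(product = x$product, rate = x$rate, std.error = x$se,
                 window_end = x$window_end)
}

#' @rdname formation_rate
#' @method glance formation_rate_fit
#' @export
glance.formation_rate_fit <- function(x, ...) {
  tibble::tibble(product = x$product, rate = x$rate, window_end = x$window_end,
                 r_squared = x$r_squared, n_points = x$n_points,
                 flagged = length(x$flags) > 0)
}

#' Molar yield and product distribution at a time point
#'
#' Yield is total product over starting substrate
#' (`100 * sum_i [product_i](t) / substrate_uM`, percent); the distribution
#' gives each product's share of the product pool
#' (`100 * [product_i](t) / sum_j [product_j](t)`), which sums to exactly
#' 100. Concentrations are linearly interpolated to `t` when it is not
#' sampled.
#'
#' @param tc A [timecourse()].
#' @param t Evaluation time, minutes (assay convention: 120).
#' @return A list with `total_yield_percent` and `distribution` (tibble of
#'   `product`, `conc_uM`, `percent_of_products`).
#' @export
yield_and_distribution <- function(tc, t = 120) {
  s0 <- attr(tc, "substrate_uM")
  conc <- dplyr::summarise(
    dplyr::group_by(tc, .data$product),
    conc_uM = {
      if (t < min(.data$time_min) || t > max(.data$time_min)) {
        stop("t = ", t, " min outside the sampled range", call. = FALSE)
      }
      stats::approx(.data$time_min, .data$conc_uM, xout = t)$y
    },
    .groups = "drop"
  )
  total <- sum(conc$conc_uM)
  if (total <= 0) {
    stop("no product formed at t = ", t, " min: distribution undefined",
         call. = FALSE)
  }
  conc$percent_of_products <- 100 * conc$conc_uM / total
  list(
    total_yield_percent = 100 * total / s0,
    distribution = conc
  )
}

#' Distribution estimated from formation-rate ratios
#'
#' Alternative distribution estimator: each product's share of the summed
#' initial formation rates. Differs from the per-timepoint concentration
#' share when curves leave the linear regime at different times.
#'
#' @param tc A [timecourse()].
#' @param ... Passed to [formation_rate()].
#' @return A tibble of `product`, `rate`, `percent_of_products`.
#' @export
rate_distribution <- function(tc, ...) {
  prods <- unique(tc$product)
  rates <- unname(vapply(prods, function(p) formation_rate(tc, p, ...)$rate,
                         numeric(1)))
  tibble::tibble(product = prods, rate = rates,
                 percent_of_products = 100 * rates / sum(rates))
}
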
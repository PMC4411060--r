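#' Assemble a DPPH kinetic trace
#'
#' One scavenging reaction followed at 515 nm: absorbance versus time for a
#' given antioxidant-to-radical molar ratio. Radical concentrations are
#' recovered from Beer-Lambert as `A / (extinction * path)`; the default
#' extinction is the 515 nm value for the radical in methanol
#' (12 mM^-1 cm^-1).
#'
#' @param times Sampling times, minutes, strictly increasing.
#' @param absorbance Absorbance at 515 nm, AU, non-negative.
#' @param ratio Antioxidant / radical molar ratio (uM/uM).
#' @param dpph_initial Initial radical concentration, uM.
#' @param extinction Molar extinction at 515 nm, mM^-1 cm^-1.
#' @param path_length Optical path, cm.
#' @param replicate Replicate identifier.
#' @return A tibble of class `dpph_trace` with per-point radical
#'   concentrations (`dpph_uM`).
#' @export
dpph_trace <- function(times, absorbance, ratio = NA_real_,
                       dpph_initial = 100, extinction = 12, path_length = 1,
                       replicate = 1L) {
  stopifnot(length(times) == length(absorbance))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (dpph_initial <= 0) stop("dpph_initial must be > 0", call. = FALSE)
  out <- tibble::tibble(
    time_min = as.numeric(times), abs515 = as.numeric(absorbance),
    ratio = ratio, replicate = replicate,
    dpph_uM = 1000 * as.numeric(absorbance) / (extinction * path_length)
  )
  attr(out, "dpph_initial") <- dpph_initial
  attr(out, "extinction") <- extinction
  attr(out, "path_length") <- path_length
  class(out) <- c("dpph_trace", class(out))
  out
}

#' Percent of radical reduced at a time point
#'
#' `%red = (1 - [DPPH](t_end) / [DPPH](0)) * 100`, with the radical
#' concentration read from the trace (linear interpolation when `t_end`
#' falls between samples). Because concentration is absorbance divided by a
#' constant, the result is invariant to joint rescaling of absorbance and
#' extinction.
#'
#' @param trace A [dpph_trace()] (or data frame with `time_min`, `abs515`).
#' @param t_end End time, minutes (assay convention: 30).
#' @return Percent reduction (can be negative for noisy null traces).
#' @export
percent_dpph_reduced <- function(trace, t_end = 30) {
  tm <- trace$time_min
  if (t_end < tm[1]) stop("t_end precedes the first sample", call. = FALSE)
  if (t_end > tm[length(tm)]) stop("t_end beyond the last sample", call. = FALSE)
  a0 <- trace$abs515[1]
  at <- stats::approx(tm, trace$abs515, xout = t_end)$y
  (1 - at / a0) * 100
}

#' Assemble a dose-response table
#'
#' @param ratios Antioxidant / radical molar ratios (uM/uM).
#' @param percent_reduced Raw percent reduction values (retained as given).
#' @param replicate Replicate identifiers.
#' @return A tibble of class `dpph_response` with a `percent_clipped` column
#'   (negatives from noise clipped to 0, capped at 100).
#' @export
dpph_response <- function(ratios, percent_reduced, replicate = 1L) {
  out <- tibble::tibble(
    ratio = as.numeric(ratios),
    percent_reduced = as.numeric(percent_reduced),
    percent_clipped = pmin(100, pmax(0, as.numeric(percent_reduced))),
    replicate = replicate
  )
  class(out) <- c("dpph_response", class(out))
  out
}

#' Fit the half-reduction ratio (EC50) from a dose-response curve
#'
#' Nonlinear least squares of the saturating Hill model
#' `%red = 100 * r^n / (EC50^n + r^n)` (floor 0, ceiling 100, exponent
#' bounded in 0.5-6), so EC50 is the ratio at which the fitted curve crosses
#' 50 percent. When no observed response reaches 50 percent the fit is
#' flagged as an extrapolation rather than silently reported.
#'
#' @param data A [dpph_response()] or data frame with `ratio` and
#'   `percent_reduced` columns.
#' @return An object of class `ec50_fit` with elements `ec50`, `hill_n`,
#'   `sse`, `n_obs`, `extrapolated`, `fit` and the data.
#' @export
fit_ec50 <- function(data) {
  stopifnot(all(c("ratio", "percent_reduced") %in% names(data)))
  df <- tibble::tibble(r = data$ratio,
                       y = pmin(100, pmax(0, data$percent_reduced)))
  if (length(unique(df$r)) < 4) {
    stop("need at least 4 distinct ratios to fit an EC50", call. = FALSE)
  }
  extrapolated <- max(df$y) < 50
  if (extrapolated) {
    warning("no response reaches 50%: EC50 is an extrapolation", call. = FALSE)
  }
  start_ec <- stats::approx(df$y + 1e-9 * seq_along(df$y), df$r, xout = 50,
                            rule = 2, ties = mean)$y
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 100 * r^n / (ec50^n + r^n), data = df,
      start = list(ec50 = max(start_ec, 1e-6), n = 1),
      lower = c(1e-9, 0.5), upper = c(Inf, 6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("EC50 fit did not converge: ", conditionMessage(e),
           " (n = ", nrow(df), ", max response = ", round(max(df$y), 2), "%)",
           call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  structure(list(
    ec50 = unname(cf[["ec50"]]), hill_n = unname(cf[["n"]]),
    sse = sum(stats::resid(fit)^2), n_obs = nrow(df),
    extrapolated = extrapolated, fit = fit, data = tibble::as_tibble(data)
  ), class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat("EC50 fit: EC50 =", signif(x$ec50, 4), "uM/uM, Hill n =",
      signif(x$hill_n, 3), if (x$extrapolated) "(extrapolated!)", "\n")
  invisible(x)
}

#' @rdname fit_ec50
#' @param x An `ec50_fit`.
#' @param ... Unused.
#' @method tidy ec50_fit
#' @export
tidy.ec50_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ec50", "hill_n"),
    estimate = c(x$ec50, x$hill_n),
    std.error = tryCatch(sqrt(diag(stats::vcov(x$fit))),
                         error = function(e) rep(NA_real_, 2))
  )
}

#' @rdname fit_ec50
#' @method glance ec50_fit
#' @export
glance.ec50_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, hill_n = x$hill_n, sse = x$sse,
                 n_obs = x$n_obs, extrapolated = x$extrapolated)
}

#' Time to a stable absorbance plateau (TEC50)
#'
#' Fits an exponential decay to plateau,
#' `A(t) = Af + (A0 - Af) * exp(-t / tau)`, to the trace recorded at the
#' EC50 ratio and reports the first time at which the remaining excess
#' absorbance falls within `plateau_tol` of the fitted asymptote, i.e.
#' `tau * log(1 / plateau_tol)`, snapped to the trace's sampling resolution.
#' Traces that do not decay to a plateau (exponential fit no better than a
#' straight line, or rising absorbance) are an error.
#'
#' @param trace A [dpph_trace()] (>= 3 points).
#' @param plateau_tol Stability criterion as a fraction of the total
#'   absorbance drop (default 0.01).
#' @return An object of class `tec50_fit` with elements `tec50` (minutes),
#'   `tau`, `a0`, `a_plateau`, `sse`, `fit`.
#' @export
tec50 <- function(trace, plateau_tol = 0.01) {
  tm <- trace$time_min
  ab <- trace$abs515
  if (length(tm) < 3) stop("need at least 3 points", call. = FALSE)
  resol <- stats::median(diff(tm))
  if (ab[length(ab)] > ab[1] + max(1e-12, 1e-6 * ab[1])) {
    stop("no plateau: absorbance increases over the trace", call. = FALSE)
  }
  drop <- ab[1] - min(ab)
  if (drop <= max(1e-12, 1e-6 * ab[1])) {
    # already stable
    out <- list(tec50 = tm[1], tau = 0, a0 = ab[1], a_plateau = ab[1],
                sse = 0, fit = NULL)
    class(out) <- "tec50_fit"
    return(out)
  }
  df <- data.frame(t = tm, a = ab)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ af + (a0 - af) * exp(-t / tau), data = df,
      start = list(af = min(ab), a0 = ab[1],
                   tau = max(resol, diff(range(tm)) / 4)),
      lower = c(0, 0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  lin_sse <- sum(stats::resid(stats::lm(a ~ t, df))^2)
  if (is.null(fit) || sum(stats::resid(fit)^2) > lin_sse + 1e-12) {
    stop("no plateau detected: exponential-to-plateau fit is no better ",
         "than a straight line", call. = FALSE)
  }
  cf <- stats::coef(fit)
  t_star <- cf[["tau"]] * log(1 / plateau_tol)
  out <- list(
    tec50 = round(t_star / resol) * resol,
    tau = cf[["tau"]], a0 = cf[["a0"]], a_plateau = cf[["af"]],
    sse = sum(stats::resid(fit)^2), fit = fit
  )
  class(out) <- "tec50_fit"
  out
}

#' @export
print.tec50_fit <- function(x, ...) {
  cat("TEC50 =", x$tec50, "min (tau =", signif(x$tau, 4), "min)\n")
  invisible(x)
}

#' @rdname tec50
#' @param x A `tec50_fit`.
#' @param ... Unused.
#' @method glance tec50_fit
#' @export
glance.tec50_fit <- function(x, ...) {
  tibble::tibble(tec50 = x$tec50, tau = x$tau, a0 = x$a0,
                 a_plateau = x$a_plateau, sse = x$sse)
}

#' Antiradical efficiency
#'
#' `AE = 1 / (EC50 * TEC50)`: a potency-speed composite in
#' `(uM/uM * min)^-1`. Larger is a stronger, faster scavenger.
#'
#' @param ec50 Half-reduction molar ratio, uM/uM (> 0).
#' @param tec50 Plateau time at that ratio, minutes (> 0).
#' @return AE value(s).
#' @export
antiradical_efficiency <- function(ec50, tec50) {
  if (any(!is.finite(ec50)) || any(!is.finite(tec50)) ||
      any(ec50 <= 0) || any(tec50 <= 0)) {
    stop("ec50 and tec50 must be positive and finite", call. = FALSE)
  }
  1 / (ec50 * tec50)
}

#' Summarize an antioxidant characterization
#'
#' Combines per-replicate EC50 and TEC50 values into the reported result.
#' AE is computed per replicate and averaged (`ae`), with the
#' mean-of-inputs convention `1 / (mean EC50 * mean TEC50)` also reported
#' (`ae_from_means`) since published tables are not always explicit about
#' which was used.
#'
#' @param ec50 Per-replicate EC50 values, uM/uM.
#' @param tec50 Per-replicate TEC50 values, minutes (recycled if scalar).
#' @return A one-row tibble: `ec50`, `tec50`, `ae`, `ae_from_means`,
#'   `n_replicates`.
#' @export
antioxidant_result <- function(ec50, tec50) {
  n <- max(length(ec50), length(tec50))
  ec50 <- rep_len(ec50, n)
  tec50 <- rep_len(tec50, n)
  ae_rep <- mean(antiradical_efficiency(ec50, tec50))
  ae_mean <- antiradical_efficiency(mean(ec50), mean(tec50))
  tibble::tibble(
    ec50 = mean(ec50), tec50 = mean(tec50),
    ae = ae_rep, ae_from_means = ae_mean,
    n_replicates = n
  )
}
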
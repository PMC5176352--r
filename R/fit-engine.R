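# Shared bounded multi-start least-squares machinery.
#
# All nonlinear fits in the package go through .ls_multistart: box-bounded
# L-BFGS-B on a transformed parameter scale (concentration-like parameters
# are fitted as log10), started from a deterministic grid, keeping the
# lowest SS and breaking exact ties by the lexicographically smallest
# parameter vector so results are bit-reproducible.

.lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0L && d[i[1L]] < 0
}

.ls_multistart <- function(obj, starts, lower, upper, maxit = 2000L) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(starts[i, ], lower), upper)
    f <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$value)) next
    if (is.null(best) ||
        f$value < best$value * (1 - 1e-12) - 1e-300 ||
        (abs(f$value - best$value) <= 1e-12 * max(1, best$value) &&
         .lex_less(f$par, best$par))) {
      best <- f
    }
  }
  if (is.null(best)) return(NULL)
  # polish from the winning start; a restart that cannot improve the SS
  # any further is stationary, even if the line search ended abnormally
  for (k in 1:3) {
    f <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$value) || f$value > best$value) break
    improved <- (best$value - f$value) > 1e-12 * max(1, best$value)
    best <- f
    if (!improved) {
      best$convergence <- 0L
      break
    }
    if (best$convergence == 0L) break
  }
  best
}

.new_fit_result <- function(params, fixed_mask, y, fitted, n_free,
                            converged, n_starts, predict_fn,
                            flags = list()) {
  residuals <- y - fitted
  structure(
    list(params = params, fixed_mask = fixed_mask,
         SS = sum(residuals^2), n_points = length(y),
         n_free_params = n_free, converged = converged,
         n_starts = n_starts, residuals = residuals, fitted = fitted,
         observed = y, predict = predict_fn, flags = flags),
    class = "p2x7_fit")
}

#' @export
print.p2x7_fit <- function(x, ...) {
  cat("<p2x7_fit> ", if (x$converged) "converged" else "NOT converged",
      sprintf(" | SS = %.4g over %d points, %d free parameter(s)\n",
              x$SS, x$n_points, x$n_free_params), sep = "")
  p <- x$params
  if (inherits(p, "hill_params")) {
    cat(sprintf("  Hill (%s): midpoint = %.4g M, slope = %.3g, top = %.3g, bottom = %.3g\n",
                p$direction, p$midpoint, p$slope, p$top, p$bottom))
  } else if (inherits(p, "mechanism_params")) {
    print(p)
  }
  if (length(x$flags)) {
    on <- names(x$flags)[vapply(x$flags, isTRUE, logical(1))]
    if (length(on)) cat("  flags:", paste(on, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Empirical Hill-curve parameters
#'
#' Parameters of the four-parameter logistic (Hill) curve used for
#' empirical EC50/IC50 estimation: activation
#' \eqn{R = bottom + (top-bottom)/(1+(mid/x)^h)} and inhibition
#' \eqn{R = bottom + (top-bottom)/(1+(x/mid)^h)}.
#'
#' @param midpoint EC50 (activation) or IC50 (inhibition), molar.
#' @param slope Hill coefficient, > 0.
#' @param top,bottom Asymptotic response levels (`top >= bottom`).
#' @param direction `"activation"` or `"inhibition"`.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(midpoint, slope, top = 1, bottom = 0,
                        direction = c("activation", "inhibition")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(midpoint), midpoint > 0, is.finite(slope), slope > 0,
            is.finite(top), is.finite(bottom), top >= bottom)
  structure(list(midpoint = midpoint, slope = slope, top = top,
                 bottom = bottom, direction = direction),
            class = "hill_params")
}

#' Evaluate a Hill curve
#'
#' @param x Concentrations, molar (zeros allowed; they map to the
#'   appropriate asymptote).
#' @param p A [hill_params()] object.
#' @return Responses.
#' @export
hill_response <- function(x, p) {
  stopifnot(inherits(p, "hill_params"))
  .check_conc(x, "x")
  lr <- p$slope * (log(x) - log(p$midpoint))   # log((x/mid)^h)
  if (p$direction == "activation") {
    frac <- 1 / (1 + exp(-lr))                 # x=0 -> 0
  } else {
    frac <- 1 / (1 + exp(lr))                  # x=0 -> 1
  }
  p$bottom + (p$top - p$bottom) * frac
}

#' Fit the Hill equation to a dose-response slice
#'
#' Bounded multi-start least squares for the four-parameter Hill curve.
#' Midpoint and slope are optimized on log10 scale; the default 8 starts
#' place candidate midpoints on a log grid spanning the observed
#' concentration range. Flat data converge to a near-zero amplitude and
#' are flagged rather than raising.
#'
#' @param conc Concentrations, molar.
#' @param response Observed responses.
#' @param direction `"activation"` (midpoint is an EC50) or `"inhibition"`
#'   (midpoint is an IC50).
#' @param n_starts Number of multi-start midpoints (default 8).
#' @param slope_bounds Allowed Hill-slope range.
#' @param fix Named list clamping any of `slope`, `top`, `bottom` at given
#'   values (e.g. `list(slope = 1.3)` to impose parallelism across curves,
#'   as Schild analysis assumes); clamped parameters do not count as free.
#' @return A `p2x7_fit` whose `$params` is a [hill_params()]; flags
#'   `zero_amplitude` when the fitted span is indistinguishable from the
#'   residual noise.
#' @export
fit_hill <- function(conc, response, direction = c("activation",
                                                   "inhibition"),
                     n_starts = 8L, slope_bounds = c(0.1, 10),
                     fix = list()) {
  direction <- match.arg(direction)
  stopifnot(length(conc) == length(response), all(is.finite(response)))
  .check_conc(conc, "conc")
  if (!all(names(fix) %in% c("slope", "top", "bottom")))
    stop("`fix` may clamp only slope, top, bottom", call. = FALSE)
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations for a Hill fit",
         call. = FALSE)
  xpos <- conc[conc > 0]
  lmid_rng <- c(log10(min(xpos)) - 2, log10(max(xpos)) + 2)
  amp <- max(diff(range(response)), 1e-6)
  free <- c("midpoint", setdiff(c("slope", "top", "bottom"), names(fix)))
  lo_all <- c(midpoint = lmid_rng[1], slope = log10(slope_bounds[1]),
              top = min(response) - amp, bottom = min(response) - amp)
  hi_all <- c(midpoint = lmid_rng[2], slope = log10(slope_bounds[2]),
              top = max(response) + amp, bottom = max(response) + amp)
  mk <- function(th) {
    v <- list(slope = if ("slope" %in% names(fix)) fix$slope
                      else 10^th[["slope"]],
              top = if ("top" %in% names(fix)) fix$top else th[["top"]],
              bottom = if ("bottom" %in% names(fix)) fix$bottom
                       else th[["bottom"]])
    hill_params(10^th[["midpoint"]], v$slope, v$top, v$bottom, direction)
  }
  obj <- function(th) {
    tp <- if ("top" %in% names(fix)) fix$top else th[["top"]]
    bt <- if ("bottom" %in% names(fix)) fix$bottom else th[["bottom"]]
    if (tp < bt) return(1e6 * (1 + bt - tp))  # keep top >= bottom
    sum((response - hill_response(conc, mk(th)))^2)
  }
  mids <- seq(log10(min(xpos)), log10(max(xpos)), length.out = n_starts)
  start_all <- cbind(midpoint = mids, slope = 0, top = max(response),
                     bottom = min(response))
  starts <- start_all[, free, drop = FALSE]
  best <- .ls_multistart(obj, starts, lo_all[free], hi_all[free])
  if (is.null(best))
    stop("Hill fit failed to converge from any start", call. = FALSE)
  p <- mk(best$par)
  fitted <- hill_response(conc, p)
  res <- response - fitted
  zero_amp <- abs(p$top - p$bottom) <=
    max(2 * stats::sd(res), 1e-10 * max(1, abs(p$top)))
  .new_fit_result(
    params = p,
    fixed_mask = c(midpoint = FALSE, slope = "slope" %in% names(fix),
                   top = "top" %in% names(fix),
                   bottom = "bottom" %in% names(fix)),
    y = response, fitted = fitted, n_free = length(free),
    converged = best$convergence == 0 && !zero_amp,
    n_starts = nrow(starts),
    predict_fn = function(x) hill_response(x, p),
    flags = list(zero_amplitude = zero_amp))
}
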
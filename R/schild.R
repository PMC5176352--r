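#' Dose ratio
#'
#' Ratio of the agonist EC50 in the presence of antagonist to the control
#' EC50. Under simple competitive antagonism the ratio obeys the Schild
#' relation r = 1 + B/KB.
#'
#' @param EC50_prime EC50 with antagonist present, molar.
#' @param EC50 Control EC50, molar.
#' @return Dimensionless dose ratio(s).
#' @export
dose_ratio <- function(EC50_prime, EC50) {
  if (any(!is.finite(EC50_prime)) || any(!is.finite(EC50)) ||
      any(EC50_prime <= 0) || any(EC50 <= 0))
    stop("EC50 values must be finite and positive", call. = FALSE)
  EC50_prime / EC50
}

#' Assemble Schild points from per-concentration Hill fits
#'
#' One point per antagonist concentration: the dose ratio r relative to the
#' control EC50, with points whose r exceeds 1 by less than `eps` marked
#' unusable (log10(r - 1) is undefined or numerically explosive as r
#' approaches 1) and excluded from regression.
#'
#' @param per_B_hill List of converged activation-direction `p2x7_fit`
#'   objects, one per non-zero antagonist concentration.
#' @param B Antagonist concentrations, molar, parallel to `per_B_hill`.
#' @param control_EC50 Antagonist-free EC50, molar.
#' @param eps Usability threshold on r - 1 (default 0.05).
#' @return Data frame with columns `B_M`, `EC50_prime_M`, `r`, `usable`.
#' @export
schild_points <- function(per_B_hill, B, control_EC50, eps = 0.05) {
  stopifnot(is.list(per_B_hill), length(per_B_hill) == length(B),
            length(control_EC50) == 1L, control_EC50 > 0)
  if (any(B <= 0))
    stop("Schild points require non-zero antagonist concentrations",
         call. = FALSE)
  ok <- vapply(per_B_hill, function(f)
    inherits(f, "p2x7_fit") && inherits(f$params, "hill_params") &&
      f$converged, logical(1))
  if (!all(ok))
    stop("all per-concentration Hill fits must have converged",
         call. = FALSE)
  ec50p <- vapply(per_B_hill, function(f) f$params$midpoint, 0)
  r <- dose_ratio(ec50p, control_EC50)
  usable <- (r - 1) > eps
  if (any(!usable))
    warning(sum(!usable), " Schild point(s) with r - 1 <= ", eps,
            " marked unusable and excluded from regression",
            call. = FALSE)
  data.frame(B_M = B, EC50_prime_M = ec50p, r = r, usable = usable)
}

#' Schild regression with a nonlinearity diagnostic
#'
#' OLS of log10(r - 1) on log10(B) over the usable points. The pA2 is the
#' x-intercept of the fitted line expressed as -log10 molar; for an ideal
#' competitive antagonist the slope is 1 and pA2 = -log10(KB). Curvature is
#' probed by refitting with a quadratic term in log10(B) and reporting the
#' t-test p-value on that coefficient: systematic downward bending at high
#' antagonist (a plateauing dose ratio) is the classical signature of
#' non-competitive action.
#'
#' @param points Data frame from [schild_points()].
#' @return Object of class `schild_result`: `slope`, `intercept`, `pA2`,
#'   `curvature_p` (`NA` when fewer than 4 usable points leave no residual
#'   df for the quadratic), `n_points_used`.
#' @export
schild_regression <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("B_M", "r", "usable") %in% names(points)))
  use <- points[points$usable, , drop = FALSE]
  if (nrow(use) < 2L)
    stop("need at least 2 usable Schild points for a regression",
         call. = FALSE)
  x <- log10(use$B_M); y <- log10(use$r - 1)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  curvature_p <- NA_real_
  if (nrow(use) >= 4L) {
    qfit <- stats::lm(y ~ x + I(x^2))
    qs <- suppressWarnings(summary(qfit))
    qc <- stats::coef(qs)["I(x^2)", ]
    curvature_p <- qc[["Pr(>|t|)"]]
    # an (almost) perfect quadratic fit makes the t-test degenerate:
    # exactly linear points carry no curvature (p = 1); exactly curved
    # points carry certain curvature (p = 0)
    if (!is.finite(curvature_p) ||
        qs$sigma < 1e-8 * max(abs(y), 1e-12)) {
      curvature_p <- if (abs(qc[["Estimate"]]) <
                           1e-6 * max(abs(slope), 1e-12)) 1 else 0
    }
  }
  structure(
    list(slope = slope, intercept = intercept,
         pA2 = intercept / slope, curvature_p = curvature_p,
         n_points_used = nrow(use)),
    class = "schild_result")
}

#' @export
print.schild_result <- function(x, ...) {
  cat("<schild_result>\n")
  cat(sprintf("  slope = %.4f, pA2 = %.3f (%d points)\n",
              x$slope, x$pA2, x$n_points_used))
  cat(sprintf("  curvature p = %s\n",
              if (is.na(x$curvature_p)) "NA (too few points)"
              else signif(x$curvature_p, 3)))
  invisible(x)
}

#' Full Schild analysis of a dose-response table
#'
#' Splits the table by antagonist concentration, fits each slice with the
#' Hill equation (free top, so each curve is normalized to its own fitted
#' maximum), derives dose ratios against the antagonist-free slice, and
#' regresses. This is the pipeline used to ask whether an antagonist's
#' Schild plot is the straight unit-slope line competitive antagonism
#' predicts.
#'
#' @param points Data frame with `agonist_conc_M`, `antagonist_conc_M`,
#'   `response` (a zero-antagonist slice must be present).
#' @param eps Usability threshold passed to [schild_points()].
#' @param share_slope Fit the antagonist slices with the Hill slope
#'   clamped at the control curve's fitted slope (default TRUE). Schild
#'   analysis presumes parallel dose-response curves, and sharing the
#'   slope removes the midpoint-slope covariance that otherwise makes
#'   EC50' estimates of strongly suppressed curves erratic.
#' @return List with `points` (the Schild point table), `result` (a
#'   `schild_result`), and `control_EC50`.
#' @export
schild_analysis <- function(points, eps = 0.05, share_slope = TRUE) {
  stopifnot(is.data.frame(points),
            all(c("agonist_conc_M", "antagonist_conc_M",
                  "response") %in% names(points)))
  Bs <- sort(unique(points$antagonist_conc_M))
  if (!0 %in% Bs)
    stop("an antagonist-free slice is required for the control EC50",
         call. = FALSE)
  fit_slice <- function(b, fix = list()) {
    d <- points[points$antagonist_conc_M == b, , drop = FALSE]
    tryCatch(fit_hill(d$agonist_conc_M, d$response, "activation",
                      fix = fix),
             error = function(e) NULL)
  }
  ctrl <- fit_slice(0)
  if (is.null(ctrl) || !ctrl$converged)
    stop("control (antagonist-free) Hill fit failed", call. = FALSE)
  slice_fix <- if (share_slope) list(slope = ctrl$params$slope)
               else list()
  Bnz <- Bs[Bs > 0]
  fits <- lapply(Bnz, fit_slice, fix = slice_fix)
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (any(!ok))
    warning(sum(!ok), " antagonist concentration(s) dropped: the ",
            "dose-response slice is too suppressed for a usable Hill fit",
            call. = FALSE)
  if (!any(ok))
    stop("no antagonist slice yielded a usable Hill fit", call. = FALSE)
  sp <- schild_points(fits[ok], Bnz[ok], ctrl$params$midpoint, eps = eps)
  list(points = sp, result = schild_regression(sp),
       control_EC50 = ctrl$params$midpoint)
}
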
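#' Goodness of fit: SS and R-squared
#'
#' @param fit A converged `p2x7_fit`.
#' @param response Observed responses; defaults to those stored in the fit.
#' @return List with `SS` and `R2` (`R2` is `NA` with a warning when the
#'   responses have zero variance).
#' @export
goodness <- function(fit, response = NULL) {
  stopifnot(inherits(fit, "p2x7_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(response)) response <- fit$observed
  SS <- sum((response - fit$fitted)^2)
  tss <- sum((response - mean(response))^2)
  if (tss == 0) {
    warning("zero response variance; R-squared undefined", call. = FALSE)
    return(list(SS = SS, R2 = NA_real_))
  }
  list(SS = SS, R2 = 1 - SS / tss)
}

#' Extra-sum-of-squares F-test between mechanism fits
#'
#' Compares the competitive (simpler; KA, tau, KB = 3 parameters across the
#' two stages) and non-competitive (richer; KA, tau, n, KB = 4 with Emax
#' fixed) fits on the same dose-response table:
#' \deqn{F = \frac{(SS_s - SS_r)/(p_r - p_s)}{SS_r/(N - p_r)},}
#' with the upper-tail p-value from the F distribution. If the simpler
#' model fits at least as well, F is clamped to 0 and p = 1. The two
#' mechanisms are not strictly nested; the comparison is reported with that
#' caveat attached.
#'
#' @param simpler Two-stage competitive `p2x7_fit`.
#' @param richer Two-stage non-competitive `p2x7_fit` on the identical
#'   points.
#' @return An object of class `mechanism_comparison` with both SS and R2
#'   values, F, p, degrees of freedom, and a `caveat` string.
#' @export
f_test <- function(simpler, richer) {
  stopifnot(inherits(simpler, "p2x7_fit"), inherits(richer, "p2x7_fit"))
  if (simpler$n_points != richer$n_points ||
      !isTRUE(all.equal(sort(simpler$observed), sort(richer$observed))))
    stop("fits must be on the identical point set", call. = FALSE)
  if (richer$n_free_params <= simpler$n_free_params)
    stop("`richer` must have more fitted parameters than `simpler`",
         call. = FALSE)
  N <- richer$n_points
  df_num <- richer$n_free_params - simpler$n_free_params
  df_den <- N - richer$n_free_params
  if (df_den < 1L) stop("no residual degrees of freedom", call. = FALSE)
  SS_s <- simpler$SS; SS_r <- richer$SS
  if (SS_s > SS_r) {
    F <- ((SS_s - SS_r) / df_num) / (SS_r / df_den)
    p <- stats::pf(F, df_num, df_den, lower.tail = FALSE)
  } else {
    # richer model gained nothing; clamp
    F <- 0; p <- 1
  }
  g_s <- goodness(simpler); g_r <- goodness(richer)
  structure(
    list(SS_competitive = SS_s, SS_noncompetitive = SS_r,
         R2_competitive = g_s$R2, R2_noncompetitive = g_r$R2,
         F = F, p = p, df_num = df_num, df_den = df_den,
         converged = c(competitive = simpler$converged,
                       noncompetitive = richer$converged),
         caveat = paste("competitive and non-competitive models are not",
                        "strictly nested; extra-SS F-test is heuristic")),
    class = "mechanism_comparison")
}

#' @export
print.mechanism_comparison <- function(x, ...) {
  cat("<mechanism_comparison>\n")
  cat(sprintf("  SS  competitive = %.4g   noncompetitive = %.4g\n",
              x$SS_competitive, x$SS_noncompetitive))
  cat(sprintf("  R2  competitive = %.4f   noncompetitive = %.4f\n",
              x$R2_competitive, x$R2_noncompetitive))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g -> %s\n", x$df_num, x$df_den,
              x$F, x$p, verdict(x)))
  invisible(x)
}

#' Mechanism verdict from a model comparison
#'
#' Declares the antagonist non-competitive when the richer model fits
#' significantly better (p < alpha and lower SS); competitive when the
#' competitive fit is not significantly worse; inconclusive when either
#' fit failed.
#'
#' @param cmp A `mechanism_comparison` from [f_test()].
#' @param alpha Significance level (default 0.05).
#' @return `"competitive"`, `"noncompetitive"`, or `"inconclusive"`.
#' @export
verdict <- function(cmp, alpha = 0.05) {
  stopifnot(inherits(cmp, "mechanism_comparison"),
            alpha > 0, alpha < 1)
  if (!all(cmp$converged)) return("inconclusive")
  if (cmp$p < alpha && cmp$SS_noncompetitive < cmp$SS_competitive)
    "noncompetitive"
  else
    "competitive"
}

#' Fit both mechanisms and compare them
#'
#' Runs the two-stage fit under each mechanism on the same dose-response
#' table, then the extra-SS F-test. Fit failures yield an `inconclusive`
#' verdict rather than an error, so simulation sweeps keep running.
#'
#' @param points Dose-response data frame (`agonist_conc_M`,
#'   `antagonist_conc_M`, `response`).
#' @param alpha Significance level for the verdict.
#' @return List with `competitive` and `noncompetitive` two-stage fits
#'   (either may be NULL on failure), the `comparison`, and the `verdict`.
#' @export
compare_mechanisms <- function(points, alpha = 0.05) {
  fit_c <- tryCatch(suppressWarnings(fit_two_stage(points, "competitive")),
                    error = function(e) NULL)
  fit_n <- tryCatch(suppressWarnings(fit_two_stage(points,
                                                   "noncompetitive")),
                    error = function(e) NULL)
  if (is.null(fit_c) || is.null(fit_n)) {
    return(list(competitive = fit_c, noncompetitive = fit_n,
                comparison = NULL, verdict = "inconclusive"))
  }
  cmp <- f_test(fit_c, fit_n)
  list(competitive = fit_c, noncompetitive = fit_n, comparison = cmp,
       verdict = verdict(cmp, alpha))
}
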
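#' Stage-1 fit: control (antagonist-free) dose-response
#'
#' Fits the chosen mechanism to the antagonist-free curve, mirroring the
#' two-stage procedure in which control data determine the agonist-side
#' parameters before any antagonist parameter is estimated. The
#' competitive model frees (KA, tau); the non-competitive model frees
#' (KA, tau, n) with Emax held at 1 for normalized responses (jointly
#' freeing Emax, tau and the plateau is not identifiable on normalized
#' data). Any parameter can instead be clamped via `fix`.
#'
#' @param points Data frame with columns `agonist_conc_M` and `response`
#'   (and, if present, `antagonist_conc_M`, which must be all zero).
#' @param kind `"competitive"` or `"noncompetitive"`.
#' @param fix Named list of parameters to hold fixed at given values,
#'   e.g. `list(tau = 10)`. `Emax` is fixed at 1 unless listed with
#'   another value or freed via `free_Emax = TRUE`.
#' @param free_Emax Free Emax in the non-competitive fit (default FALSE).
#' @param KA_bounds,tau_bounds Search bounds; the defaults cover any
#'   plausible agonist potency in molar units, and both can be rescaled
#'   when fitting data expressed in other units.
#' @return A `p2x7_fit` whose `$params` is a [mechanism_params()] with
#'   `KB` left at its inert default of 1 M.
#' @export
fit_control <- function(points, kind = c("competitive", "noncompetitive"),
                        fix = list(), free_Emax = FALSE,
                        KA_bounds = c(1e-9, 1e-1),
                        tau_bounds = c(1e-4, 1e4)) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(points),
            all(c("agonist_conc_M", "response") %in% names(points)))
  if ("antagonist_conc_M" %in% names(points) &&
      any(points$antagonist_conc_M != 0))
    stop("control fit requires antagonist-free data (all B = 0)",
         call. = FALSE)
  A <- points$agonist_conc_M; y <- points$response
  if (length(unique(A)) < 6L)
    stop("need at least 6 distinct agonist concentrations", call. = FALSE)

  # parameters on the optimizer scale: lKA = log10 KA, ltau = log10 tau,
  # n and Emax linear
  free <- c("KA", "tau", if (kind == "noncompetitive") "n",
            if (kind == "noncompetitive" && free_Emax) "Emax")
  free <- setdiff(free, names(fix))
  if (length(free) == 0L) stop("no free parameters left", call. = FALSE)
  base <- list(KA = 1e-4, tau = 1,
               n = if (kind == "competitive") 1 else 1.3,
               Emax = 1, alpha = 1)
  base[names(fix)] <- fix

  scale_in <- function(nm, v) if (nm %in% c("KA", "tau")) log10(v) else v
  scale_out <- function(nm, v) if (nm %in% c("KA", "tau")) 10^v else v
  bounds <- list(KA = log10(KA_bounds), tau = log10(tau_bounds),
                 n = c(0.3, 6), Emax = c(0.1, 10))
  lo <- vapply(free, function(nm) bounds[[nm]][1], 0)
  hi <- vapply(free, function(nm) bounds[[nm]][2], 0)

  mk <- function(th) {
    pl <- base
    for (i in seq_along(free)) pl[[free[i]]] <- scale_out(free[i], th[i])
    mechanism_params(kind, KA = pl$KA, KB = 1, tau = pl$tau,
                     n = if (kind == "competitive") 1 else pl$n,
                     Emax = if (kind == "competitive") 1 else pl$Emax,
                     alpha = pl$alpha)
  }
  obj <- function(th) sum((y - mechanism_response(A, 0, mk(th)))^2)

  apos <- A[A > 0]
  ka_grid <- seq(max(log10(min(apos)) - 1, bounds$KA[1]),
                 min(log10(max(apos)) + 1, bounds$KA[2]), length.out = 4)
  tau_grid <- c(-1.5, 0, 1.5)
  grid <- expand.grid(KA = ka_grid, tau = tau_grid, n = 1.3, Emax = 1)
  starts <- as.matrix(grid[, free, drop = FALSE])
  for (i in seq_along(free))
    if (free[i] %in% names(fix))
      starts[, i] <- scale_in(free[i], fix[[free[i]]])
  best <- .ls_multistart(obj, starts, lo, hi)
  if (is.null(best))
    stop("control fit failed to converge from any start", call. = FALSE)
  p <- mk(best$par)
  fitted <- mechanism_response(A, 0, p)
  all_names <- c("KA", "tau", "n", "Emax")
  .new_fit_result(
    params = p,
    fixed_mask = stats::setNames(!(all_names %in% free), all_names),
    y = y, fitted = fitted, n_free = length(free),
    converged = best$convergence == 0, n_starts = nrow(starts),
    predict_fn = function(Anew, Bnew = 0) mechanism_response(Anew, Bnew, p))
}

#' Stage-2 fit: antagonist dissociation constant
#'
#' Holding the stage-1 control parameters fixed, estimates KB as the only
#' free parameter (alpha stays clamped at 1) by minimizing the joint SS
#' over all points, including the antagonist-free curve. KB is searched on
#' log10 scale over [1e-12, 1e-2] M: a coarse 61-point grid locates the
#' basin and a golden-section refinement polishes it, which is immune to
#' the multi-modality a single gradient start can fall into.
#'
#' @param points Data frame with `agonist_conc_M`, `antagonist_conc_M`,
#'   `response`; at least 2 distinct non-zero antagonist concentrations.
#' @param control A converged stage-1 `p2x7_fit` from [fit_control()].
#' @param kind Mechanism kind; defaults to the control fit's kind.
#' @param KB_bounds Search range for KB, molar.
#' @return A `p2x7_fit` whose `$params` carries the full parameter set and
#'   whose SS/df span both stages (`n_free_params` counts the control's
#'   free parameters plus KB, the convention used by the F-test). Flags
#'   `no_inhibition_signal` when freeing KB barely improves on a
#'   no-antagonist-effect model.
#' @export
fit_KB <- function(points, control, kind = NULL,
                   KB_bounds = c(1e-12, 1e-2)) {
  stopifnot(is.data.frame(points),
            all(c("agonist_conc_M", "antagonist_conc_M",
                  "response") %in% names(points)),
            inherits(control, "p2x7_fit"),
            inherits(control$params, "mechanism_params"))
  if (!control$converged)
    stop("stage-1 control fit did not converge", call. = FALSE)
  if (is.null(kind)) kind <- control$params$kind
  Bnz <- unique(points$antagonist_conc_M[points$antagonist_conc_M > 0])
  if (length(Bnz) == 0L)
    stop("all antagonist concentrations are zero; nothing to fit",
         call. = FALSE)
  if (length(Bnz) < 2L)
    stop("need at least 2 distinct non-zero antagonist concentrations",
         call. = FALSE)
  A <- points$agonist_conc_M; B <- points$antagonist_conc_M
  y <- points$response
  cp <- control$params
  mk <- function(KB) mechanism_params(kind, KA = cp$KA, KB = KB,
                                      tau = cp$tau, n = cp$n,
                                      Emax = cp$Emax, alpha = cp$alpha)
  ss_at <- function(lKB) sum((y - mechanism_response(A, B, mk(10^lKB)))^2)
  lgrid <- seq(log10(KB_bounds[1]), log10(KB_bounds[2]), length.out = 61)
  ss_grid <- vapply(lgrid, ss_at, 0)
  i0 <- which.min(ss_grid)
  lw <- lgrid[max(1L, i0 - 1L)]; up <- lgrid[min(length(lgrid), i0 + 1L)]
  opt <- stats::optimize(ss_at, c(lw, up), tol = 1e-9)
  KB <- 10^opt$minimum
  p <- mk(KB)
  fitted <- mechanism_response(A, B, p)
  # SS if the antagonist had no effect at all (KB -> infinity); freeing KB
  # must buy a clearly significant improvement, else the data carry no
  # inhibition signal and the KB estimate is noise
  ss_null <- sum((y - mechanism_response(A, 0, cp))^2)
  ss_fit <- sum((y - fitted)^2)
  df_res <- length(y) - (control$n_free_params + 1L)
  f_gain <- if (ss_fit > 0) (ss_null - ss_fit) / (ss_fit / df_res)
            else Inf
  no_signal <- f_gain < stats::qf(0.99, 1, df_res)
  if (no_signal)
    warning("responses at the highest antagonist concentration are ",
            "indistinguishable from control; KB is unidentified",
            call. = FALSE)
  fm <- control$fixed_mask
  .new_fit_result(
    params = p,
    fixed_mask = c(fm, KB = FALSE, alpha = TRUE),
    y = y, fitted = fitted,
    n_free = control$n_free_params + 1L,
    converged = TRUE, n_starts = length(lgrid),
    predict_fn = function(Anew, Bnew) mechanism_response(Anew, Bnew, p),
    flags = list(no_inhibition_signal = no_signal))
}

#' Two-stage mechanism fit
#'
#' Convenience wrapper: stage-1 [fit_control()] on the antagonist-free
#' subset, then stage-2 [fit_KB()] on the full table.
#'
#' @inheritParams fit_KB
#' @param kind Mechanism kind.
#' @param ... Passed to [fit_control()].
#' @return The stage-2 `p2x7_fit`, with the stage-1 fit attached as
#'   `$control`.
#' @export
fit_two_stage <- function(points, kind = c("competitive",
                                           "noncompetitive"),
                          KB_bounds = c(1e-12, 1e-2), ...) {
  kind <- match.arg(kind)
  ctrl_pts <- points[points$antagonist_conc_M == 0, , drop = FALSE]
  ctrl <- fit_control(ctrl_pts, kind, ...)
  fit <- fit_KB(points, ctrl, kind, KB_bounds = KB_bounds)
  fit$control <- ctrl
  fit
}

#' Fold change in IC50 between two Hill fits
#'
#' Ratio of fitted midpoints, mutant over wildtype, for inhibition-direction
#' Hill fits; the readout used to rank binding-site mutations by their
#' effect on antagonist potency.
#'
#' @param mutant,wildtype Converged `p2x7_fit` objects from [fit_hill()]
#'   with `direction = "inhibition"`.
#' @return Dimensionless ratio.
#' @export
fold_change_ic50 <- function(mutant, wildtype) {
  for (f in list(mutant, wildtype)) {
    if (!inherits(f, "p2x7_fit") || !inherits(f$params, "hill_params"))
      stop("inputs must be Hill fits", call. = FALSE)
    if (!f$converged) stop("both fits must have converged", call. = FALSE)
    if (f$params$direction != "inhibition")
      stop("fold change is defined for inhibition fits (IC50s)",
           call. = FALSE)
  }
  mutant$params$midpoint / wildtype$params$midpoint
}
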
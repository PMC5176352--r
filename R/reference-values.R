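# Published P2X7 pharmacology values used to parameterize simulations.
# These are the study's fitted constants for BzATP-evoked, YO-PRO-1
# uptake-based dose responses of the panda P2X7 receptor, and serve as
# ground truth for the parameter-recovery suites.

#' Published operational-model parameters for P2X7 antagonism
#'
#' Control-curve parameters of the competitive model (KA = 28 uM,
#' tau = 0.031) and the non-competitive model (KA = 220 uM, tau = 10,
#' n = 2.6, Emax = 1, alpha = 1), with the per-antagonist KB fitted under
#' each mechanism.
#'
#' @param kind `"competitive"` or `"noncompetitive"`.
#' @param drug One of `"JNJ47965567"`, `"A804598"`, `"A740003"`,
#'   `"AZ10606120"`, `"GW791343"`, or `NULL` for the control parameters
#'   only (KB left at its inert default).
#' @return A [mechanism_params()] object.
#' @export
p2x7_published_params <- function(kind = c("competitive",
                                           "noncompetitive"),
                                  drug = NULL) {
  kind <- match.arg(kind)
  kb <- if (is.null(drug)) 1 else p2x7_published_kb(kind)[[drug]]
  if (is.null(kb) || is.na(kb)) stop("unknown drug: ", drug, call. = FALSE)
  if (kind == "competitive")
    mechanism_params("competitive", KA = 28e-6, KB = kb, tau = 0.031)
  else
    mechanism_params("noncompetitive", KA = 220e-6, KB = kb, tau = 10,
                     n = 2.6, Emax = 1, alpha = 1)
}

#' Published antagonist dissociation constants
#'
#' @param kind Mechanism under which the KB values were fitted.
#' @return Named numeric vector of KB values in molar.
#' @export
p2x7_published_kb <- function(kind = c("competitive", "noncompetitive")) {
  kind <- match.arg(kind)
  if (kind == "competitive")
    c(JNJ47965567 = 1.7e-9, A804598 = 15e-9, A740003 = 24e-9,
      AZ10606120 = 56e-9, GW791343 = 3.0e-6)
  else
    c(JNJ47965567 = 0.14e-6, A804598 = 0.57e-6, A740003 = 1.2e-6,
      AZ10606120 = 3.4e-6, GW791343 = 266e-6)
}

#' Published empirical potencies
#'
#' Hill-fit IC50 of each antagonist against dye uptake on the wildtype
#' receptor, and whole-cell ATP EC50s of the full-length and
#' crystallization constructs.
#'
#' @return List with `ic50_M` (named vector, molar) and `ec50_M`
#'   (named vector, molar).
#' @export
p2x7_published_potencies <- function() {
  list(ic50_M = c(A740003 = 69.3e-9, A804598 = 21.7e-9,
                  AZ10606120 = 231e-9, GW791343 = 8.9e-6,
                  JNJ47965567 = 11.9e-9),
       ec50_M = c(pdP2X7 = 122e-6, pdP2X7cryst = 40e-6))
}
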
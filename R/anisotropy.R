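#' Instrument G factor
#'
#' Grating correction factor for polarization-dependent detection
#' sensitivity, G = IHV/IHH, from the horizontally-excited intensity pair.
#'
#' @param IHV,IHH Fluorescence intensities with horizontal excitation and
#'   vertical/horizontal emission polarizers, arbitrary units.
#' @return G (dimensionless). A zero IHV is returned as G = 0 with a
#'   warning, since it usually means a detector problem.
#' @export
g_factor <- function(IHV, IHH) {
  if (any(!is.finite(IHV)) || any(!is.finite(IHH)) || any(IHV < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (any(IHH <= 0)) stop("IHH must be positive", call. = FALSE)
  if (any(IHV == 0))
    warning("IHV = 0 gives G = 0, which is physically suspicious",
            call. = FALSE)
  IHV / IHH
}

#' Fluorescence anisotropy
#'
#' Steady-state anisotropy from vertically-excited intensities with the G
#' correction: r = (IVV - G*IVH)/(IVV + 2*G*IVH). Binding of a small
#' fluorescent ligand to a large receptor slows its tumbling and raises r.
#'
#' @param IVV,IVH Intensities with vertical excitation and
#'   vertical/horizontal emission polarizers.
#' @param G Grating factor from [g_factor()].
#' @return Anisotropy r. Values outside the physically plausible band
#'   [-0.2, 0.4] are returned with a warning, not an error; deciding
#'   whether they are instrument artifacts is the user's call.
#' @export
anisotropy <- function(IVV, IVH, G) {
  if (any(!is.finite(IVV)) || any(!is.finite(IVH)) || any(!is.finite(G)) ||
      any(IVV < 0) || any(IVH < 0) || any(G <= 0))
    stop("intensities must be finite and non-negative and G positive",
         call. = FALSE)
  denom <- IVV + 2 * G * IVH
  if (any(denom <= 0)) stop("total intensity IVV + 2*G*IVH must be positive",
                            call. = FALSE)
  r <- (IVV - G * IVH) / denom
  if (any(r < -0.2 | r > 0.4))
    warning("anisotropy outside the plausible band [-0.2, 0.4]",
            call. = FALSE)
  r
}

#' Anisotropy per polarization record
#'
#' Computes the per-row G factor and anisotropy for a table of intensity
#' quadruples in the `polarization.csv` schema.
#'
#' @param records Data frame with columns `IVV`, `IVH`, `IHV`, `IHH` plus
#'   any titration metadata.
#' @return The input with `G` and `r` columns appended.
#' @export
anisotropy_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("IVV", "IVH", "IHV", "IHH") %in% names(records)))
  records$G <- g_factor(records$IHV, records$IHH)
  records$r <- anisotropy(records$IVV, records$IVH, records$G)
  records
}

#' Fit a protein-binding anisotropy titration
#'
#' Hill fit of anisotropy against receptor concentration, all four
#' parameters free: bottom is the anisotropy of the free fluorescent
#' ligand, top the bound-state anisotropy, the midpoint the apparent
#' dissociation constant of the labelled ligand.
#'
#' @param protein_conc_M Receptor concentrations, molar (>= 5 distinct).
#' @param r Measured anisotropy values.
#' @return A `p2x7_fit` with activation-direction [hill_params()].
#' @export
fit_binding_titration <- function(protein_conc_M, r) {
  if (length(unique(protein_conc_M)) < 5L)
    stop("need at least 5 protein concentrations", call. = FALSE)
  fit_hill(protein_conc_M, r, "activation")
}

#' Fit an ATP-competition anisotropy titration
#'
#' Decreasing Hill fit of anisotropy against unlabelled-ATP concentration:
#' displacement of the fluorescent ATP analogue from the receptor by excess
#' ATP collapses the anisotropy toward the free-ligand value, the behaviour
#' expected when the analogue occupies the orthosteric ATP site.
#'
#' @param atp_conc_M Competitor (unlabelled ATP) concentrations, molar.
#' @param r Measured anisotropy values.
#' @return A `p2x7_fit` with inhibition-direction [hill_params()]; its
#'   `$flags$monotone_decreasing` diagnostic reports whether the
#'   per-concentration means actually decrease, and `zero_amplitude`
#'   whether there is any titration signal at all.
#' @export
fit_competition <- function(atp_conc_M, r) {
  if (length(unique(atp_conc_M)) < 4L)
    stop("need at least 4 competitor concentrations", call. = FALSE)
  fit <- fit_hill(atp_conc_M, r, "inhibition")
  means <- tapply(r, atp_conc_M, mean)
  means <- means[order(as.numeric(names(means)))]
  fit$flags$monotone_decreasing <-
    unname(stats::cor(seq_along(means), as.numeric(means),
                      method = "spearman") < 0)
  fit
}
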
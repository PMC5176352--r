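#' Normalized channel activity around a reagent application
#'
#' Ratio of the current amplitude after to before application of the
#' thiol-reactive probe, computed per cell so absolute expression level
#' cancels.
#'
#' @param I_before,I_after Current amplitudes (same units, any scale).
#' @return Dimensionless ratio(s) I_after/I_before.
#' @export
normalized_activity <- function(I_before, I_after) {
  if (any(!is.finite(I_before)) || any(!is.finite(I_after)))
    stop("current amplitudes must be finite", call. = FALSE)
  if (any(I_before <= 0))
    stop("I_before must be positive for normalization", call. = FALSE)
  I_after / I_before
}

#' Rundown correction
#'
#' Divides an after/before activity ratio by the matching control ratio
#' measured without the reagent, so progressive current rundown between
#' the two measurements is removed: a cell whose ratio equals the control
#' ratio has experienced rundown only and maps to 1.
#'
#' @param ratio Activity ratio(s) from [normalized_activity()].
#' @param control_ratio Control (no-reagent) ratio(s); positive.
#' @return Rundown-corrected ratio(s).
#' @export
rundown_correct <- function(ratio, control_ratio) {
  if (any(!is.finite(ratio)) || any(!is.finite(control_ratio)))
    stop("ratios must be finite", call. = FALSE)
  if (any(control_ratio <= 0))
    stop("control ratio must be positive", call. = FALSE)
  ratio / control_ratio
}

#' Many-to-one Dunnett comparisons by Monte Carlo
#'
#' One-way ANOVA followed by Dunnett's test of every group against a
#' designated control. The family-wise adjusted p-value for group i is
#' P(max_j |T_j| >= |t_i|) under the joint null of the many-to-one
#' t-statistics, which share the control sample and the pooled variance;
#' that reference distribution is evaluated by seeded Monte Carlo rather
#' than table lookup so arbitrary group counts and unequal sample sizes
#' are handled exactly the same way.
#'
#' @param values Numeric response vector (e.g. rundown-corrected activity
#'   ratios).
#' @param groups Group labels, parallel to `values`.
#' @param control Label of the control group.
#' @param n_mc Number of Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo reference (local to this call).
#' @return List with `anova_F`, `anova_p`, `df`, and `table`: one row per
#'   non-control group with n, mean, sem, t, and Dunnett-adjusted p.
#' @export
dunnett_many_to_one <- function(values, groups, control,
                                n_mc = 1e5, seed = 1) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) < 2L)
    stop("need at least 2 groups (control plus one comparison)",
         call. = FALSE)
  if (!control %in% labs)
    stop("control group '", control, "' not present", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)

  fit <- stats::aov(values ~ factor(groups))
  at <- stats::anova(fit)
  s2 <- at["Residuals", "Mean Sq"]
  df <- at["Residuals", "Df"]

  others <- setdiff(labs, control)
  m0 <- mean(values[groups == control]); n0 <- ns[[control]]
  stat <- vapply(others, function(g) {
    (mean(values[groups == g]) - m0) /
      sqrt(s2 * (1 / ns[[g]] + 1 / n0))
  }, 0)

  # Monte-Carlo null for max_j |T_j|: group means are independent normals,
  # the pooled SD an independent scaled chi; T_j share u0 and S.
  maxT <- withr::with_seed(seed, {
    k <- length(others)
    u0 <- stats::rnorm(n_mc, sd = sqrt(1 / n0))
    S <- sqrt(stats::rchisq(n_mc, df) / df)
    m <- matrix(stats::rnorm(n_mc * k), n_mc, k)
    m <- sweep(m, 2, sqrt(1 / unlist(ns[others])), `*`)
    Tm <- abs(m - u0) / S
    Tm <- sweep(Tm, 2, sqrt(1 / unlist(ns[others]) + 1 / n0), `/`)
    apply(Tm, 1, max)
  })
  p_adj <- vapply(stat, function(t) mean(maxT >= abs(t)), 0)

  tab <- data.frame(
    group = others,
    n = as.integer(ns[others]),
    mean = vapply(others, function(g) mean(values[groups == g]), 0),
    sem = vapply(others, function(g)
      stats::sd(values[groups == g]) / sqrt(ns[[g]]), 0),
    t = stat, p_adj = p_adj, row.names = NULL)
  list(anova_F = at[1, "F value"], anova_p = at[1, "Pr(>F)"],
       df = df, control = control,
       control_mean = m0, control_n = as.integer(n0), table = tab)
}

#' Cohort summary of a cysteine-accessibility experiment
#'
#' Per-cell after/before ratios, rundown correction against the cohort
#' mean of the matching no-reagent control cells, and Dunnett statistics
#' of every construct against the designated control construct. Controls
#' are matched per construct when present; otherwise the pooled control
#' cohort is used and the fallback is flagged.
#'
#' @param patch Data frame in the `patch.csv` schema: `cell_id`,
#'   `construct`, `state_during_MTS` (`closed`, `open`, or
#'   `control_no_MTS`), `I_before_nA`, `I_after_nA`, `dtt_pretreated`.
#' @param control_construct Construct compared against (default
#'   `"wildtype"`).
#' @param alpha Significance level for the flag column (default 0.01).
#' @param n_mc,seed Monte-Carlo settings for [dunnett_many_to_one()].
#' @return List with the per-cell `cells` table (corrected ratios), the
#'   `stats` table (mean, sem, n, adjusted p, significance flag per
#'   construct), and the ANOVA summary.
#' @export
access_summary <- function(patch, control_construct = "wildtype",
                           alpha = 0.01, n_mc = 1e5, seed = 1) {
  stopifnot(is.data.frame(patch),
            all(c("construct", "state_during_MTS", "I_before_nA",
                  "I_after_nA") %in% names(patch)))
  patch$ratio <- normalized_activity(patch$I_before_nA, patch$I_after_nA)
  is_ctrl <- patch$state_during_MTS == "control_no_MTS"
  if (!any(is_ctrl))
    stop("no control_no_MTS cells; rundown cannot be corrected",
         call. = FALSE)
  pooled <- mean(patch$ratio[is_ctrl])
  ctrl_by_construct <- tapply(patch$ratio[is_ctrl],
                              patch$construct[is_ctrl], mean)
  treated <- patch[!is_ctrl, , drop = FALSE]
  cc <- ctrl_by_construct[treated$construct]
  fallback <- is.na(cc)
  cc[fallback] <- pooled
  treated$control_ratio <- as.numeric(cc)
  treated$control_fallback_pooled <- fallback
  treated$corrected <- rundown_correct(treated$ratio,
                                       treated$control_ratio)
  if (!control_construct %in% treated$construct)
    stop("control construct '", control_construct,
         "' has no treated cells", call. = FALSE)
  dn <- dunnett_many_to_one(treated$corrected, treated$construct,
                            control_construct, n_mc = n_mc, seed = seed)
  stats_tab <- rbind(
    data.frame(group = control_construct, n = dn$control_n,
               mean = dn$control_mean,
               sem = stats::sd(treated$corrected[
                 treated$construct == control_construct]) /
                 sqrt(dn$control_n),
               t = NA_real_, p_adj = NA_real_),
    dn$table)
  stats_tab$significant <- !is.na(stats_tab$p_adj) &
    stats_tab$p_adj < alpha
  list(cells = treated, stats = stats_tab,
       anova = list(F = dn$anova_F, p = dn$anova_p, df = dn$df),
       alpha = alpha)
}
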
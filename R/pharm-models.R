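#' Mechanistic inhibition-model parameters
#'
#' Container for the parameters of the two operational-model variants used
#' to describe antagonism of BzATP-evoked P2X7 responses: a competitive
#' model in which agonist and antagonist contest one site, and a
#' non-competitive (allosteric) model in which the antagonist depresses the
#' maximal response. All concentrations are stored in molar.
#'
#' @param kind `"competitive"` or `"noncompetitive"`.
#' @param KA Agonist equilibrium dissociation constant (M).
#' @param KB Antagonist equilibrium dissociation constant (M). Defaults to
#'   1 M, which is inert whenever the antagonist concentration is zero
#'   (e.g. control-curve fitting).
#' @param tau Operational efficacy (dimensionless transducer ratio).
#' @param n Hill coefficient; forced to 1 for the competitive model, which
#'   is printed without an exponent.
#' @param Emax Maximal response in normalized units; forced to 1 for the
#'   competitive model.
#' @param alpha Allosteric binding cooperativity between agonist and
#'   antagonist; 1 (neutral cooperativity) by default and unused by the
#'   competitive model.
#' @return An object of class `mechanism_params`.
#' @export
mechanism_params <- function(kind = c("competitive", "noncompetitive"),
                             KA, KB = 1, tau, n = 1, Emax = 1, alpha = 1) {
  kind <- match.arg(kind)
  for (nm in c("KA", "KB", "tau", "n", "Emax", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (KA <= 0 || KB <= 0 || tau <= 0 || n <= 0 || Emax <= 0 || alpha < 0)
    stop("KA, KB, tau, n, Emax must be > 0 and alpha >= 0", call. = FALSE)
  if (kind == "competitive" && (n != 1 || Emax != 1))
    stop("the competitive model has no Hill exponent or Emax; ",
         "n and Emax must be 1", call. = FALSE)
  structure(
    list(kind = kind, KA = KA, KB = KB, tau = tau, n = n,
         Emax = Emax, alpha = alpha),
    class = "mechanism_params")
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat("<mechanism_params: ", x$kind, ">\n", sep = "")
  cat(sprintf("  KA = %.4g M, KB = %.4g M, tau = %.4g\n", x$KA, x$KB, x$tau))
  if (x$kind == "noncompetitive")
    cat(sprintf("  n = %.4g, Emax = %.4g, alpha = %.4g\n",
                x$n, x$Emax, x$alpha))
  invisible(x)
}

.check_conc <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("`", what, "` must be finite and non-negative (molar)",
         call. = FALSE)
  x
}

#' Competitive-antagonism response
#'
#' Response of the competitive operational-model variant,
#' \deqn{R = \frac{A/K_A}{(A/K_A)(1+\tau) + B/K_B + 1},}
#' already normalized to the control maximum. The response is bounded above
#' by \eqn{1/(1+\tau)} and decreases monotonically with antagonist.
#'
#' @param A Agonist concentration(s), molar.
#' @param B Antagonist concentration(s), molar.
#' @param p A [mechanism_params()] object with `kind = "competitive"`.
#' @return Numeric vector of normalized responses.
#' @export
competitive_response <- function(A, B, p) {
  stopifnot(inherits(p, "mechanism_params"))
  if (p$kind != "competitive")
    stop("`p` must have kind = \"competitive\"", call. = FALSE)
  A <- .check_conc(A, "A"); B <- .check_conc(B, "B")
  x <- A / p$KA
  x / (x * (1 + p$tau) + B / p$KB + 1)
}

#' Non-competitive (allosteric) inhibition response
#'
#' Response of the non-competitive operational model,
#' \deqn{R = \frac{A^n \tau^n E_{max}}
#'   {A^n \tau^n + \left(A(1+\alpha B/K_B) + K_A B/K_B + K_A\right)^n}.}
#' At \eqn{B = 0} this reduces to the operational model of agonism
#' \eqn{E_{max}\tau^n A^n/(\tau^n A^n + (A+K_A)^n)}. Evaluation is carried
#' out in log space so large Hill exponents on extreme concentration grids
#' cannot overflow.
#'
#' @inheritParams competitive_response
#' @param p A [mechanism_params()] object with `kind = "noncompetitive"`.
#' @return Numeric vector of normalized responses.
#' @export
noncompetitive_response <- function(A, B, p) {
  stopifnot(inherits(p, "mechanism_params"))
  if (p$kind != "noncompetitive")
    stop("`p` must have kind = \"noncompetitive\"", call. = FALSE)
  A <- .check_conc(A, "A"); B <- .check_conc(B, "B")
  k <- pmax(length(A), length(B))
  A <- rep_len(A, k); B <- rep_len(B, k)
  out <- numeric(k)
  pos <- A > 0
  if (any(pos)) {
    a <- A[pos]; b <- B[pos]
    # numerator term: n*(log A + log tau); denominator core D > 0 always
    lu <- p$n * (log(a) + log(p$tau))
    D <- a * (1 + p$alpha * b / p$KB) + p$KA * b / p$KB + p$KA
    lv <- p$n * log(D)
    # R = Emax / (1 + exp(lv - lu)), stable for any magnitude
    out[pos] <- p$Emax / (1 + exp(lv - lu))
  }
  out
}

#' Response under either mechanism
#'
#' Dispatch helper evaluating whichever printed model `p` encodes.
#' @inheritParams competitive_response
#' @param p A [mechanism_params()] object.
#' @return Numeric vector of normalized responses.
#' @export
mechanism_response <- function(A, B, p) {
  if (p$kind == "competitive") competitive_response(A, B, p)
  else noncompetitive_response(A, B, p)
}

#' High-agonist plateau of a mechanism
#'
#' Closed-form limit of the response as agonist concentration grows without
#' bound. The competitive plateau \eqn{1/(1+\tau)} is independent of
#' antagonist (surmountable inhibition); the non-competitive plateau
#' \eqn{E_{max}\tau^n/(\tau^n + (1+\alpha B/K_B)^n)} declines with
#' antagonist (insurmountable inhibition).
#'
#' @param p A [mechanism_params()] object.
#' @param B Antagonist concentration(s), molar.
#' @return Plateau response(s).
#' @export
model_plateau <- function(p, B = 0) {
  stopifnot(inherits(p, "mechanism_params"))
  B <- .check_conc(B, "B")
  if (p$kind == "competitive") {
    rep_len(1 / (1 + p$tau), length(B))
  } else {
    # tau^n/(tau^n + c^n) in log space with c = 1 + alpha*B/KB
    lc <- p$n * log1p(p$alpha * B / p$KB)
    lt <- p$n * log(p$tau)
    p$Emax / (1 + exp(lc - lt))
  }
}

#' Model-implied EC50 at a fixed antagonist concentration
#'
#' Finds the agonist concentration producing half the model's own plateau
#' at antagonist concentration `B`, by bisection on a log-concentration
#' bracket. For the competitive model the closed form
#' \eqn{K_A(1+B/K_B)/(1+\tau)} exists and the numeric root agrees with it;
#' the root search is used for both kinds so the same code path feeds the
#' Schild machinery.
#'
#' @param p A [mechanism_params()] object.
#' @param B Antagonist concentration, molar (scalar).
#' @param interval Bracketing interval for the root, molar.
#' @param tol Relative tolerance on the root.
#' @return EC50 in molar.
#' @export
ec50_of_model <- function(p, B = 0, interval = c(1e-15, 1), tol = 1e-6) {
  stopifnot(inherits(p, "mechanism_params"), length(B) == 1L)
  half <- model_plateau(p, B) / 2
  if (half <= 0) stop("model plateau is not positive at this B",
                      call. = FALSE)
  f <- function(lx) mechanism_response(10^lx, B, p) - half
  lo <- log10(interval[1]); hi <- log10(interval[2])
  if (f(lo) > 0 || f(hi) < 0)
    stop("EC50 root not bracketed in [", interval[1], ", ", interval[2],
         "] M (f(lo) = ", signif(f(lo), 3), ", f(hi) = ",
         signif(f(hi), 3), ")", call. = FALSE)
  r <- stats::uniroot(f, c(lo, hi), tol = tol / 3)
  10^r$root
}

#' Model-implied IC50 at a fixed agonist concentration
#'
#' Finds the antagonist concentration halving the drug-free response at
#' agonist concentration `A`, by bisection on a log bracket. If even the
#' upper bracket cannot halve the response (e.g. an absurdly weak
#' antagonist), `Inf` is returned with a warning flagging the IC50 as
#' unreachable.
#'
#' @param p A [mechanism_params()] object.
#' @param A Agonist concentration, molar (scalar).
#' @param interval Bracketing interval for the root, molar.
#' @param tol Relative tolerance on the root.
#' @return IC50 in molar (possibly `Inf`).
#' @export
ic50_of_model <- function(p, A, interval = c(1e-15, 1), tol = 1e-6) {
  stopifnot(inherits(p, "mechanism_params"), length(A) == 1L)
  r0 <- mechanism_response(A, 0, p)
  if (r0 <= 0) stop("drug-free response at this A is not positive",
                    call. = FALSE)
  f <- function(lb) mechanism_response(A, 10^lb, p) - r0 / 2
  lo <- log10(interval[1]); hi <- log10(interval[2])
  if (f(hi) > 0) {
    warning("IC50 unreachable: response not halved at B = ",
            interval[2], " M", call. = FALSE)
    return(Inf)
  }
  if (f(lo) < 0)
    stop("IC50 root not bracketed: response already halved at B = ",
         interval[1], " M", call. = FALSE)
  r <- stats::uniroot(f, c(lo, hi), tol = tol / 3)
  10^r$root
}
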
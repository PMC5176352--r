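# The two printed inhibition equations and their derived quantities,
# checked against hand evaluation, algebraic limits, and brute-force
# grid-search oracles.

test_that("competitive response matches hand evaluation and limits", {
  p <- mechanism_params("competitive", KA = 28e-6, KB = 1.7e-9,
                        tau = 0.031)
  expect_identical(competitive_response(0, 5e-9, p), 0)
  # A = KA, B = 0: x/(x(1+tau)+1) with x = 1 -> 1/2.031
  expect_equal(competitive_response(28e-6, 0, p), 1 / 2.031,
               tolerance = 1e-12)
  # A -> infinity plateau 1/(1+tau)
  expect_equal(competitive_response(1e3, 0, p), 1 / 1.031,
               tolerance = 1e-4)
  expect_equal(model_plateau(p, 0), 1 / 1.031, tolerance = 1e-12)
  expect_equal(model_plateau(p, 1e-6), model_plateau(p, 0))
})

test_that("noncompetitive response matches limit algebra", {
  p <- mechanism_params("noncompetitive", KA = 220e-6, KB = 0.14e-6,
                        tau = 10, n = 2.6)
  expect_identical(noncompetitive_response(0, 1e-6, p), 0)
  # B = 0, A -> inf: tau^n/(1+tau^n)
  tn <- 10^2.6
  expect_equal(model_plateau(p, 0), tn / (1 + tn), tolerance = 1e-12)
  expect_equal(noncompetitive_response(10, 0, p), tn / (1 + tn),
               tolerance = 1e-6)
  # B = KB, alpha = 1, A -> inf: tau^n/(tau^n + 2^n)
  expect_equal(model_plateau(p, p$KB), tn / (tn + 2^2.6),
               tolerance = 1e-12)
  # B -> infinity kills the response
  expect_lt(model_plateau(p, 1), 1e-10)
  # at B = 0 reduces to the operational model of agonism
  A <- 10^seq(-7, -3, length.out = 9)
  direct <- (A^2.6 * 10^2.6) / (A^2.6 * 10^2.6 + (A + 220e-6)^2.6)
  expect_equal(noncompetitive_response(A, 0, p), direct,
               tolerance = 1e-10)
})

test_that("log-space evaluation equals direct arithmetic where finite", {
  p <- mechanism_params("noncompetitive", KA = 220e-6, KB = 0.14e-6,
                        tau = 10, n = 2.6)
  A <- 10^seq(-9, -1, length.out = 13)
  B <- 10^seq(-9, -4, length.out = 13)
  direct <- (A^p$n * p$tau^p$n * p$Emax) /
    (A^p$n * p$tau^p$n +
       (A * (1 + p$alpha * B / p$KB) + p$KA * B / p$KB + p$KA)^p$n)
  expect_equal(noncompetitive_response(A, B, p), direct,
               tolerance = 1e-10)
  # extreme grid that would overflow naive powers stays finite
  expect_true(all(is.finite(
    noncompetitive_response(10^seq(-300, 300, by = 100) |>
                              pmin(1) |> pmax(0), 0, p))))
})

test_that("reduction property: B = 0 equals huge KB at any B", {
  p0 <- mechanism_params("noncompetitive", KA = 220e-6, KB = 1,
                         tau = 10, n = 2.6)
  phuge <- mechanism_params("noncompetitive", KA = 220e-6, KB = 1e12,
                            tau = 10, n = 2.6)
  A <- 10^seq(-7, -3, length.out = 15)
  expect_equal(noncompetitive_response(A, 0, p0),
               noncompetitive_response(A, 1e-3, phuge),
               tolerance = 1e-10)
})

test_that("responses are monotone in A and B over random draws", {
  withr::with_seed(7, {
    for (i in 1:20) {
      kind <- sample(c("competitive", "noncompetitive"), 1)
      p <- if (kind == "competitive")
        mechanism_params("competitive", KA = 10^stats::runif(1, -7, -3),
                         KB = 10^stats::runif(1, -9, -5),
                         tau = 10^stats::runif(1, -2, 1))
      else
        mechanism_params("noncompetitive",
                         KA = 10^stats::runif(1, -7, -3),
                         KB = 10^stats::runif(1, -9, -5),
                         tau = 10^stats::runif(1, -1, 1.5),
                         n = stats::runif(1, 0.5, 3))
      A <- 10^seq(-8, -2, length.out = 25)
      B <- 10^seq(-10, -4, length.out = 25)
      rA <- mechanism_response(A, B[5], p)
      rB <- mechanism_response(A[20], B, p)
      expect_true(all(diff(rA) >= -1e-12))
      expect_true(all(diff(rB) <= 1e-12))
    }
  })
})

test_that("model-implied EC50 agrees with closed forms and grid oracle", {
  pc <- mechanism_params("competitive", KA = 28e-6, KB = 1.7e-9,
                         tau = 0.031)
  # closed form KA(1+B/KB)/(1+tau)
  expect_rel(ec50_of_model(pc, 0), 28e-6 / 1.031, 1e-4)
  expect_rel(ec50_of_model(pc, pc$KB), 2 * ec50_of_model(pc, 0), 1e-4)
  # dose ratio r = 1 + B/KB across three decades of B
  for (b in pc$KB * c(0.01, 0.1, 1, 10, 100)) {
    r <- ec50_of_model(pc, b) / ec50_of_model(pc, 0)
    expect_rel(r, 1 + b / pc$KB, 1e-4)
  }

  pn <- mechanism_params("noncompetitive", KA = 220e-6, KB = 0.14e-6,
                         tau = 10, n = 2.6)
  # independent dense-grid + bisection oracle
  grid_oracle <- function(p, B) {
    half <- model_plateau(p, B) / 2
    lA <- seq(-12, 0, length.out = 20001)
    resp <- mechanism_response(10^lA, B, p)
    i <- which(resp >= half)[1]
    lo <- 10^lA[i - 1]; hi <- 10^lA[i]
    for (k in 1:80) {
      mid <- sqrt(lo * hi)
      if (mechanism_response(mid, B, p) >= half) hi <- mid else lo <- mid
    }
    sqrt(lo * hi)
  }
  expect_rel(ec50_of_model(pn, 0), grid_oracle(pn, 0), 1e-5)
  expect_rel(ec50_of_model(pn, 1e-6), grid_oracle(pn, 1e-6), 1e-5)
})

test_that("model-implied IC50 matches closed form / oracle and flags", {
  pc <- mechanism_params("competitive", KA = 28e-6, KB = 1.7e-9,
                         tau = 0.031)
  A <- 1e-4
  closed <- pc$KB * ((A / pc$KA) * (1 + pc$tau) + 1)
  expect_rel(ic50_of_model(pc, A), closed, 1e-4)

  pn <- mechanism_params("noncompetitive", KA = 220e-6, KB = 0.14e-6,
                         tau = 10, n = 2.6)
  oracle <- function(p, A) {
    half <- mechanism_response(A, 0, p) / 2
    lB <- seq(-12, -2, length.out = 20001)
    resp <- mechanism_response(A, 10^lB, p)
    i <- which(resp <= half)[1]
    lo <- 10^lB[i - 1]; hi <- 10^lB[i]
    for (k in 1:80) {
      mid <- sqrt(lo * hi)
      if (mechanism_response(A, mid, p) <= half) hi <- mid else lo <- mid
    }
    sqrt(lo * hi)
  }
  expect_rel(ic50_of_model(pn, 1e-3), oracle(pn, 1e-3), 1e-5)
  # an antagonist with an absurdly weak KB cannot halve the response
  weak <- mechanism_params("noncompetitive", KA = 220e-6, KB = 1e6,
                           tau = 10, n = 2.6)
  expect_warning(ic <- ic50_of_model(weak, 1e-3), "unreachable")
  expect_identical(ic, Inf)
})

test_that("invalid inputs and kind mismatches error cleanly", {
  pc <- mechanism_params("competitive", KA = 28e-6, tau = 0.031)
  pn <- mechanism_params("noncompetitive", KA = 220e-6, KB = 0.14e-6,
                         tau = 10, n = 2.6)
  expect_error(competitive_response(-1e-6, 0, pc), "non-negative")
  expect_error(competitive_response(NA_real_, 0, pc), "finite")
  expect_error(competitive_response(1e-6, 0, pn), "competitive")
  expect_error(noncompetitive_response(1e-6, 0, pc), "noncompetitive")
  expect_error(mechanism_params("competitive", KA = 28e-6, tau = 0.031,
                                n = 2), "must be 1")
  expect_error(mechanism_params("noncompetitive", KA = -1, tau = 1),
               "> 0")
})
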
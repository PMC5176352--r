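# Hill fits and the two-stage mechanism estimation.

test_that("hill_response arithmetic and midpoint identity", {
  hp <- hill_params(40e-6, 1, 1, 0, "activation")
  expect_equal(hill_response(40e-6, hp), 0.5, tolerance = 1e-12)
  expect_equal(hill_response(120e-6, hp), 0.75, tolerance = 1e-12)
  expect_equal(hill_response(0, hp), 0)
  hpi <- hill_params(40e-6, 2, 1, 0.2, "inhibition")
  expect_equal(hill_response(40e-6, hpi), 0.6, tolerance = 1e-12)
  expect_equal(hill_response(0, hpi), 1)
})

test_that("fit_hill recovers exact Hill data and honors fix", {
  x <- 10^seq(-6.5, -3, length.out = 8)
  hp <- hill_params(40e-6, 1, 1, 0, "activation")
  y <- hill_response(x, hp)
  f <- fit_hill(rep(x, 3), rep(y, 3), "activation")
  expect_true(f$converged)
  expect_rel(f$params$midpoint, 40e-6, 1e-3)
  expect_rel(f$params$slope, 1, 1e-3)
  # clamped slope is not free and is returned verbatim
  f2 <- fit_hill(x, y, "activation", fix = list(slope = 1, bottom = 0))
  expect_equal(f2$n_free_params, 2L)
  expect_identical(f2$params$slope, 1)
  expect_rel(f2$params$midpoint, 40e-6, 1e-3)
  expect_error(fit_hill(x[1:3], y[1:3], "activation"), "4 distinct")
})

test_that("fit_hill flags flat titrations instead of inventing a curve", {
  x <- 10^seq(-7, -3, length.out = 8)
  f <- suppressWarnings(fit_hill(x, rep(0.2, 8), "activation"))
  expect_true(f$flags$zero_amplitude)
  expect_false(f$converged)
})

test_that("control fits recover generating parameters at zero noise", {
  # competitive: free (KA, tau)
  dc <- sim_c(1, noise_sd = 0)
  fc <- fit_control(dc[dc$antagonist_conc_M == 0, ], "competitive")
  expect_true(fc$converged)
  expect_rel(fc$params$KA, 28e-6, 0.01)
  expect_rel(fc$params$tau, 0.031, 0.01)
  expect_equal(fc$n_free_params, 2L)

  # noncompetitive with tau, Emax clamped at truth: KA, n within 1%
  dn <- sim_nc(1, noise_sd = 0)
  fn <- fit_control(dn[dn$antagonist_conc_M == 0, ], "noncompetitive",
                    fix = list(tau = 10))
  expect_true(fn$converged)
  expect_rel(fn$params$KA, 220e-6, 0.01)
  expect_rel(fn$params$n, 2.6, 0.01)
  expect_true(fn$fixed_mask[["tau"]])

  short <- dc[dc$agonist_conc_M %in% unique(dc$agonist_conc_M)[1:3], ]
  expect_error(fit_control(short[short$antagonist_conc_M == 0, ],
                           "competitive"), "6 distinct")
  expect_error(fit_control(dn, "noncompetitive"), "antagonist-free")
})

test_that("fit_KB recovers generating KB at zero noise for both kinds", {
  dn <- sim_nc(2, noise_sd = 0)
  fitn <- fit_two_stage(dn, "noncompetitive")
  expect_rel(fitn$params$KB, 0.14e-6, 0.01)

  dc <- sim_c(2, noise_sd = 0)
  fitc <- fit_two_stage(dc, "competitive")
  expect_rel(fitc$params$KB, 1.7e-9, 0.01)
  # parameter counting across the two stages
  expect_equal(fitc$n_free_params, 3L)
  expect_equal(fitn$n_free_params, 4L)
})

test_that("fit_KB demands an antagonist signal and non-zero B", {
  d <- sim_nc(3)
  ctrl <- fit_control(d[d$antagonist_conc_M == 0, ], "noncompetitive")
  b0 <- d[d$antagonist_conc_M == 0, ]
  expect_error(fit_KB(b0, ctrl), "zero")
  # inert antagonist: responses indistinguishable from control
  inert <- jnj_nc(); inert <- mechanism_params(
    "noncompetitive", KA = inert$KA, KB = 1e6, tau = inert$tau,
    n = inert$n)
  dinert <- simulate_dose_response(simulation_design(
    inert, antagonist_grid = kb_grid_nc(), seed = 4))
  ctrl2 <- fit_control(dinert[dinert$antagonist_conc_M == 0, ],
                       "noncompetitive")
  expect_warning(f <- fit_KB(dinert, ctrl2), "indistinguishable")
  expect_true(f$flags$no_inhibition_signal)
})

test_that("estimates are equivariant under concentration-unit relabeling", {
  d <- sim_nc(5)
  f1 <- fit_two_stage(d, "noncompetitive")
  du <- d
  du$agonist_conc_M <- du$agonist_conc_M * 1e6     # relabel M -> uM
  du$antagonist_conc_M <- du$antagonist_conc_M * 1e6
  f2 <- fit_two_stage(du, "noncompetitive",
                      KB_bounds = c(1e-12, 1e-2) * 1e6,
                      KA_bounds = c(1e-9, 1e-1) * 1e6)
  expect_rel(f2$params$KA, f1$params$KA * 1e6, 1e-3)
  expect_rel(f2$params$KB, f1$params$KB * 1e6, 1e-3)
  expect_rel(f2$params$tau, f1$params$tau, 1e-3)
})

test_that("each stage's converged SS is no worse than SS at its
           generating parameters", {
  truth <- jnj_nc()
  for (s in 1:5) {
    d <- sim_nc(s)
    f <- fit_two_stage(d, "noncompetitive")
    # stage 1 on the antagonist-free subset
    b0 <- d[d$antagonist_conc_M == 0, ]
    ss_ctrl_truth <- sum((b0$response -
                            mechanism_response(b0$agonist_conc_M, 0,
                                               truth))^2)
    expect_lte(f$control$SS, ss_ctrl_truth + 1e-10)
    # stage 2: joint SS at the fitted KB vs at the generating KB, with
    # the stage-1 parameters held fixed in both
    cp <- f$control$params
    at_true_kb <- mechanism_params("noncompetitive", KA = cp$KA,
                                   KB = truth$KB, tau = cp$tau,
                                   n = cp$n)
    ss_true_kb <- sum((d$response -
                         mechanism_response(d$agonist_conc_M,
                                            d$antagonist_conc_M,
                                            at_true_kb))^2)
    expect_lte(f$SS, ss_true_kb + 1e-10)
  }
})

test_that("median KB recovery over seeded noisy replicates, all drugs", {
  # sigma = 0.02, 5 replicates; median over seeds within +/-25% of the
  # generating non-competitive KB for each antagonist
  kbs <- p2x7_published_kb("noncompetitive")
  for (drug in names(kbs)) {
    truth <- p2x7_published_params("noncompetitive", drug)
    grid <- c(0, truth$KB * 10^seq(-0.7, 0.9, length.out = 4))
    est <- sapply(1:7, function(s) {
      d <- simulate_dose_response(simulation_design(
        truth, antagonist_grid = grid, seed = 1000 * s,
        antagonist_id = drug))
      fit_two_stage(d, "noncompetitive")$params$KB
    })
    expect_rel(median(est), kbs[[drug]], 0.25)
  }
})

test_that("hill midpoint of model-generated control data matches the
           model-implied EC50", {
  p <- jnj_nc()
  d <- sim_nc(6, noise_sd = 0)
  b0 <- d[d$antagonist_conc_M == 0, ]
  f <- fit_hill(b0$agonist_conc_M, b0$response, "activation")
  expect_rel(f$params$midpoint, ec50_of_model(p, 0), 0.05)
})

test_that("fold_change_ic50 is the midpoint ratio with guards", {
  x <- 10^seq(-9, -6, length.out = 8)
  mk <- function(mid) {
    y <- hill_response(x, hill_params(mid, 1, 1, 0, "inhibition"))
    fit_hill(x, y, "inhibition")
  }
  wt <- mk(20e-9); mut <- mk(200e-9)
  expect_rel(fold_change_ic50(mut, wt), 10, 0.01)
  expect_equal(fold_change_ic50(wt, wt), 1, tolerance = 1e-9)
  act <- fit_hill(x, hill_response(x, hill_params(1e-7, 1, 1, 0,
                                                  "activation")),
                  "activation")
  expect_error(fold_change_ic50(act, wt), "inhibition")
})
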
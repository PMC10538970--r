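test_that("theoretical initial rates follow the closed form and its identities", {
  ex <- reference_case()
  r0 <- theoretical_initial_rates(ex$mechanism, ex$setup)
  ax0 <- 12004 * 1.65 * 1.58e-5
  expect_equal(unname(r0["X"]), -0.062 * 1.25e-5 * (1 - 10^(-ax0)),
               tolerance = 1e-12)

  cs <- branch_case(0.03, 0.05)
  rb <- theoretical_initial_rates(cs$mechanism, cs$setup)
  expect_equal(unname(rb["X"]), -unname(rb["Y1"] + rb["Y3"]), tolerance = 1e-12)

  s2 <- ex$setup; s2$p0 <- 2 * s2$p0
  r0_2 <- theoretical_initial_rates(ex$mechanism, s2)
  expect_equal(unname(r0_2 / r0), c(2, 2))
})

test_that("theory, fit and numerical initial rates coincide across many systems", {
  set.seed(2024)
  theo_all <- c(); fit_all <- c(); rk_all <- c()
  n_ok <- 0L
  while (n_ok < 20L) {
    cs <- random_submechanism()
    tr <- simulate_to_steady(cs$mechanism, cs$setup, warn_absorbance = FALSE)
    cf <- suppressWarnings(fit_species_traces(tr, cs$mechanism,
                                              seed = 900 + n_ok,
                                              fit_atot = FALSE))
    trip <- initial_rate_triplet(cs$mechanism, cs$setup, tr, cf)
    if (any(trip$flagged)) next
    expect_lt(max(trip$max_rel_spread), 0.01)
    theo_all <- c(theo_all, trip$theo)
    fit_all <- c(fit_all, trip$fit)
    rk_all <- c(rk_all, trip$rk)
    n_ok <- n_ok + 1L
  }
  # identity-line regressions over the pooled rates
  f1 <- stats::lm(fit_all ~ theo_all)
  f2 <- stats::lm(rk_all ~ theo_all)
  expect_equal(unname(stats::coef(f1)[2]), 1, tolerance = 0.01)
  expect_equal(unname(stats::coef(f2)[2]), 1, tolerance = 0.01)
  # squared correlation (summary.lm warns on numerically perfect lines)
  expect_gt(stats::cor(fit_all, theo_all)^2, 0.999)
  expect_gt(stats::cor(rk_all, theo_all)^2, 0.999)
})

test_that("the spectator sweep matches the closed-form reduction and is monotone", {
  ex <- reference_case()
  a_vals <- c(0, 0.1, 0.25, 0.5, 1, 2)
  sw <- spectator_sweep(ex$mechanism, ex$setup, a_vals)
  expect_equal(sw$pct_reduction[1], 0)
  expect_true(all(diff(sw$pct_reduction) > 0))
  # closed form from the rate law at t = 0 with only the reactant absorbing
  ax0 <- 12004 * 1.65 * 1.58e-5
  red <- 100 * (1 - (ax0 / (ax0 + a_vals)) *
                  (1 - 10^(-ax0 - a_vals)) / (1 - 10^(-ax0)))
  expect_equal(sw$pct_reduction, red, tolerance = 1e-12)
})

test_that("the fitted route of the spectator sweep agrees with theory", {
  ex <- reference_case()
  sw <- spectator_sweep(ex$mechanism, ex$setup, c(0, 0.5), fit = TRUE,
                        seed = 31)
  expect_lt(max(rel_err(sw$r0x_fit, sw$r0x)), 0.01)
})

test_that("raising the initial concentration speeds, then saturates, the reaction", {
  ex <- reference_case()
  cx0 <- c(0.5, 1, 2, 4, 8) * 1.58e-5
  sw <- concentration_sweep(ex$mechanism, ex$setup, cx0, seed = 17)
  tab <- sw$table
  expect_true(all(diff(abs(tab$r0x_theo)) > 0))
  # saturation toward total absorption of the incident light
  expect_true(all(abs(tab$r0x_theo) < 0.062 * 1.25e-5))
  expect_gt(abs(tab$r0x_theo[5]) / (0.062 * 1.25e-5), 0.8)
  expect_lt(max(rel_err(tab$r0x_fit, tab$r0x_theo)), 0.01)
  # continuation-fitted rate constants decrease as the photokinetic factor shrinks
  expect_true(all(diff(tab$k1) < 0))
  # final-concentration ratios do not depend on the initial concentration
  # (tolerance allows for the finite integration horizon of each trace)
  expect_lt(max(abs(sw$final_ratio[, 2] / sw$final_ratio[1, 2] - 1)), 1e-4)
})

test_that("the wavelength-invariance ratio test separates the two verdicts", {
  run <- list(r0x = -3.98e-7, p0 = 1.25e-5, ax0 = 0.31294)
  v0 <- wavelength_invariance_test(run, run)
  expect_equal(v0$ratio, 1)
  expect_equal(v0$reference, 1)
  expect_equal(v0$verdict, "invariant quantum yield")

  # same summed yield at a second wavelength: ratio equals the reference
  m2 <- photoreversible_example()$mechanism
  m2$species$epsilon <- c(8000, 15000)  # different absorption at wavelength 2
  s <- photoreversible_example()$setup
  s2 <- s; s2$p0 <- 2e-5
  r1 <- unname(theoretical_initial_rates(photoreversible_example()$mechanism, s)[1])
  r2 <- unname(theoretical_initial_rates(m2, s2)[1])
  v1 <- wavelength_invariance_test(
    list(r0x = r1, p0 = s$p0, ax0 = 12004 * 1.65 * 1.58e-5),
    list(r0x = r2, p0 = s2$p0, ax0 = 8000 * 1.65 * 1.58e-5), tol = 1e-6)
  expect_equal(v1$verdict, "invariant quantum yield")

  # doubling the quantum yield at wavelength 2 halves the measured ratio
  m3 <- m2; m3$steps$phi[1] <- 2 * m3$steps$phi[1]
  r3 <- unname(theoretical_initial_rates(m3, s2)[1])
  v2 <- wavelength_invariance_test(
    list(r0x = r1, p0 = s$p0, ax0 = 12004 * 1.65 * 1.58e-5),
    list(r0x = r3, p0 = s2$p0, ax0 = 8000 * 1.65 * 1.58e-5), tol = 1e-3)
  expect_equal(v2$verdict, "wavelength-dependent quantum yield")
  expect_equal(v2$ratio / v2$reference, 0.5, tolerance = 1e-9)
})
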
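test_that("photokinetic factor has the right limits and monotonicity", {
  expect_equal(photokinetic_factor(0), log(10))
  expect_equal(photokinetic_factor(1), 0.9)
  expect_equal(photokinetic_factor(0.42096), 1.474368, tolerance = 1e-6)
  # continuity at 0 through the series regime
  expect_equal(photokinetic_factor(1e-12), log(10), tolerance = 1e-9)
  a <- seq(0, 3, by = 0.01)
  expect_true(all(diff(photokinetic_factor(a)) < 0))
  expect_error(photokinetic_factor(-0.1), "negative")
})

test_that("absorbed light reproduces the reference worked values", {
  # photoreversible system, t = 30 s and 60 s states
  expect_equal(absorbed_light(0.19636204, 0.42096, 1.25e-5), 3.61887e-6,
               tolerance = 1e-5)
  expect_equal(absorbed_light(0.2758036, 0.44558, 1.25e-5), 4.96385e-6,
               tolerance = 1e-5)
  expect_equal(absorbed_light(0, 0.3, 1e-5), 0)
  # the absorber shares sum to the total absorbed flux
  a <- c(0.1, 0.15, 0.05); atot <- sum(a); p0 <- 1.25e-5
  expect_equal(sum(absorbed_light(a, atot, p0)), p0 * (1 - 10^(-atot)))
  expect_error(absorbed_light(0.5, 0.3, 1e-5), "exceeds total")
})

test_that("the rate law reproduces the reference state and conserves mass", {
  ex <- reference_case()
  r <- rate_law(ex$mechanism, ex$setup, c(9.91197e-6, 5.88738e-6))
  expect_equal(unname(r["X"]), -8.35686e-8, tolerance = 1e-3)
  expect_equal(unname(r["Y1"]), -unname(r["X"]))
  expect_equal(unname(rate_law(ex$mechanism, ex$setup, c(0, 0))), c(0, 0))
  expect_error(rate_law(ex$mechanism, ex$setup, c(1e-5)), "dimension")
})

test_that("RK4 simulation reproduces the photoreversible trace landmarks", {
  tr <- reference_trace()
  i30 <- which(tr$times == 30); i60 <- which(tr$times == 60)
  expect_equal(unname(tr$conc[i30, "X"]), 9.91197e-6, tolerance = 1e-3)
  expect_equal(unname(tr$conc[i60, "X"]), 8.57014e-6, tolerance = 1e-3)
  expect_equal(unname(tr$conc[i60, "Y1"]), 7.22959e-6, tolerance = 1e-3)
  expect_equal(tr$atot[i30], 0.42096, tolerance = 1e-3)
  expect_equal(tr$atot[i60], 0.44558, tolerance = 1e-3)
})

test_that("mass is conserved and halving dt leaves concentrations unchanged", {
  set.seed(11)
  for (i in 1:5) {
    cs <- random_submechanism()
    tr <- simulate_mechanism(cs$mechanism, cs$setup, t_end = 60, dt = 0.5,
                             warn_absorbance = FALSE)
    tot <- rowSums(tr$conc)
    expect_lt(max(abs(tot / tot[1] - 1)), 1e-9)
  }
  ex <- reference_case()
  a <- simulate_mechanism(ex$mechanism, ex$setup, t_end = 60, dt = 0.2)
  b <- simulate_mechanism(ex$mechanism, ex$setup, t_end = 60, dt = 0.1)
  ia <- which(a$times == 60); ib <- which(b$times == 60)
  expect_lt(rel_err(a$conc[ia, "X"], b$conc[ib, "X"]), 1e-8)
})

test_that("the primary photoprocess matches its analytic closed form", {
  cs <- primary_case(phi = 0.05)
  s <- cs$setup
  tr <- simulate_mechanism(cs$mechanism, s, t_end = 200, dt = 0.1)
  eps_x <- 12004
  kx <- 0.05 * eps_x * s$p0 * s$l_irr * log(10)
  ax0 <- eps_x * s$l_irr * 1.58e-5
  # 10^(AX(t)) = 1 + (10^(AX0) - 1) exp(-kX t)
  ax_exact <- log10(1 + (10^ax0 - 1) * exp(-kx * tr$times))
  cx_exact <- ax_exact / (eps_x * s$l_irr)
  expect_lt(max(abs(tr$conc[, "X"] - cx_exact)) / 1.58e-5, 1e-6)
})

test_that("isosbestic irradiation gives constant absorbance and first-order traces", {
  m <- photoreversible_example()$mechanism
  m$species$epsilon <- c(15000, 15000)
  s <- photoreversible_example()$setup
  tr <- simulate_mechanism(m, s, t_end = 200, dt = 0.1)
  expect_lt(diff(range(tr$atot)), 1e-10)
  # constant-PKF rate law is linear: CX(t) = CXinf + (CX0-CXinf) e^(-(a+b) t)
  pkf0 <- photokinetic_factor(tr$atot[1])
  a <- 0.062 * 15000 * s$l_irr * s$p0 * pkf0
  b <- 0.034 * 15000 * s$l_irr * s$p0 * pkf0
  cx0 <- 1.58e-5
  cxinf <- cx0 * b / (a + b)
  cx_exact <- cxinf + (cx0 - cxinf) * exp(-(a + b) * tr$times)
  expect_lt(max(abs(tr$conc[, "X"] - cx_exact)) / cx0, 1e-8)
})

test_that("spectators slow every species without entering the chemistry", {
  ex <- reference_case()
  r0 <- vapply(c(0, 0.2, 0.5, 1), function(a) {
    m <- ex$mechanism
    if (a > 0) m$spectators <- data.frame(name = "SPM", absorbance = a)
    abs(unname(theoretical_initial_rates(m, ex$setup)[1]))
  }, 0)
  expect_true(all(diff(r0) < 0))

  m <- ex$mechanism
  m$spectators <- data.frame(name = "SPM", absorbance = 0.5)
  tr0 <- simulate_mechanism(ex$mechanism, ex$setup, t_end = 10, dt = 0.1)
  tr1 <- simulate_mechanism(m, ex$setup, t_end = 10, dt = 0.1,
                            warn_absorbance = FALSE)
  # absorbance additivity at t = 0 (identical concentrations)
  expect_equal(tr1$atot[1], tr0$atot[1] + 0.5)
})

test_that("total absorbance recomputes from concentrations and rescales paths", {
  ex <- reference_case()
  tr <- reference_trace()
  at <- total_absorbance_trace(tr, ex$mechanism, ex$setup)
  expect_equal(at, tr$atot)
  expect_equal(at[1], 12004 * 1.65 * 1.58e-5, tolerance = 1e-12)
  at_obs <- total_absorbance_trace(tr, ex$mechanism, ex$setup, l_obs = 1)
  expect_equal(rescale_absorbance(at_obs, 1, 1.65), at)
})

test_that("the photostationary state matches closed form, RK limit and Table-like constants", {
  ex <- reference_case()
  ps <- photostationary_state(ex$mechanism, ex$setup)
  expect_equal(unname(ps["X"]), 8.1165e-6, tolerance = 1e-3)
  ps_rk <- photostationary_state(ex$mechanism, ex$setup, closed_form = FALSE,
                                 rate_tol = 1e-16)
  expect_lt(max(abs(ps - ps_rk)), 1e-9)

  cs <- primary_case(phi = 0.05, eps_y = 3000)
  ps2 <- photostationary_state(cs$mechanism, cs$setup)
  expect_equal(unname(ps2), c(0, 1.58e-5), tolerance = 1e-6)
})

test_that("trace CSV round-trips losslessly", {
  tr <- simulate_mechanism(reference_case()$mechanism, reference_case()$setup,
                           t_end = 5, dt = 0.1)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$times, tr$times, tolerance = 0)
  expect_equal(tr2$conc, tr$conc, tolerance = 0)
  expect_equal(tr2$atot, tr$atot, tolerance = 0)
  unlink(f)
})

test_that("simulation guards its preconditions", {
  ex <- reference_case()
  expect_error(simulate_mechanism(ex$mechanism, ex$setup, t_end = -1))
  expect_warning(simulate_mechanism(ex$mechanism, ex$setup, t_end = 60,
                                    dt = 6), "upper bound")
  expect_error(simulate_mechanism(reference_topology(), ex$setup, t_end = 10),
               "placeholders")
  m <- ex$mechanism
  m$species$epsilon <- c(40000, 40000)
  expect_warning(simulate_mechanism(m, ex$setup, t_end = 5, dt = 0.1),
                 "> 0.5")
})

test_that("the reactant half-life falls with stronger flux", {
  ex <- reference_case()
  th <- vapply(c(1, 2, 4) * 1.25e-5, function(p0) {
    s <- ex$setup; s$p0 <- p0
    half_life(simulate_mechanism(ex$mechanism, s, t_end = 300, dt = 0.1))
  }, 0)
  expect_true(all(diff(th) < 0))
  # interpolated crossing sits at the concentration midpoint
  tr <- reference_trace()
  t12 <- half_life(tr)
  cx_mid <- stats::approx(tr$times, tr$conc[, 1], t12)$y
  expect_equal(cx_mid, unname(tr$conc[1, 1] + tr$conc[nrow(tr$conc), 1]) / 2,
               tolerance = 1e-6)
})
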
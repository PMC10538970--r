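test_that("reactant and branch quantum yields invert the initial-rate law", {
  ex <- reference_case()
  s <- ex$setup
  ax0 <- 12004 * 1.65 * 1.58e-5
  r0 <- unname(theoretical_initial_rates(ex$mechanism, s)[1])
  expect_equal(reactant_qy_sum(r0, s$p0, ax0), 0.062, tolerance = 1e-12)
  expect_equal(reactant_qy_sum(0, s$p0, ax0), 0)

  cs <- branch_case(0.03, 0.05)
  rb <- theoretical_initial_rates(cs$mechanism, cs$setup)
  ax0b <- 12004 * 1.65 * 1.58e-5
  phi1 <- branch_qy(unname(rb["Y1"]), cs$setup$p0, ax0b)
  phi3 <- branch_qy(unname(rb["Y3"]), cs$setup$p0, ax0b)
  expect_equal(phi1 + phi3, reactant_qy_sum(unname(rb["X"]), cs$setup$p0, ax0b),
               tolerance = 1e-12)
  expect_equal(phi1 + phi3, 0.08, tolerance = 1e-12)

  expect_error(reactant_qy_sum(1e-8, s$p0, ax0), "non-positive")
  expect_error(branch_qy(-1e-8, s$p0, ax0), "non-negative")
})

test_that("branch quantum yields are recovered from fitted initial rates", {
  cs <- branch_case(0.03, 0.05)
  tr <- simulate_to_steady(cs$mechanism, cs$setup, warn_absorbance = FALSE)
  cf <- fit_species_traces(tr, cs$mechanism, seed = 13, fit_atot = FALSE)
  ax0 <- 12004 * 1.65 * 1.58e-5
  p0 <- cs$setup$p0
  expect_lt(rel_err(reactant_qy_sum(model_initial_rate(cf$models$X), p0, ax0),
                    0.08), 0.005)
  expect_lt(rel_err(branch_qy(model_initial_rate(cf$models$Y1), p0, ax0),
                    0.03), 0.005)
  expect_lt(rel_err(branch_qy(model_initial_rate(cf$models$Y3), p0, ax0),
                    0.05), 0.005)
})

test_that("greedy timepoint selection is at least as well conditioned as the reference pair", {
  ex <- reference_case()
  cf <- reference_fit()
  attr(cf, "times") <- reference_trace()$times
  tp <- select_timepoints(cf, 2, ex$setup)
  cond_at <- function(times) {
    M <- do.call(rbind, lapply(times, function(t) ex$setup$l_irr *
      c(eval_model(cf$models$X, t), eval_model(cf$models$Y1, t))))
    sv <- svd(M)$d
    max(sv) / min(sv)
  }
  expect_lte(attr(tp, "cond"), cond_at(c(30, 60)) + 1e-9)
  expect_identical(anyDuplicated(tp), 0L)
  # a duplicated timepoint makes the absorbance system singular
  expect_error(solve_epsilons(cf, ex$setup, c(30, 30)), "singular")
})

test_that("absorption coefficients are recovered exactly from exact traces", {
  ex <- reference_case()
  tr <- reference_trace()
  st2 <- solve_epsilons(tr, ex$setup, c(30, 60))
  expect_lt(rel_err(st2$epsilons[["X"]], 12004), 1e-6)
  expect_lt(rel_err(st2$epsilons[["Y1"]], 23123), 1e-6)
  expect_lt(st2$residual, 1e-10)
})

test_that("quantum yields are recovered exactly from exact traces and true epsilons", {
  ex <- reference_case()
  tr <- reference_trace()
  st3 <- solve_phis(tr, ex$mechanism, ex$setup,
                    epsilons = c(X = 12004, Y1 = 23123),
                    timepoints = c(30, 60))
  expect_lt(rel_err(st3$phis[["X->Y1"]], 0.062), 1e-4)
  expect_lt(rel_err(st3$phis[["Y1->X"]], 0.034), 1e-4)
})

test_that("the full three-stage procedure recovers the photoreversible intrinsics", {
  ex <- reference_case()
  rep <- solve_intrinsics(reference_trace(), reference_topology(), ex$setup,
                          seed = 7, timepoints = c(30, 60),
                          truth = list(epsilon = c(X = 12004, Y1 = 23123),
                                       phi = c("X->Y1" = 0.062,
                                               "Y1->X" = 0.034)))
  expect_lt(max(rep$pct_err$epsilon), 0.05)
  expect_lt(max(rep$pct_err$phi), 0.05)
  expect_lt(rep$cond_eps, 1e3)
  expect_true(all(rep$epsilons > 0) && all(rep$phis > 0))
})

test_that("a three-species consecutive chain solves within half a percent", {
  m <- scheme1_template(c("X->Y1", "Y1->Y2"),
                        epsilon = c(X = 12004, Y1 = 16000, Y2 = 5000),
                        phi = c(0.062, 0.09), c0 = 1.58e-5)
  s <- irradiation_setup(lambda_irr = 365, p0 = 1.25e-5, l_irr = 1.65)
  tr <- simulate_to_steady(m, s, warn_absorbance = FALSE)
  topo <- m; topo$species$epsilon <- NA_real_; topo$steps$phi <- NA_real_
  rep <- suppressWarnings(solve_intrinsics(tr, topo, s, seed = 3,
                          truth = list(epsilon = c(X = 12004, Y1 = 16000,
                                                   Y2 = 5000),
                                       phi = c("X->Y1" = 0.062,
                                               "Y1->Y2" = 0.09))))
  expect_lt(max(rep$pct_err$epsilon), 0.5)
  expect_lt(max(rep$pct_err$phi), 0.5)
})

test_that("the procedure requires every species trace and the absorbance series", {
  ex <- reference_case()
  tr <- reference_trace()
  tr_missing <- tr
  tr_missing$conc <- tr$conc[, 1, drop = FALSE]
  expect_error(solve_intrinsics(tr_missing, reference_topology(), ex$setup),
               "every species")
  tr_noa <- tr; tr_noa$atot <- NULL
  expect_error(solve_intrinsics(tr_noa, reference_topology(), ex$setup),
               "absorbance")
})

test_that("the primary-photoprocess integrated formulas agree and recover the yield", {
  cs <- primary_case(phi = 0.05)
  tr <- simulate_mechanism(cs$mechanism, cs$setup, t_end = 300, dt = 0.1)
  out <- qy_primary_integrated(tr, cs$mechanism, cs$setup)
  expect_lt(rel_err(out$phi, 0.05), 1e-3)
  expect_lt(out$max_rel_diff, 1e-6)
  k_true <- 0.05 * 12004 * cs$setup$p0 * cs$setup$l_irr * log(10)
  expect_lt(rel_err(out$k, k_true), 1e-4)
  # the t -> 0 limit is the initial-rate quotient
  r0 <- unname(theoretical_initial_rates(cs$mechanism, cs$setup)[1])
  ax0 <- 12004 * 1.65 * 1.58e-5
  expect_lt(rel_err(out$phi, reactant_qy_sum(r0, cs$setup$p0, ax0)), 1e-3)

  cs2 <- primary_case(phi = 0.05, eps_y = 3000)
  tr2 <- simulate_mechanism(cs2$mechanism, cs2$setup, t_end = 100, dt = 0.1)
  expect_error(qy_primary_integrated(tr2, cs2$mechanism, cs2$setup),
               "photoproduct absorbs")
})

test_that("the general integral route solves single steps and exposes the total-absorption bias", {
  # photoreversible: solve the forward yield given the reverse one
  ex <- reference_case()
  tr <- reference_trace()
  m_known <- ex$mechanism
  m_known$steps$phi[1] <- NA_real_
  phi_f <- qy_general_integral(tr, suppressWarnings(
    mechanism(m_known$species, m_known$steps)), ex$setup, step = "X->Y1")
  expect_lt(rel_err(phi_f, 0.062), 0.005)

  # transparent product: reduces to the closed form
  cs <- primary_case(phi = 0.05)
  trp <- simulate_mechanism(cs$mechanism, cs$setup, t_end = 300, dt = 0.1)
  phi_g <- qy_general_integral(trp, cs$mechanism, cs$setup, step = "X->Y1")
  phi_c <- qy_primary_integrated(trp, cs$mechanism, cs$setup)$phi
  expect_lt(rel_err(phi_g, phi_c), 1e-4)
  # ... where the total-absorption convention is also exact
  expect_lt(rel_err(qy_warburg(trp, cs$mechanism, cs$setup), 0.05), 1e-3)

  # absorbing product: dividing by the total absorbed light biases the yield
  cs2 <- primary_case(phi = 0.05, eps_y = 9000)
  tr2 <- simulate_mechanism(cs2$mechanism, cs2$setup, t_end = 300, dt = 0.1)
  phi_ok <- qy_general_integral(tr2, cs2$mechanism, cs2$setup, step = "X->Y1")
  phi_w <- qy_warburg(tr2, cs2$mechanism, cs2$setup)
  expect_lt(rel_err(phi_ok, 0.05), 0.005)
  expect_gt(rel_err(phi_w, 0.05), 0.05)
})

test_that("randomized mechanisms solve end to end within a percent", {
  set.seed(555)
  n_ok <- 0L
  attempts <- 0L
  while (n_ok < 4L && attempts < 15L) {
    attempts <- attempts + 1L
    cs <- random_submechanism(n_products = sample(1:3, 1))
    m <- cs$mechanism
    if (n_steps(m) < n_species(m) - 1L) next
    tr <- simulate_to_steady(m, cs$setup, warn_absorbance = FALSE)
    topo <- m; topo$species$epsilon <- NA_real_; topo$steps$phi <- NA_real_
    rep <- tryCatch(suppressWarnings(solve_intrinsics(
      tr, topo, cs$setup, seed = 60 + n_ok,
      truth = list(epsilon = stats::setNames(m$species$epsilon,
                                             m$species$name),
                   phi = stats::setNames(m$steps$phi, step_labels(m))))),
      error = function(e) NULL)
    if (is.null(rep)) next
    if (any(rep$fit$quality$r2 < 0.999)) next
    expect_lt(max(rep$pct_err$epsilon), 1)
    expect_lt(max(rep$pct_err$phi), 1)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 3L)
})
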
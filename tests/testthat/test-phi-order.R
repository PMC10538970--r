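reference_reactant_model <- function() {
  # the reference fit of the photoreversible reactant trace
  phi_order_model(c_inf = 8.1165e-6, cc = 3.175e-5,
                  omega = c(0.0649, 0.492), k = c(0.09915, 0.04517))
}

test_that("model evaluation reproduces the reference reactant fit", {
  pm <- reference_reactant_model()
  expect_equal(eval_model(pm, 30), 9.91197e-6, tolerance = 1e-10 / 9.9e-6)
  expect_equal(eval_model(pm, 1e9), pm$c_inf)
  pm0 <- phi_order_model(c_inf = 5e-6, cc = 0, omega = 0.1, k = 0.05)
  expect_equal(eval_model(pm0, c(0, 10, 100)), rep(5e-6, 3))
  expect_error(eval_model(pm, -1), "negative time")
})

test_that("the model rate matches its finite-difference and rate-law oracles", {
  pm <- reference_reactant_model()
  # against the reference rate-law value at t = 30 s
  expect_equal(model_rate(pm, 30), -8.35686e-8, tolerance = 1e-2)
  expect_equal(model_rate(pm, 1e9), 0)
  # Richardson-extrapolated central difference of eval_model
  for (t in c(1, 30, 120)) {
    h <- 1e-2
    d1 <- (eval_model(pm, t + h) - eval_model(pm, t - h)) / (2 * h)
    d2 <- (eval_model(pm, t + h / 2) - eval_model(pm, t - h / 2)) / h
    fd <- (4 * d2 - d1) / 3
    expect_equal(model_rate(pm, t), fd, tolerance = 1e-10)
  }
})

test_that("the initial rate has its closed form and matches theory", {
  pm <- reference_reactant_model()
  r0 <- model_initial_rate(pm)
  expect_equal(r0, -3.9515e-7, tolerance = 1e-4)
  # equals the theoretical -phi * P0 * (1 - 10^(-AX0)) within fit rounding
  ax0 <- 12004 * 1.65 * 1.58e-5
  expect_equal(r0, -0.062 * 1.25e-5 * (1 - 10^(-ax0)), tolerance = 1e-2)
  expect_equal(model_rate(pm, 0), model_initial_rate(pm), tolerance = 1e-12)
  expect_equal(model_initial_rate(phi_order_model(1e-5, 0.5)), 0)
})

test_that("a model-generated trace refits to closure", {
  pm <- phi_order_model(c_inf = 0.21, cc = 0.02,
                        omega = c(-1.9, -13.6), k = c(0.099, 0.045))
  t <- seq(0, 200, by = 0.5)
  y <- eval_model(pm, t)
  refit <- fit_total_absorbance(y, t, n_phi = 2, seed = 3)
  yhat <- eval_model(refit, t)
  expect_gt(stats::cor(y, yhat)^2, 1 - 1e-12)
  expect_lt(rel_err(model_initial_rate(refit), model_initial_rate(pm)), 1e-6)
})

test_that("the coupled fit of the photoreversible traces meets the quality bar", {
  cf <- reference_fit()
  q <- cf$quality
  expect_true(all(q$r2 >= 0.999))
  conc_rows <- q$trace %in% c("X", "Y1")
  expect_true(all(q$sse[conc_rows] <= 1e-18))
  expect_true(all(q$rmse[conc_rows] <= 1e-9))
  # both species carry the same coupling factor by protocol
  expect_identical(cf$models$X$cc, cf$models$Y1$cc)
  # the absorbance model reuses the species rate constants exactly
  expect_true(all(cf$atot_model$k %in% cf$k_pool))
})

test_that("initial rates are invariant across fitting seeds despite identifiability", {
  ex <- reference_case()
  cf1 <- reference_fit()
  cf2 <- fit_species_traces(reference_trace(), ex$mechanism, seed = 23)
  r1 <- model_initial_rate(cf1$models$X)
  r2 <- model_initial_rate(cf2$models$X)
  expect_lt(rel_err(r1, r2), 1e-3)
  # parameter sets themselves may differ (many equally good minima)
})

test_that("a cyclic mechanism shares one coupling factor and one k set", {
  cs <- cyclic_case()
  tr <- simulate_to_steady(cs$mechanism, cs$setup, warn_absorbance = FALSE)
  cf <- fit_species_traces(tr, cs$mechanism, seed = 5)
  ccs <- vapply(cf$models, function(pm) pm$cc, 0)
  expect_true(all(ccs == ccs[1]))
  for (pm in cf$models) expect_true(all(pm$k %in% cf$k_pool))
  expect_true(all(cf$quality$r2 >= 0.999))
  # term counts: bounded by the step count, minimal for the reactant
  n_terms <- vapply(cf$models, function(pm) length(pm$k), 0L)
  expect_true(all(n_terms <= n_steps(cs$mechanism)))
  expect_true(all(n_terms["X"] <= n_terms))
})

test_that("the absorbance fit obeys the linear-combination identity for its initial rate", {
  ex <- reference_case()
  cf <- reference_fit()
  r0a <- model_initial_rate(cf$atot_model)
  r0s <- vapply(cf$models, model_initial_rate, 0)
  lhs <- ex$setup$l_irr * sum(ex$mechanism$species$epsilon * r0s)
  expect_lt(rel_err(r0a, lhs), 1e-2)
})

test_that("a constant absorbance series yields a zero-term model", {
  t <- seq(0, 100, 0.5)
  pm <- fit_total_absorbance(rep(0.31294, length(t)), t, n_phi = 3, seed = 1)
  expect_length(pm$k, 0L)
  expect_equal(pm$c_inf, 0.31294)
})

test_that("constraining cc to its true value identifies the primary-process rate constant", {
  cs <- primary_case(phi = 0.05)
  s <- cs$setup
  tr <- simulate_mechanism(cs$mechanism, s, t_end = 200, dt = 0.1)
  ax0 <- 12004 * s$l_irr * 1.58e-5
  cc_true <- 10^ax0 - 1
  y <- tr$conc[, "X"]
  fit <- phikinet:::.po_fit_one(tr$times, y, y[1], n_new = 1, cc = cc_true,
                                n_starts = 16)
  k_true <- 0.05 * 12004 * s$p0 * s$l_irr * log(10)
  expect_lt(rel_err(fit$k, k_true), 1e-3)
})

test_that("fitting guards its preconditions", {
  ex <- reference_case()
  short <- simulate_mechanism(ex$mechanism, ex$setup, t_end = 1, dt = 0.1)
  expect_error(fit_species_traces(short, ex$mechanism), "too short")
})
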
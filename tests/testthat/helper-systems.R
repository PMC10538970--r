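# Reference systems and cached traces shared across test files. All inputs
# are generated in code by the simulator; nothing is read from disk.

.helper_cache <- new.env(parent = emptyenv())

reference_case <- function() photoreversible_example()

reference_topology <- function() {
  m <- photoreversible_example()$mechanism
  m$species$epsilon <- NA_real_
  m$steps$phi <- NA_real_
  suppressWarnings(mechanism(m$species, m$steps))
}

reference_trace <- function() {
  if (is.null(.helper_cache$tr_ref)) {
    ex <- reference_case()
    .helper_cache$tr_ref <- simulate_mechanism(ex$mechanism, ex$setup,
                                                  t_end = 300, dt = 0.1)
  }
  .helper_cache$tr_ref
}

reference_fit <- function() {
  if (is.null(.helper_cache$cf_ref)) {
    ex <- reference_case()
    .helper_cache$cf_ref <- fit_species_traces(reference_trace(), ex$mechanism,
                                                  seed = 7)
  }
  .helper_cache$cf_ref
}

# primary photoprocess X -> Y1; transparent product by default
primary_case <- function(phi = 0.05, eps_x = 12004, eps_y = 0,
                         cx0 = 1.58e-5) {
  m <- mechanism(
    species = data.frame(name = c("X", "Y1"), epsilon = c(eps_x, eps_y),
                         c0 = c(cx0, 0), stringsAsFactors = FALSE),
    steps = data.frame(from = "X", to = "Y1", phi = phi,
                       stringsAsFactors = FALSE))
  list(mechanism = m,
       setup = irradiation_setup(lambda_irr = 365, p0 = 1.25e-5, l_irr = 1.65))
}

# divergent branching Y1 <- X -> Y3
branch_case <- function(phi1 = 0.03, phi3 = 0.05) {
  m <- scheme1_template(c("X->Y1", "X->Y3"),
                        epsilon = c(X = 12004, Y1 = 8000, Y3 = 3000),
                        phi = c(phi1, phi3), c0 = 1.58e-5)
  list(mechanism = m,
       setup = irradiation_setup(lambda_irr = 365, p0 = 1.25e-5, l_irr = 1.65))
}

# three-species cycle X -> Y1 -> Y2 -> X (beyond the template's step set)
cyclic_case <- function() {
  m <- mechanism(species = data.frame(name = c("X", "Y1", "Y2"),
                                      epsilon = c(12004, 18000, 6000),
                                      c0 = c(1.58e-5, 0, 0)),
                 steps = data.frame(from = c("X", "Y1", "Y2"),
                                    to = c("Y1", "Y2", "X"),
                                    phi = c(0.062, 0.12, 0.08)))
  list(mechanism = m,
       setup = irradiation_setup(lambda_irr = 365, p0 = 1.25e-5, l_irr = 1.65))
}

rel_err <- function(a, b) abs(a / b - 1)
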
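#' Physical constants used in photon-flux computations
#'
#' Planck's constant (J s), the speed of light (m s^-1) and Avogadro's
#' number per einstein, hard-coded at the precision used throughout the
#' actinometry formulas so worked values are reproducible to the digit.
#'
#' @format list with elements `h`, `c`, `na`.
#' @export
photon_constants <- list(h = 6.62608e-34, c = 299792458, na = 6.02214e23)

#' Molar photon energy at a wavelength
#'
#' Energy carried by one einstein (one mole of photons):
#' `E_mol = Na * h * c / lambda`, in J einstein^-1.
#'
#' @param lambda_nm wavelength, nm.
#' @return molar photon energy, J einstein^-1.
#' @export
#' @examples
#' molar_photon_energy(400)  # ~ 2.99e5 J/einstein
molar_photon_energy <- function(lambda_nm) {
  stopifnot(all(lambda_nm > 0))
  with(photon_constants, na * h * c / (lambda_nm * 1e-9))
}

#' Lamp specification
#'
#' The quantities needed to convert a lamp's measured spectral irradiance
#' into the incident photon flux of a slab reactor: irradiance at the
#' (monochromatic) irradiation wavelength, irradiated sample area and
#' irradiated volume. For monochromatic light the per-nm dimension of the
#' spectral irradiance is dropped.
#'
#' @param e_sp_irr spectral irradiance at the irradiation wavelength,
#'   J s^-1 cm^-2.
#' @param lambda_irr irradiation wavelength, nm.
#' @param s_irr irradiated sample area, cm^2.
#' @param v_irr irradiated sample volume, dm^3.
#' @param l_irr optional irradiation path length, cm; when given, a warning
#'   is issued if `v_irr / s_irr` (in cm) is smaller than `l_irr`, which is
#'   geometrically inconsistent for a slab reactor.
#' @return an object of class `lamp_spec`.
#' @export
lamp_spec <- function(e_sp_irr, lambda_irr, s_irr, v_irr, l_irr = NULL) {
  stopifnot(e_sp_irr > 0, lambda_irr > 0, s_irr > 0, v_irr > 0)
  if (!is.null(l_irr) && (v_irr * 1000 / s_irr) < l_irr) {
    warning("v_irr / s_irr is smaller than l_irr: geometry inconsistent for a slab reactor",
            call. = FALSE)
  }
  structure(list(e_sp_irr = e_sp_irr, lambda_irr = lambda_irr,
                 s_irr = s_irr, v_irr = v_irr, l_irr = l_irr),
            class = "lamp_spec")
}

#' Incident photon flux from a lamp specification
#'
#' Chains the conversions: photon flux per unit area
#' `flx = E_sp * lambda / (Na h c)` (einstein s^-1 cm^-2), multiplied by the
#' irradiated area and divided by the irradiated volume:
#' `P0 = flx * S_irr / V_irr` in einstein s^-1 dm^-3. This differs from the
#' IUPAC `q_(n,p)/V` convention by the factor `S_irr` (the two coincide for
#' an irradiated area of 1 cm^2); both are reported.
#'
#' @param ls a [lamp_spec()].
#' @return list with `p0` (einstein s^-1 dm^-3), `flx` (einstein s^-1
#'   cm^-2), `e_mol` (J einstein^-1) and `qnp_over_v` (the IUPAC
#'   convention, einstein s^-1 dm^-3).
#' @export
photon_flux <- function(ls) {
  e_mol <- molar_photon_energy(ls$lambda_irr)
  flx <- ls$e_sp_irr / e_mol
  list(p0 = flx * ls$s_irr / ls$v_irr, flx = flx, e_mol = e_mol,
       qnp_over_v = flx / ls$v_irr)
}

#' Kinactinometry: photon flux from photokinetic data
#'
#' Inverts the initial-rate law of a standardized reaction: with the summed
#' quantum yields of the steps leaving the reactant and its initial
#' absorbance known,
#' `P0 = -r0X / (phi_sum * (1 - 10^(-AX0)))`. The initial rate can come
#' from the theoretical rate law, a Phi-order trace fit (the identifiable
#' route for measured data) or the numerical trace.
#'
#' @param r0x initial reactant rate, M s^-1 (strictly negative).
#' @param phi_sum summed quantum yields of the steps leaving the reactant.
#' @param ax0 initial reactant absorbance at the irradiation wavelength.
#' @return incident photon flux P0, einstein s^-1 dm^-3.
#' @export
kinactinometry <- function(r0x, phi_sum, ax0) {
  if (r0x >= 0) stop("r0x must be negative (the reactant is consumed)")
  if (phi_sum <= 0) stop("phi_sum must be positive")
  if (ax0 <= 0) stop("ax0 must be positive")
  -r0x / (phi_sum * -expm1(-ax0 * log(10)))
}

#' Actinometer calibration lines against photon flux
#'
#' From a series of runs differing only in the incident photon flux, fits
#' ordinary least-squares lines (with intercept, so a non-zero intercept is
#' a visible diagnostic) of every fitted rate constant, every species'
#' initial rate, and the total-absorbance initial rate against P0. For a
#' valid actinometer all lines are linear through the origin, while the
#' final concentrations, weights and coupling factor are invariant across
#' runs; the largest relative spread of the final values is reported.
#'
#' @param runs list of runs; each a list with elements `p0` and `fit` (a
#'   `coupled_fit`). At least three runs are required.
#' @return list with `lines` (data frame: `quantity`, `slope`, `intercept`,
#'   `r2`) and `c_inf_spread` (max relative spread of each species' final
#'   concentration across runs).
#' @export
calibrate_actinometer <- function(runs) {
  if (length(runs) < 3L) stop("need at least 3 runs at different P0")
  p0 <- vapply(runs, function(r) r$p0, 0)
  if (length(unique(p0)) < 3L) stop("rank-deficient input: P0 values must differ")
  sp_names <- names(runs[[1L]]$fit$models)

  ln <- function(y, label) {
    f <- stats::lm(y ~ p0)
    # squared correlation (summary.lm warns on numerically perfect lines)
    r2 <- stats::cor(y, stats::fitted(f))^2
    data.frame(quantity = label, slope = unname(stats::coef(f)[2L]),
               intercept = unname(stats::coef(f)[1L]),
               r2 = r2, stringsAsFactors = FALSE)
  }
  lines <- list()
  # rate constants: pool sorted decreasing, matched by rank across runs
  nk <- min(vapply(runs, function(r) length(r$fit$k_pool), 0L))
  for (i in seq_len(nk)) {
    ki <- vapply(runs, function(r) sort(r$fit$k_pool, decreasing = TRUE)[i], 0)
    lines[[length(lines) + 1L]] <- ln(ki, paste0("k", i))
  }
  for (sp in sp_names) {
    r0 <- vapply(runs, function(r) model_initial_rate(r$fit$models[[sp]]), 0)
    lines[[length(lines) + 1L]] <- ln(r0, paste0("r0_", sp))
  }
  if (!is.null(runs[[1L]]$fit$atot_model)) {
    r0a <- vapply(runs, function(r) model_initial_rate(r$fit$atot_model), 0)
    lines[[length(lines) + 1L]] <- ln(r0a, "r0_Atot")
  }
  cinf <- vapply(runs, function(r)
    vapply(r$fit$models, function(pm) pm$c_inf, 0), numeric(length(sp_names)))
  cinf <- matrix(cinf, nrow = length(sp_names))
  # spread relative to the conserved total, so a fully depleted species
  # (final concentration ~ 0) does not blow up the ratio
  scale <- max(colSums(abs(cinf)))
  spread <- apply(cinf, 1L, function(v) {
    if (scale == 0) 0 else (max(v) - min(v)) / scale
  })
  list(lines = do.call(rbind, lines),
       c_inf_spread = stats::setNames(spread, sp_names))
}

#' Simulate and fit a photon-flux calibration grid
#'
#' Helper producing the input for [calibrate_actinometer()]: simulates the
#' mechanism at each photon flux and fits all traces. After the first grid
#' point the fits are warm-started from the previous solution with the rate
#' constants pre-scaled by the flux ratio (the exact time-rescaling property
#' of the rate law), which keeps the rate constants on one solution branch
#' so their linearity in P0 is observable.
#'
#' @param m a [mechanism()].
#' @param s an [irradiation_setup()] whose `p0` is replaced by each grid
#'   value.
#' @param p0_values photon fluxes, einstein s^-1 dm^-3 (at least 3).
#' @param seed,dt,n_starts simulation and fitting controls.
#' @return list of runs suitable for [calibrate_actinometer()]; each run
#'   also carries the trace's reactant `t_half`.
#' @export
p0_calibration_runs <- function(m, s, p0_values, seed = 1L, dt = 0.1,
                                n_starts = 32L) {
  stopifnot(length(p0_values) >= 3L)
  runs <- vector("list", length(p0_values))
  prev_fit <- NULL
  prev_p0 <- NULL
  for (i in seq_along(p0_values)) {
    s2 <- s
    s2$p0 <- p0_values[i]
    tr <- simulate_to_steady(m, s2, dt = dt, warn_absorbance = FALSE)
    if (is.null(prev_fit)) {
      cf <- fit_species_traces(tr, m, seed = seed, n_starts = n_starts)
    } else {
      cf <- .refit_scaled(tr, m, prev_fit, p0_values[i] / prev_p0)
    }
    prev_fit <- cf
    prev_p0 <- p0_values[i]
    runs[[i]] <- list(p0 = p0_values[i], fit = cf, t_half = half_life(tr))
  }
  runs
}

# re-fit a coupled fit after a photon-flux change: the rate law scales time
# by the flux ratio, so k -> k * ratio with cc unchanged is already a
# solution; re-solving the (linear) weights on the new trace is all that is
# needed.
.refit_scaled <- function(tr, m, prev, ratio) {
  idx <- unique(round(seq(1L, length(tr$times), length.out =
                            min(400L, length(tr$times)))))
  tfit <- tr$times[idx]
  k_map <- sort(prev$k_pool, decreasing = TRUE) * ratio
  models <- prev$models
  qual <- list()
  for (j in seq_along(models)) {
    y <- tr$conc[, j]
    pmv <- prev$models[[j]]
    kj <- pmv$k * ratio
    G <- .po_basis(tfit, prev$cc, kj)
    w <- .po_lstsq(G, y[idx] - y[1L])
    pm <- phi_order_model(y[1L] - sum(w) * log10(1 + prev$cc), prev$cc, w, kj)
    models[[j]] <- pm
    q <- .po_quality(pm, tr$times, y)
    qual[[j]] <- data.frame(trace = names(models)[j], n_terms = length(kj),
                            r2 = q$r2, sse = q$sse, rmse = q$rmse,
                            stringsAsFactors = FALSE)
  }
  atot_model <- NULL
  if (!is.null(prev$atot_model) && !is.null(tr$atot)) {
    pa <- prev$atot_model
    if (length(pa$k)) {
      ka <- pa$k * ratio
      G <- .po_basis(tfit, pa$cc, ka)
      w <- .po_lstsq(G, tr$atot[idx] - tr$atot[1L])
      atot_model <- phi_order_model(tr$atot[1L] - sum(w) * log10(1 + pa$cc),
                                    pa$cc, w, ka)
    } else {
      atot_model <- pa
    }
  }
  structure(list(models = models, atot_model = atot_model, cc = prev$cc,
                 k_pool = k_map, quality = do.call(rbind, qual),
                 seed = prev$seed, n_starts = 1L),
            class = "coupled_fit")
}
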
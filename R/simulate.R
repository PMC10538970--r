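#' Photokinetic factor
#'
#' The dimensionless factor `(1 - 10^(-Atot)) / Atot` that multiplies every
#' absorbed-light term in the photokinetic rate law and makes it nonlinear.
#' It is continuous at zero total absorbance, where it tends to `ln(10)`,
#' and strictly decreasing in `Atot` (computed through `expm1` so the limit
#' is reached smoothly, with no series switch-over).
#'
#' @param atot total absorbance of the medium at the irradiation wavelength
#'   (dimensionless, non-negative); vectorized.
#' @return the photokinetic factor, same length as `atot`.
#' @export
#' @examples
#' photokinetic_factor(0)      # ln(10)
#' photokinetic_factor(1)      # 0.9
photokinetic_factor <- function(atot) {
  if (any(atot < 0)) stop("negative total absorbance")
  ifelse(atot == 0, log(10), -expm1(-atot * log(10)) / atot)
}

#' Light absorbed by one species
#'
#' Each absorbing species captures a share of the total absorbed photon flux
#' proportional to its own absorbance:
#' `Pa = A_species * P0 * PKF(Atot)`. Summed over every absorber (including
#' spectators) this equals the total absorbed flux `P0 * (1 - 10^(-Atot))`.
#'
#' @param a_species absorbance of the species at the irradiation wavelength.
#' @param atot total absorbance of the medium (must be >= `a_species`).
#' @param p0 incident photon flux, einstein s^-1 dm^-3.
#' @return absorbed photon flux, einstein s^-1 dm^-3.
#' @export
absorbed_light <- function(a_species, atot, p0) {
  stopifnot(p0 > 0)
  if (any(a_species < 0)) stop("negative species absorbance")
  if (any(a_species > atot * (1 + 1e-12) + 1e-15)) {
    stop("species absorbance exceeds total absorbance")
  }
  a_species * p0 * photokinetic_factor(atot)
}

# closure evaluating species absorbances, Atot, Pa and rates; built once per
# simulation so the RK inner loop does no bookkeeping
.make_rate_fn <- function(m, s) {
  eps <- m$species$epsilon
  l <- s$l_irr
  p0 <- s$p0
  a_spm <- sum(m$spectators$absorbance)
  from_i <- match(m$steps$from, m$species$name)
  to_i <- match(m$steps$to, m$species$name)
  phi <- m$steps$phi
  nsp <- nrow(m$species)
  function(conc) {
    a <- eps * l * conc
    atot <- sum(a) + a_spm
    pa <- a * p0 * photokinetic_factor(max(atot, 0))
    flux <- phi * pa[from_i]            # M/s converted by each step
    r <- numeric(nsp)
    for (k in seq_along(flux)) {
      r[from_i[k]] <- r[from_i[k]] - flux[k]
      r[to_i[k]] <- r[to_i[k]] + flux[k]
    }
    r
  }
}

#' Photokinetic rate law
#'
#' Evaluates the rate of every species for a given concentration state. For
#' species j the rate collects, over the declared steps, the loss through
#' steps leaving j (`-Phi * Pa_j`) and the gain through steps arriving at j
#' (`+Phi * Pa_source`), where each absorbed flux is computed with
#' [absorbed_light()] from the current absorbances. Spectator absorbances
#' enter the total absorbance (they compete for photons) but spectators have
#' no rate of their own. The rates always sum to zero (mass conservation).
#'
#' @param m a [mechanism()].
#' @param s an [irradiation_setup()].
#' @param conc concentration vector (M), in mechanism species order.
#' @return named rate vector, M s^-1.
#' @export
rate_law <- function(m, s, conc) {
  if (length(conc) != n_species(m)) stop("dimension mismatch: conc vs species")
  stats::setNames(.make_rate_fn(m, s)(conc), m$species$name)
}

#' Simulate a photoreaction with fixed-step fourth-order Runge-Kutta
#'
#' Integrates the photokinetic rate law from the mechanism's declared
#' initial concentrations on a fixed grid `seq(0, t_end, dt)` using the
#' classic RK4 scheme (via [deSolve::rk4()]). Fixed stepping keeps traces
#' bit-reproducible; the default `dt` of 0.1 s resolves the fastest regimes
#' of typical drug-photodegradation experiments.
#'
#' Concentrations in `[-1e-12, 0)` arising from roundoff are clamped to
#' zero; larger negative excursions abort with a suggestion to reduce `dt`.
#' A single warning is emitted if the total absorbance ever exceeds 0.5,
#' the usual guideline for staying within calibration linearity ranges.
#'
#' @param m a [mechanism()] (no `NA` placeholders).
#' @param s an [irradiation_setup()].
#' @param t_end end time, s.
#' @param dt time step, s; a warning is issued outside the (0, 5] range
#'   recommended for these reactions.
#' @param warn_absorbance warn when `Atot(t)` exceeds 0.5 (default TRUE).
#' @return a `kinetic_trace`: list with `times` (s), `conc` (matrix, one
#'   column per species, M) and `atot` (total absorbance at the irradiation
#'   wavelength and path, including spectators).
#' @export
simulate_mechanism <- function(m, s, t_end, dt = 0.1, warn_absorbance = TRUE) {
  stopifnot(t_end > 0, dt > 0)
  if (dt > 5) warning("dt above the 5 s recommended upper bound", call. = FALSE)
  if (anyNA(m$species$epsilon) || anyNA(m$species$c0) || anyNA(m$steps$phi)) {
    stop("mechanism has NA placeholders; fill them before simulating")
  }
  rate <- .make_rate_fn(m, s)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  out <- deSolve::rk4(y = m$species$c0, times = times,
                      func = function(t, y, p) list(rate(y)), parms = NULL)
  conc <- unname(out[, -1L, drop = FALSE])
  if (any(conc < -1e-12)) {
    stop("negative concentration beyond roundoff tolerance; use a smaller dt")
  }
  conc[conc < 0] <- 0
  colnames(conc) <- m$species$name
  tr <- structure(list(times = times, conc = conc,
                       atot = .atot_from_conc(conc, m, s)),
                  class = "kinetic_trace")
  if (warn_absorbance && any(tr$atot > 0.5)) {
    warning(sprintf("Atot reaches %.3f (> 0.5): concentrations may leave calibration linearity ranges",
                    max(tr$atot)), call. = FALSE)
  }
  tr
}

.atot_from_conc <- function(conc, m, s) {
  as.vector(conc %*% (m$species$epsilon * s$l_irr)) + sum(m$spectators$absorbance)
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, t in [0, %g] s, species: %s\n",
              length(x$times), max(x$times),
              paste(colnames(x$conc), collapse = ", ")))
  invisible(x)
}

#' Total absorbance series of a trace
#'
#' Recomputes the total absorbance at the irradiation wavelength from the
#' concentration columns: the sum of every species' `epsilon * l * C(t)`
#' plus the constant spectator absorbances. With `l_obs` differing from the
#' irradiation path, the series is returned on the observation path scale
#' (`Atot * l_obs / l_irr`); multiplying back by `l_irr / l_obs` restores
#' the irradiation-path series used by all rate-law equations.
#'
#' @param tr a `kinetic_trace` whose columns match the mechanism.
#' @param m a [mechanism()].
#' @param s an [irradiation_setup()].
#' @param l_obs observation path length, cm (default: the irradiation path).
#' @return numeric absorbance series.
#' @export
total_absorbance_trace <- function(tr, m, s, l_obs = s$l_irr) {
  stopifnot(identical(colnames(tr$conc), m$species$name))
  .atot_from_conc(tr$conc, m, s) * (l_obs / s$l_irr)
}

#' Rescale an absorbance between optical paths
#'
#' @param a absorbance values.
#' @param l_from path length the values were measured at, cm.
#' @param l_to path length to rescale to, cm.
#' @return rescaled absorbance.
#' @export
rescale_absorbance <- function(a, l_from, l_to) a * (l_to / l_from)

#' Photostationary (or final) state of a mechanism
#'
#' For the two-species photoreversible couple the closed form is used: the
#' forward and reverse photon fluxes balance when
#' `C_Y1 / C_X = (Phi_f * eps_X) / (Phi_b * eps_Y1)`, with the pair summing
#' to the initial reactant concentration. Any other mechanism is integrated
#' until the largest rate magnitude falls below `rate_tol` (steady state) or
#' `t_max` is reached (convergence failure).
#'
#' @param m a [mechanism()].
#' @param s an [irradiation_setup()].
#' @param rate_tol steady-state detection threshold, M s^-1.
#' @param dt integration step for the long-time limit, s.
#' @param t_max time budget for the long-time limit, s.
#' @param closed_form use the photoreversible closed form when applicable
#'   (default TRUE); set FALSE to force the RK limit.
#' @return named concentration vector at the stationary state, M.
#' @export
photostationary_state <- function(m, s, rate_tol = 1e-15, dt = 0.1,
                                  t_max = 1e5, closed_form = TRUE) {
  cx0 <- sum(m$species$c0)
  if (closed_form && n_species(m) == 2L && n_steps(m) == 2L &&
      all(sort(step_labels(m)) == sort(c(
        paste0(m$species$name[1], "->", m$species$name[2]),
        paste0(m$species$name[2], "->", m$species$name[1]))))) {
    fwd <- m$steps$phi[m$steps$from == m$species$name[1]]
    bwd <- m$steps$phi[m$steps$from == m$species$name[2]]
    eps <- m$species$epsilon
    if (eps[2] > 0 && bwd > 0) {
      ratio <- (fwd * eps[1]) / (bwd * eps[2])   # C_Y1_inf / C_X_inf
      cx <- cx0 / (1 + ratio)
      return(stats::setNames(c(cx, cx0 - cx), m$species$name))
    }
  }
  # irreversible sink shortcut: if nothing leaves the terminal species set,
  # the RK limit still applies; integrate in chunks
  rate <- .make_rate_fn(m, s)
  conc <- m$species$c0
  t_done <- 0
  chunk <- max(200 * dt, 50)
  while (t_done < t_max) {
    out <- deSolve::rk4(y = conc, times = seq(0, chunk, by = dt),
                        func = function(t, y, p) list(rate(y)), parms = NULL)
    conc <- pmax(unname(out[nrow(out), -1L]), 0)
    t_done <- t_done + chunk
    if (max(abs(rate(conc))) < rate_tol) {
      return(stats::setNames(conc, m$species$name))
    }
    chunk <- min(chunk * 2, t_max - t_done + dt)
  }
  stop(sprintf("no steady state within t_max = %g s (max |rate| = %.3g M/s)",
               t_max, max(abs(rate(conc)))))
}

#' Simulate until the reaction has effectively reached its final state
#'
#' Convenience wrapper around [simulate_mechanism()] that extends the time
#' horizon until the largest rate magnitude has dropped below `rel_tol`
#' times its initial value, then returns one trace covering the whole
#' approach to the plateau (at least several half-lives, as required for
#' trace fitting).
#'
#' @inheritParams simulate_mechanism
#' @param dt time step, s; `NULL` (default) picks a step within the
#'   recommended 0.1-5 s band from the initial rate scale, so slow systems
#'   do not force hundreds of thousands of integration steps.
#' @param rel_tol stop when `max|rate|` falls below `rel_tol * max|rate(0)|`.
#' @param t_cap hard cap on the horizon, s.
#' @return a `kinetic_trace`.
#' @export
simulate_to_steady <- function(m, s, dt = NULL, rel_tol = 1e-4, t_cap = 36000,
                               warn_absorbance = TRUE) {
  rate <- .make_rate_fn(m, s)
  r0 <- max(abs(rate(m$species$c0)))
  if (is.null(dt)) {
    t_scale <- if (r0 > 0) sum(m$species$c0) / r0 else Inf
    dt <- min(5, max(0.1, t_scale / 500))
  }
  if (r0 == 0) return(simulate_mechanism(m, s, t_end = 10 * dt, dt = dt,
                                         warn_absorbance = warn_absorbance))
  t_end <- 100 * dt
  repeat {
    tr <- simulate_mechanism(m, s, t_end = t_end, dt = dt,
                             warn_absorbance = FALSE)
    rend <- max(abs(rate(tr$conc[nrow(tr$conc), ])))
    if (rend <= rel_tol * r0 || t_end >= t_cap) break
    t_end <- min(t_end * 3, t_cap)
  }
  if (warn_absorbance && any(tr$atot > 0.5)) {
    warning(sprintf("Atot reaches %.3f (> 0.5)", max(tr$atot)), call. = FALSE)
  }
  tr
}

#' Half-life of the reactant
#'
#' Defined operationally as the first time the reactant concentration
#' reaches the midpoint between its initial and final values, located by
#' linear interpolation on the trace grid.
#'
#' @param tr a `kinetic_trace`.
#' @param c_inf final reactant concentration; defaults to the last trace
#'   value.
#' @return time in seconds (NA if the midpoint is never reached).
#' @export
half_life <- function(tr, c_inf = NULL) {
  cx <- tr$conc[, 1L]
  if (is.null(c_inf)) c_inf <- cx[length(cx)]
  target <- (cx[1L] + c_inf) / 2
  below <- which(cx <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(0)
  t0 <- tr$times[i - 1L]; t1 <- tr$times[i]
  c0 <- cx[i - 1L]; c1 <- cx[i]
  t0 + (target - c0) / (c1 - c0) * (t1 - t0)
}

#' Read / write kinetic traces as CSV
#'
#' The on-disk format is a plain CSV with header
#' `t_s,C_<name>,...,A_tot`; times in seconds, concentrations in M, values
#' written at 17 significant digits so the round trip is lossless.
#'
#' @param tr a `kinetic_trace`.
#' @param file path.
#' @return `read_trace` returns a `kinetic_trace`; `write_trace` returns
#'   `file` invisibly.
#' @export
write_trace <- function(tr, file) {
  df <- data.frame(t_s = tr$times, tr$conc, check.names = FALSE)
  names(df) <- c("t_s", paste0("C_", colnames(tr$conc)))
  if (!is.null(tr$atot)) df$A_tot <- tr$atot
  txt <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = TRUE), character(nrow(df)))
  utils::write.table(txt, file, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = names(df))
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  stopifnot(names(df)[1L] == "t_s")
  cc <- grepl("^C_", names(df))
  conc <- as.matrix(df[, cc, drop = FALSE])
  colnames(conc) <- sub("^C_", "", names(df)[cc])
  structure(list(times = df$t_s, conc = conc,
                 atot = if ("A_tot" %in% names(df)) df$A_tot else NULL),
            class = "kinetic_trace")
}
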
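#' Phi-order trace model
#'
#' The unifying integrated rate-law model for photoreaction traces under
#' non-isosbestic monochromatic light. A species' concentration (or a total
#' absorbance, in absorbance units) is described by
#'
#'   C(t) = C_inf + sum_i omega_i * Log10(1 + cc * exp(-k_i * t))
#'
#' with a final value `C_inf`, one positive rate constant `k_i` per kinetic
#' regime, pre-logarithmic weights `omega_i` of either sign, and a single
#' pre-exponential coupling factor `cc` shared by all terms of the model
#' (and, within a coupled fit, by every species of the mechanism).
#'
#' @param c_inf final value (M, or absorbance units for a total-absorbance
#'   model); non-negative for concentration models.
#' @param cc coupling factor, dimensionless; must exceed -1 so the logarithm
#'   argument stays positive for all t >= 0.
#' @param omega weights, one per term (may be empty for a constant model).
#' @param k rate constants, s^-1, one per term, all positive.
#' @return an object of class `phi_order_model`.
#' @export
phi_order_model <- function(c_inf, cc, omega = numeric(), k = numeric()) {
  stopifnot(length(omega) == length(k), cc > -1, all(k > 0))
  structure(list(c_inf = as.numeric(c_inf), cc = as.numeric(cc),
                 omega = as.numeric(omega), k = as.numeric(k)),
            class = "phi_order_model")
}

#' @export
print.phi_order_model <- function(x, ...) {
  cat(sprintf("<phi_order_model> %d term(s), cc=%.4g, c_inf=%.6g\n",
              length(x$k), x$cc, x$c_inf))
  if (length(x$k)) {
    for (i in seq_along(x$k)) {
      cat(sprintf("  omega=%+.6g  k=%.6g /s\n", x$omega[i], x$k[i]))
    }
  }
  invisible(x)
}

#' Evaluate a Phi-order model
#'
#' @param pm a [phi_order_model()].
#' @param t times, s (non-negative).
#' @return model values at `t`.
#' @export
eval_model <- function(pm, t) {
  if (any(t < 0)) stop("negative time")
  if (!length(pm$k)) return(rep(pm$c_inf, length(t)))
  x <- pm$cc * exp(-outer(t, pm$k))
  if (any(x <= -1)) stop("logarithm argument not positive")
  pm$c_inf + as.vector(log1p(x) %*% pm$omega) / log(10)
}

#' Rate of a Phi-order model
#'
#' The analytic time derivative of [eval_model()]:
#' `-sum_i omega_i * cc * k_i * exp(-k_i t) / ((1 + cc * exp(-k_i t)) * ln 10)`.
#'
#' @inheritParams eval_model
#' @return model rate at `t`, M s^-1 (or absorbance s^-1).
#' @export
model_rate <- function(pm, t) {
  if (any(t < 0)) stop("negative time")
  if (!length(pm$k)) return(rep(0, length(t)))
  e <- exp(-outer(t, pm$k))
  num <- sweep(e, 2L, pm$omega * pm$cc * pm$k, `*`)
  -as.vector(rowSums(num / (1 + pm$cc * e))) / log(10)
}

#' Initial rate of a Phi-order model
#'
#' [model_rate()] at t = 0 in closed form:
#' `-(1/ln 10) * (cc / (1 + cc)) * sum_i omega_i * k_i`. This quantity is
#' invariant across the many equally good parameter sets the fit can return
#' (the identifiability issue), which is what makes it the preferred
#' photokinetic metric.
#'
#' @param pm a [phi_order_model()].
#' @return initial rate, M s^-1.
#' @export
model_initial_rate <- function(pm) {
  if (!length(pm$k)) return(0)
  -(1 / log(10)) * (pm$cc / (1 + pm$cc)) * sum(pm$omega * pm$k)
}

## ---- fitting machinery ----------------------------------------------------

# Eq-7-constrained basis: g_i(t) = Log10(1+cc e^{-k_i t}) - Log10(1+cc),
# so that y0 + G w satisfies the initial-value identity exactly for any w.
.po_basis <- function(t, cc, k) {
  L0 <- log1p(cc)
  G <- vapply(k, function(ki) (log1p(cc * exp(-ki * t)) - L0) / log(10),
              numeric(length(t)))
  if (!is.matrix(G)) G <- matrix(G, nrow = length(t))
  G
}

.po_lstsq <- function(G, b) {
  w <- stats::lm.fit(G, b)$coefficients
  w[is.na(w)] <- 0
  unname(w)
}

# single trace fit with variable projection: LM searches only the nonlinear
# parameters (cc unless fixed, and any new k); the weights (and, through the
# initial-value constraint, C_inf) are eliminated by exact linear least
# squares inside the residual. With keep > 1 the distinct multi-start minima
# are returned ranked by SSE (the identifiability issue makes several minima
# equally acceptable; downstream couplings may prefer a non-first one).
.po_fit_one <- function(t, y, y0, n_new, cc = NULL, k_fixed = numeric(),
                        n_starts = 32L, k_range = c(1e-4, 1e1),
                        cc_range = c(1e-6, 1e2), maxiter = 200L, keep = 1L) {
  b <- y - y0
  cc_free <- is.null(cc)

  build <- function(p) {
    ccv <- if (cc_free) expm1(p[1L]) else cc
    k_new <- if (n_new) exp(p[(1L + cc_free):(n_new + cc_free)]) else numeric()
    list(cc = ccv, k = c(k_fixed, k_new))
  }
  finish <- function(par, sse) {
    pr <- build(par)
    G <- .po_basis(t, pr$cc, pr$k)
    w <- .po_lstsq(G, b)
    list(cc = pr$cc, k = pr$k, omega = w, sse = sse)
  }
  resid_fn <- function(p) {
    pr <- build(p)
    G <- .po_basis(t, pr$cc, pr$k)
    as.vector(G %*% .po_lstsq(G, b)) - b
  }

  if (!cc_free && n_new == 0L) {           # fully linear: exact solve
    G <- .po_basis(t, cc, k_fixed)
    w <- .po_lstsq(G, b)
    sse <- sum((as.vector(G %*% w) - b)^2)
    fit <- list(cc = cc, k = k_fixed, omega = w, sse = sse)
    return(if (keep > 1L) list(fit) else fit)
  }

  sols <- list()
  for (i in seq_len(n_starts)) {
    p0 <- numeric()
    if (cc_free) p0 <- log1p(10^stats::runif(1, log10(cc_range[1]), log10(cc_range[2])))
    if (n_new) p0 <- c(p0, log(sort(10^stats::runif(n_new, log10(k_range[1]),
                                                    log10(k_range[2])),
                                    decreasing = TRUE)))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sols[[length(sols) + 1L]] <- list(par = fit$par, sse = sum(fit$fvec^2))
  }
  if (!length(sols)) stop("trace fit failed to converge from any start")
  sols <- sols[order(vapply(sols, function(s) s$sse, 0))]
  # basin refinement: restart a few times from jittered copies of the best
  # minimum, which reliably escapes the near-flat regions where a regime's
  # weight collapsed to zero
  for (i in seq_len(8L)) {
    p0 <- sols[[1L]]$par + stats::rnorm(length(sols[[1L]]$par), 0, 0.3)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (sse < sols[[1L]]$sse) {
      sols <- c(list(list(par = fit$par, sse = sse)), sols)
    }
  }
  if (keep <= 1L) return(finish(sols[[1L]]$par, sols[[1L]]$sse))
  # deduplicate near-identical minima by parameter distance
  out <- list()
  for (s in sols) {
    dup <- any(vapply(out, function(o)
      length(o$par) == length(s$par) && max(abs(o$par - s$par)) < 1e-4, TRUE))
    if (!dup) out[[length(out) + 1L]] <- c(s, list(fit = finish(s$par, s$sse)))
    if (length(out) >= keep) break
  }
  lapply(out, function(o) o$fit)
}

.po_as_model <- function(fit, y0) {
  phi_order_model(y0 - sum(fit$omega) * log10(1 + fit$cc),
                  fit$cc, fit$omega, fit$k)
}

# second-order one-sided estimate of the initial slope from the first three
# points of the dense grid; used as a data-driven consistency check that
# discards fit minima whose spurious fast regimes distort the model's
# initial rate while leaving the residual untouched
.po_r0_stencil <- function(times, y) {
  dt <- times[2L] - times[1L]
  (-3 * y[1L] + 4 * y[2L] - y[3L]) / (2 * dt)
}

.po_quality <- function(pm, t, y) {
  yhat <- eval_model(pm, t)
  rmse <- sqrt(mean((yhat - y)^2))
  r2 <- if (stats::sd(y) < 1e-300 || stats::sd(yhat) < 1e-300) {
    if (rmse <= 1e-12 * max(abs(y), 1e-300)) 1 else 0
  } else {
    stats::cor(y, yhat)^2
  }
  list(r2 = r2, sse = sum((yhat - y)^2), rmse = rmse)
}

# drop terms whose contribution to the trace is far below the accepted noise
# floor, re-solving the (linear) weights; never drops below n_min terms.
# Terms whose whole contribution to the trace sits below the accepted error
# floor are statistically zero, yet when their rate constant is large they
# still distort the model's initial slope (slope harm scales with
# k * amplitude). Drop them, smallest contribution first, as long as the
# refitted residual does not meaningfully degrade.
.po_prune <- function(fit, t, b, rmse_tol, n_min = 0L) {
  repeat {
    if (length(fit$k) <= n_min) return(fit)
    G <- .po_basis(t, fit$cc, fit$k)
    rmse_now <- sqrt(mean((as.vector(G %*% fit$omega) - b)^2))
    contrib <- vapply(seq_along(fit$k),
                      function(i) max(abs(fit$omega[i] * G[, i])), 0)
    drop_i <- which(contrib < rmse_tol)
    if (!length(drop_i)) return(fit)
    i <- drop_i[which.min(contrib[drop_i])]
    k2 <- fit$k[-i]
    G2 <- .po_basis(t, fit$cc, k2)
    w2 <- .po_lstsq(G2, b)
    rmse2 <- sqrt(mean((as.vector(G2 %*% w2) - b)^2))
    if (rmse2 > max(rmse_tol, 1.02 * rmse_now)) return(fit)
    fit$k <- k2; fit$omega <- w2
    fit$sse <- rmse2^2 * length(b)
  }
}

#' Fit all species traces of a mechanism with coupled Phi-order models
#'
#' Implements the sequential coupled fitting protocol. The reactant trace is
#' fitted first, with as many terms as there are steps touching the reactant
#' (escalating one term at a time if the quality thresholds are not met);
#' its coupling factor `cc` is then shared, fixed, by every subsequent
#' species. Species are visited in breadth-first order from the reactant;
#' each inherits the pool of rate constants found so far (kept fixed, which
#' makes its fit an exact linear solve) and may add new regimes up to the
#' total number of reaction steps. The initial-value identity (the model at
#' t = 0 equals the trace's initial value) is built into the basis, not
#' penalised. When the trace carries a total-absorbance series it is fitted
#' last with the shared rate constants but its own coupling factor.
#'
#' The Levenberg-Marquardt search runs over the nonlinear parameters only
#' (coupling factor and new rate constants); weights and final values are
#' eliminated by exact linear least squares (variable projection). Because
#' many distinct parameter sets fit equally well, the multi-start (seeded,
#' reproducible) selects the best sum of squares; invariant quantities
#' (initial rates, shared rate constants) do not depend on which minimum is
#' returned.
#'
#' @param tr a `kinetic_trace` from [simulate_mechanism()] (or read from
#'   CSV) whose columns match the mechanism species.
#' @param m the [mechanism()] (used for its topology: term counts and
#'   fitting order; intrinsic values are not consulted).
#' @param seed integer seed controlling the multi-start draws.
#' @param n_starts number of multi-start runs per nonlinear fit.
#' @param r2_min,rmse_rel quality thresholds: minimum squared correlation
#'   and maximum root-mean-square error relative to the conserved total
#'   concentration for species traces, or to the series' own scale for a
#'   total-absorbance trace (the default reproduces an absolute RMSE of
#'   1e-9 M on a 1.58e-5 M concentration scale).
#' @param max_points fits use at most this many (evenly spaced) trace
#'   points; quality is always reported on the full grid.
#' @param fit_atot also fit the total absorbance series when present.
#' @param k_range,cc_range log-uniform multi-start ranges for rate constants
#'   (s^-1) and the coupling factor.
#' @return a `coupled_fit`: list with `models` (one [phi_order_model()] per
#'   species), `atot_model` (or NULL), shared `cc`, the `k_pool`, a
#'   `quality` data frame (per-trace r2, SSE, RMSE, term count), and the
#'   seed/start bookkeeping.
#' @export
fit_species_traces <- function(tr, m, seed = 1L, n_starts = 32L,
                               r2_min = 0.999, rmse_rel = 1e-9 / 1.58e-5,
                               max_points = 400L,
                               fit_atot = !is.null(tr$atot),
                               k_range = c(1e-4, 1e1),
                               cc_range = c(1e-6, 1e2)) {
  stopifnot(identical(colnames(tr$conc), m$species$name))
  n_phi <- n_steps(m)
  if (length(tr$times) < 10L * n_phi) {
    stop("trace too short: need at least 10 points per reaction step")
  }
  set.seed(as.integer(seed))
  idx <- unique(round(seq(1L, length(tr$times), length.out =
                            min(max_points, length(tr$times)))))
  tfit <- tr$times[idx]

  if (fit_atot && is.null(tr$atot)) stop("trace has no total-absorbance series")
  ord <- .bfs_order(m)

  # reactant fit: escalate the term count from the reactant's own step count;
  # keep several ranked minima, since the shared coupling factor a minimum
  # carries may suit the downstream traces more or less well
  rx <- ord[1L]
  yx <- tr$conc[, rx]
  n0 <- .n_phi_j(m, m$species$name[rx])
  cands <- list()
  for (n_terms in seq(max(n0, 1L), max(n0, n_phi))) {
    cands <- .po_fit_one(tfit, yx[idx], yx[1L], n_new = n_terms, cc = NULL,
                         k_fixed = numeric(), n_starts = n_starts,
                         k_range = k_range, cc_range = cc_range, keep = 6L)
    q <- .po_quality(.po_as_model(cands[[1L]], yx[1L]), tr$times, yx)
    if (q$r2 >= r2_min && q$rmse <= rmse_rel * sum(tr$conc[1L, ])) break
  }

  best <- NULL
  for (cand in cands) {
    out <- .po_fit_downstream(cand, tr, m, ord, idx, tfit, n_phi, n_starts,
                              r2_min, rmse_rel, fit_atot, k_range, cc_range)
    if (is.null(best) || out$worst_margin < best$worst_margin) best <- out
    if (out$ok) { best <- out; break }
  }
  if (!best$ok) {
    # sequential pass missed the thresholds for some trace: refine the shared
    # coupling factor and rate-constant pool jointly over all species traces
    joint <- .po_fit_joint(tr, m, ord, idx, tfit, n_phi, n_starts, r2_min,
                           rmse_rel, fit_atot, k_range, cc_range, init = best)
    if (joint$worst_margin < best$worst_margin) best <- joint
  }

  quality <- best$quality
  poor <- quality$trace[quality$r2 < r2_min]
  if (length(poor)) {
    warning("poor fit (r2 below threshold) for: ", paste(poor, collapse = ", "),
            call. = FALSE)
  }
  structure(list(models = best$models, atot_model = best$atot_model,
                 cc = best$cc, k_pool = best$k_pool, quality = quality,
                 seed = seed, n_starts = n_starts),
            class = "coupled_fit")
}

# runs the sequential protocol below the reactant for one reactant minimum:
# downstream species inherit the shared cc and the growing k pool (linear
# solves unless escalation adds regimes), then the total absorbance is
# fitted with the final pool. Reports the worst quality margin across all
# traces so the caller can compare reactant minima.
.po_fit_downstream <- function(reactant_fit, tr, m, ord, idx, tfit, n_phi,
                               n_starts, r2_min, rmse_rel, fit_atot,
                               k_range, cc_range) {
  models <- vector("list", n_species(m))
  names(models) <- m$species$name
  qual <- list()
  margins <- numeric()

  rx <- ord[1L]
  cx0 <- max(sum(tr$conc[1L, ]), 1e-300)   # conserved total concentration
  r0_data <- apply(tr$conc, 2L, function(y) .po_r0_stencil(tr$times, y))
  r0_scale <- max(abs(r0_data), 1e-300)
  yx <- tr$conc[, rx]
  rmse_tol_x <- rmse_rel * cx0
  fit <- .po_prune(reactant_fit, tfit, yx[idx] - yx[1L], rmse_tol_x)
  cc_shared <- fit$cc
  k_pool <- fit$k
  push <- function(name, pm, y, rmse_tol) {
    q <- .po_quality(pm, tr$times, y)
    mg <- min(q$r2 - r2_min, (rmse_tol - q$rmse) / rmse_tol)
    if (name %in% colnames(tr$conc)) {
      dr0 <- abs(model_initial_rate(pm) - r0_data[[name]]) / r0_scale
      mg <- min(mg, (0.005 - dr0) / 0.005)
    }
    qual[[name]] <<- data.frame(trace = name, n_terms = length(pm$k),
                                r2 = q$r2, sse = q$sse, rmse = q$rmse,
                                pass = mg >= 0, stringsAsFactors = FALSE)
    margins <<- c(margins, mg)
  }
  models[[rx]] <- .po_as_model(fit, yx[1L])
  push(m$species$name[rx], models[[rx]], yx, rmse_tol_x)

  for (j in ord[-1L]) {
    name <- m$species$name[j]
    y <- tr$conc[, j]
    rmse_tol <- rmse_rel * cx0
    n_start_terms <- max(length(k_pool), .n_phi_j(m, name))
    fit <- NULL
    for (n_terms in unique(pmin(seq(n_start_terms, max(n_start_terms, n_phi)),
                                n_phi))) {
      fit <- .po_fit_one(tfit, y[idx], y[1L],
                         n_new = max(n_terms - length(k_pool), 0L),
                         cc = cc_shared, k_fixed = k_pool,
                         n_starts = n_starts,
                         k_range = k_range, cc_range = cc_range)
      pmq <- .po_quality(.po_as_model(fit, y[1L]), tr$times, y)
      if (pmq$r2 >= r2_min && pmq$rmse <= rmse_tol) break
    }
    fit <- .po_prune(fit, tfit, y[idx] - y[1L], rmse_tol,
                     n_min = length(models[[rx]]$k))
    k_pool <- unique(c(k_pool, fit$k))
    models[[j]] <- .po_as_model(fit, y[1L])
    push(name, models[[j]], y, rmse_tol)
  }

  atot_model <- NULL
  if (fit_atot) {
    atot_model <- fit_total_absorbance(tr$atot, tr$times, n_phi = n_phi,
                                       seed = NULL, k_fixed = k_pool,
                                       n_starts = n_starts,
                                       rmse_rel = rmse_rel,
                                       cc_range = cc_range)
    push("A_tot", atot_model, tr$atot, rmse_rel * max(abs(tr$atot), 1e-300))
  }

  list(models = models, atot_model = atot_model, cc = cc_shared,
       k_pool = k_pool, quality = do.call(rbind, c(qual, list(make.row.names = FALSE))),
       worst_margin = -min(margins), ok = all(margins >= 0))
}

# joint coupled refinement: one shared coupling factor and one pool of up to
# n_phi rate constants for all species traces at once, with every species'
# weights eliminated by linear least squares. This is the fully coupled form
# of the model system; it is used when the sequential pass cannot reach the
# quality thresholds (typically consecutive chains, where the reactant's
# mono-term fit leaves the coupling factor on a degenerate ridge).
.po_fit_joint <- function(tr, m, ord, idx, tfit, n_phi, n_starts, r2_min,
                          rmse_rel, fit_atot, k_range, cc_range, init = NULL) {
  nsp <- n_species(m)
  b <- lapply(seq_len(nsp), function(j) tr$conc[idx, j] - tr$conc[1L, j])
  cx0 <- max(sum(tr$conc[1L, ]), 1e-300)
  scales <- rep(cx0, nsp)   # one concentration scale: the conserved total
  resid_fn <- function(p) {
    cc <- expm1(p[1L]); k <- exp(p[-1L])
    G <- .po_basis(tfit, cc, k)
    unlist(lapply(seq_len(nsp), function(j) {
      (as.vector(G %*% .po_lstsq(G, b[[j]])) - b[[j]]) / scales[j]
    }))
  }
  starts <- list()
  if (!is.null(init) && length(init$k_pool)) {
    k0 <- sort(init$k_pool, decreasing = TRUE)
    if (length(k0) < n_phi) {
      k0 <- c(k0, 10^stats::runif(n_phi - length(k0), log10(k_range[1]),
                                  log10(k_range[2])))
    }
    starts[[1L]] <- c(log1p(init$cc), log(k0))
  }
  for (i in seq_len(max(8L, n_starts %/% 2L))) {
    starts[[length(starts) + 1L]] <-
      c(log1p(10^stats::runif(1, log10(cc_range[1]), log10(cc_range[2]))),
        log(sort(10^stats::runif(n_phi, log10(k_range[1]), log10(k_range[2])),
                 decreasing = TRUE)))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) stop("joint coupled fit failed to converge")
  for (i in seq_len(8L)) {   # basin refinement as in the single-trace fit
    p0 <- best$par + stats::rnorm(length(best$par), 0, 0.3)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300L)),
      error = function(e) NULL)
    if (!is.null(fit) && sum(fit$fvec^2) < best$sse) {
      best <- list(par = fit$par, sse = sum(fit$fvec^2))
    }
  }
  cc <- expm1(best$par[1L]); k <- exp(best$par[-1L])

  models <- vector("list", nsp)
  names(models) <- m$species$name
  qual <- list(); margins <- numeric()
  r0_data <- apply(tr$conc, 2L, function(y) .po_r0_stencil(tr$times, y))
  r0_scale <- max(abs(r0_data), 1e-300)
  rx <- ord[1L]
  floor_terms <- 0L
  for (j in c(rx, setdiff(ord, rx))) {
    y <- tr$conc[, j]
    rmse_tol <- rmse_rel * cx0
    G <- .po_basis(tfit, cc, k)
    fit_j <- list(cc = cc, k = k, omega = .po_lstsq(G, y[idx] - y[1L]))
    fit_j <- .po_prune(fit_j, tfit, y[idx] - y[1L], rmse_tol, n_min = floor_terms)
    if (j == rx) floor_terms <- length(fit_j$k)
    models[[j]] <- .po_as_model(fit_j, y[1L])
    q <- .po_quality(models[[j]], tr$times, y)
    mg <- min(q$r2 - r2_min, (rmse_tol - q$rmse) / rmse_tol)
    dr0 <- abs(model_initial_rate(models[[j]]) - r0_data[[j]]) / r0_scale
    mg <- min(mg, (0.005 - dr0) / 0.005)
    qual[[j]] <- data.frame(trace = m$species$name[j],
                            n_terms = length(fit_j$k),
                            r2 = q$r2, sse = q$sse, rmse = q$rmse,
                            pass = mg >= 0, stringsAsFactors = FALSE)
    margins <- c(margins, mg)
  }
  qual <- qual[order(match(seq_len(nsp), ord))]

  atot_model <- NULL
  if (fit_atot) {
    atot_model <- fit_total_absorbance(tr$atot, tr$times, n_phi = n_phi,
                                       seed = NULL, k_fixed = k,
                                       n_starts = n_starts, rmse_rel = rmse_rel,
                                       cc_range = cc_range)
    q <- .po_quality(atot_model, tr$times, tr$atot)
    rmse_tol <- rmse_rel * max(abs(tr$atot), 1e-300)
    mg <- min(q$r2 - r2_min, (rmse_tol - q$rmse) / rmse_tol)
    qual[[length(qual) + 1L]] <- data.frame(trace = "A_tot",
                                            n_terms = length(atot_model$k),
                                            r2 = q$r2, sse = q$sse, rmse = q$rmse,
                                            pass = mg >= 0, stringsAsFactors = FALSE)
    margins <- c(margins, mg)
  }
  list(models = models, atot_model = atot_model, cc = cc, k_pool = k,
       quality = do.call(rbind, c(qual, list(make.row.names = FALSE))),
       worst_margin = -min(margins), ok = all(margins >= 0))
}

# breadth-first species order from the reactant through the step graph
.bfs_order <- function(m) {
  nm <- m$species$name
  visited <- 1L
  queue <- 1L
  while (length(queue)) {
    cur <- nm[queue[1L]]; queue <- queue[-1L]
    nb <- unique(c(m$steps$to[m$steps$from == cur],
                   m$steps$from[m$steps$to == cur]))
    nb_i <- match(nb, nm)
    new <- setdiff(nb_i, visited)
    visited <- c(visited, new)
    queue <- c(queue, new)
  }
  c(visited, setdiff(seq_along(nm), visited))
}

#' @export
print.coupled_fit <- function(x, ...) {
  cat(sprintf("<coupled_fit> cc=%.6g, k pool: %s\n", x$cc,
              paste(signif(sort(x$k_pool, decreasing = TRUE), 6), collapse = ", ")))
  print(x$quality, row.names = FALSE)
  invisible(x)
}

#' Fit a total-absorbance trace with a Phi-order model
#'
#' The total absorbance is a linear combination of the species traces, so
#' its model has the same template with the same rate constants but its own
#' coupling factor and weights (in absorbance units). When `k_fixed` is
#' supplied (normally the pool from a coupled species fit) the rate
#' constants are held exactly and only the coupling factor is searched; the
#' weights are solved linearly. A constant series (isosbestic irradiation)
#' yields a zero-term model whose final value is that constant.
#'
#' @param atot absorbance series.
#' @param times matching times, s.
#' @param n_phi maximum number of terms (the mechanism's step count);
#'   required when `k_fixed` is NULL.
#' @param seed integer seed for the multi-start (NULL to keep the caller's
#'   RNG stream, as done inside [fit_species_traces()]).
#' @param k_fixed optional rate constants to hold fixed.
#' @inheritParams fit_species_traces
#' @return a [phi_order_model()] in absorbance units.
#' @export
fit_total_absorbance <- function(atot, times, n_phi = NULL, seed = 1L,
                                 k_fixed = NULL, n_starts = 32L,
                                 max_points = 400L, rmse_rel = 1e-9 / 1.58e-5,
                                 k_range = c(1e-4, 1e1), cc_range = c(1e-6, 1e2)) {
  stopifnot(length(atot) == length(times))
  if (!is.null(seed)) set.seed(as.integer(seed))
  scale <- max(abs(atot), 1e-300)
  if (max(atot) - min(atot) < 1e-12 * scale) {     # isosbestic: constant
    return(phi_order_model(c_inf = mean(atot), cc = 0))
  }
  idx <- unique(round(seq(1L, length(times), length.out =
                            min(max_points, length(times)))))
  a0 <- atot[1L]
  if (!is.null(k_fixed)) {
    fit <- .po_fit_one(times[idx], atot[idx], a0, n_new = 0L, cc = NULL,
                       k_fixed = k_fixed, n_starts = n_starts,
                       cc_range = cc_range)
  } else {
    stopifnot(!is.null(n_phi))
    fit <- NULL
    best_rmse <- Inf
    for (n_terms in seq_len(n_phi)) {
      cand <- .po_fit_one(times[idx], atot[idx], a0, n_new = n_terms,
                          cc = NULL, k_fixed = numeric(), n_starts = n_starts,
                          k_range = k_range, cc_range = cc_range)
      q <- .po_quality(.po_as_model(cand, a0), times, atot)
      if (q$rmse < best_rmse) { fit <- cand; best_rmse <- q$rmse }
      # an essentially exact representation needs no further terms
      if (best_rmse <= 1e-10 * scale) break
    }
  }
  fit <- .po_prune(fit, times[idx], atot[idx] - a0, rmse_rel * scale)
  phi_order_model(a0 - sum(fit$omega) * log10(1 + fit$cc),
                  fit$cc, fit$omega, fit$k)
}
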
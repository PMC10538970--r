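#' Reference photoreversible system
#'
#' The worked photoreversible example used throughout the documentation and
#' tests: reactant and photoproduct interconverting under monochromatic
#' light with absorption coefficients 12004 and 23123 M^-1 cm^-1, quantum
#' yields 0.062 (forward) and 0.034 (reverse), initial reactant
#' concentration 1.58e-5 M, photon flux 1.25e-5 einstein s^-1 dm^-3 and a
#' 1.65 cm path.
#'
#' @return list with `mechanism` and `setup`.
#' @export
photoreversible_example <- function() {
  m <- mechanism(
    species = data.frame(name = c("X", "Y1"),
                         epsilon = c(12004, 23123),
                         c0 = c(1.58e-5, 0), stringsAsFactors = FALSE),
    steps = data.frame(from = c("X", "Y1"), to = c("Y1", "X"),
                       phi = c(0.062, 0.034), stringsAsFactors = FALSE))
  list(mechanism = m,
       setup = irradiation_setup(lambda_irr = 365, p0 = 1.25e-5, l_irr = 1.65))
}

#' Random sub-mechanism drawn from the template network
#'
#' Synthetic-study generator: draws a connected sub-mechanism of the
#' Phi-shaped template with 1 to 4 photoproducts, quantum yields uniform in
#' [0.01, 0.5] and absorption coefficients uniform in [1e3, 5e4] M^-1 cm^-1.
#' The reactant's initial concentration is set so the medium's largest
#' attainable absorbance stays near `a_target` (the recommended linearity
#' guideline), and the irradiation conditions mirror the reference system
#' (P0 = 1.25e-5 einstein s^-1 dm^-3, l = 1.65 cm).
#'
#' Draws depend only on the current RNG state: call `set.seed()` first (or
#' pass `seed`) for reproducibility.
#'
#' @param seed optional integer seed.
#' @param n_products number of photoproducts (1-4); drawn when NULL.
#' @param a_target cap on the attainable total absorbance.
#' @return list with `mechanism`, `setup` and the `labels` of the selected
#'   template steps.
#' @export
random_submechanism <- function(seed = NULL, n_products = NULL,
                                a_target = 0.35) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  # rejection loop: only kinetically live mechanisms (every species actually
  # formed, i.e. reachable from X along step directions) describe a real
  # photoreaction study
  for (try in 1:50) {
    cs <- .draw_submechanism(n_products, a_target)
    if (.directed_live(cs$mechanism)) return(cs)
  }
  stop("could not draw a kinetically live sub-mechanism")
}

.directed_live <- function(m) {
  nm <- m$species$name
  reach <- nm == nm[1L]
  repeat {
    new <- reach | nm %in% m$steps$to[m$steps$from %in% nm[reach]]
    if (identical(new, reach)) break
    reach <- new
  }
  all(reach)
}

.draw_submechanism <- function(n_products = NULL, a_target = 0.35) {
  if (is.null(n_products)) n_products <- sample(1:4, 1L)
  # grow a connected selection from X
  all_steps <- scheme1_steps()
  parts <- strsplit(all_steps, "->", fixed = TRUE)
  ends <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  species <- "X"
  labels <- character()
  while (length(species) < n_products + 1L) {
    touch <- which(ends[, 1L] %in% species | ends[, 2L] %in% species)
    grow <- touch[!(ends[touch, 1L] %in% species & ends[touch, 2L] %in% species)]
    if (!length(grow)) break
    pick <- if (length(grow) == 1L) grow else sample(grow, 1L)
    labels <- c(labels, all_steps[pick])
    species <- unique(c(species, ends[pick, ]))
  }
  # optionally close extra steps among the selected species
  inside <- which(ends[, 1L] %in% species & ends[, 2L] %in% species &
                    !(all_steps %in% labels))
  if (length(inside)) {
    extra <- inside[stats::runif(length(inside)) < 0.4]
    labels <- c(labels, all_steps[extra])
  }
  # the system must actually photoreact: ensure a step leaves the reactant
  if (!any(startsWith(labels, "X->"))) {
    into_x <- labels[endsWith(labels, "->X")]
    labels <- unique(c(labels, sub("(.+)->X", "X->\\1", into_x[1L])))
  }
  nm <- unique(c("X", as.vector(t(ends[match(labels, all_steps), , drop = FALSE]))))
  ord <- c("X", paste0("Y", 1:7))
  nm <- ord[ord %in% nm]
  eps <- stats::setNames(stats::runif(length(nm), 1e3, 5e4), nm)
  phi <- stats::runif(length(labels), 0.01, 0.5)
  l_irr <- 1.65
  cx0 <- a_target / (l_irr * max(eps))
  m <- scheme1_template(labels, epsilon = eps, phi = phi, c0 = cx0)
  list(mechanism = m,
       setup = irradiation_setup(lambda_irr = 365, p0 = 1.25e-5, l_irr = l_irr),
       labels = labels)
}

#' Write a named fixture case to disk
#'
#' Emits reproducible input files (mechanism + setup YAML, simulated trace
#' CSV) and a JSON manifest of expected values for the named case:
#' \describe{
#'   \item{photoreversible}{the reference photoreversible system with its expected
#'     trace landmarks (concentrations, absorbances, rates at 30 and 60 s).}
#'   \item{isosbestic}{all species share one absorption coefficient; the
#'     manifest expects a constant total absorbance.}
#'   \item{branch}{divergent branching Y1 <- X -> Y3.}
#'   \item{cyclic}{three-species cycle X -> Y1 -> Y2 -> X.}
#'   \item{spectator}{the reference system plus a spectator of absorbance
#'     0.5.}
#'   \item{p0grid}{five setups with photon fluxes 0.25, 0.5, 1, 2 and 4
#'     times the reference flux, for calibration studies.}
#' }
#'
#' @param case case name.
#' @param dir output directory (created if missing).
#' @param dt,t_end simulation grid, s.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
generate_fixtures <- function(case, dir, dt = 0.1, t_end = 300) {
  cases <- c("photoreversible", "isosbestic", "branch", "cyclic", "spectator", "p0grid")
  if (!case %in% cases) {
    stop("unknown case '", case, "'; available: ", paste(cases, collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- photoreversible_example()
  manifest <- list(case = case, dt = dt, t_end = t_end)

  emit <- function(m, s, tag, manifest_extra = list()) {
    writeLines(serialize_mechanism(m, s), file.path(dir, paste0(tag, ".yml")))
    tr <- simulate_mechanism(m, s, t_end = t_end, dt = dt,
                             warn_absorbance = FALSE)
    write_trace(tr, file.path(dir, paste0(tag, "_trace.csv")))
    manifest_extra
  }

  extra <- switch(case,
    photoreversible = {
      ex <- emit(ref$mechanism, ref$setup, "photoreversible")
      list(expected = list(CX_30s = 9.91197e-6, CX_60s = 8.57014e-6,
                           CY1_60s = 7.22959e-6, Atot_30s = 0.42096,
                           AY1_60s = 0.2758036, rX_30s = -8.35686e-8,
                           rY1_60s = 2.06243e-8, PaX_30s = 3.61887e-6,
                           tol_rel = 1e-3))
    },
    isosbestic = {
      m <- ref$mechanism
      m$species$epsilon <- c(15000, 15000)
      emit(m, ref$setup, "isosbestic")
      list(expected = list(constant_atot = 15000 * 1.65 * 1.58e-5))
    },
    branch = {
      m <- scheme1_template(c("X->Y1", "X->Y3"),
                            epsilon = c(X = 12004, Y1 = 8000, Y3 = 3000),
                            phi = c(0.03, 0.05), c0 = 1.58e-5)
      emit(m, ref$setup, "branch")
      list(expected = list(phi_sum = 0.08))
    },
    cyclic = {
      m <- scheme1_template(c("X->Y1", "Y1->Y2", "Y2->Y3", "Y3->X"),
                            epsilon = c(X = 12004, Y1 = 18000, Y2 = 6000,
                                        Y3 = 9500),
                            phi = c(0.062, 0.12, 0.08, 0.05), c0 = 1.58e-5)
      emit(m, ref$setup, "cyclic")
      list(expected = list(shared_cc = TRUE))
    },
    spectator = {
      m <- ref$mechanism
      m$spectators <- data.frame(name = "SPM1", absorbance = 0.5,
                                 stringsAsFactors = FALSE)
      emit(m, ref$setup, "spectator")
      list(expected = list(atot_offset = 0.5))
    },
    p0grid = {
      mult <- c(0.25, 0.5, 1, 2, 4)
      for (i in seq_along(mult)) {
        s <- ref$setup
        s$p0 <- 1.25e-5 * mult[i]
        emit(ref$mechanism, s, sprintf("p0grid_%02d", i))
      }
      list(p0_values = 1.25e-5 * mult)
    })

  manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
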
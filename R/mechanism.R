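#' Construct a photomechanism
#'
#' A mechanism is the complete description of a unimolecular photoreaction
#' network at one irradiation wavelength: the species (with their molar
#' absorption coefficients and initial concentrations), the directed
#' photoreaction steps (each with its quantum yield), and any inert
#' spectator molecules that absorb at the irradiation wavelength without
#' taking part in the chemistry.
#'
#' The first species is, by convention, the reactant X. All steps are
#' unimolecular photoisomerizations with implicit 1:1 stoichiometry, which
#' is what makes the mass balance (the sum of all concentrations equals the
#' reactant's initial concentration) hold throughout a simulation.
#'
#' @param species data frame with columns `name`, `epsilon` (molar
#'   absorption coefficient at the irradiation wavelength, M^-1 cm^-1) and
#'   `c0` (initial concentration, M). Row order is preserved; the first row
#'   is the reactant.
#' @param steps data frame with columns `from`, `to` (species names) and
#'   `phi` (quantum yield of the step, dimensionless).
#' @param spectators optional data frame with columns `name` and
#'   `absorbance` (constant absorbance at the irradiation wavelength).
#' @return an object of class `mechanism`.
#' @seealso [parse_mechanism()], [validate_mechanism()], [scheme1_template()]
#' @export
#' @examples
#' m <- mechanism(
#'   species = data.frame(name = c("X", "Y1"),
#'                        epsilon = c(12004, 23123),
#'                        c0 = c(1.58e-5, 0)),
#'   steps = data.frame(from = c("X", "Y1"), to = c("Y1", "X"),
#'                      phi = c(0.062, 0.034)))
#' n_steps(m)
mechanism <- function(species, steps, spectators = NULL) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  steps <- as.data.frame(steps, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "epsilon", "c0") %in% names(species)),
            all(c("from", "to", "phi") %in% names(steps)))
  if (is.null(spectators)) {
    spectators <- data.frame(name = character(), absorbance = numeric(),
                             stringsAsFactors = FALSE)
  } else {
    spectators <- as.data.frame(spectators, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "absorbance") %in% names(spectators)))
  }
  m <- structure(list(species = species[, c("name", "epsilon", "c0")],
                      steps = steps[, c("from", "to", "phi")],
                      spectators = spectators[, c("name", "absorbance")]),
                 class = "mechanism")
  issues <- validate_mechanism(m)
  bad <- issues$message[issues$level == "error"]
  if (length(bad)) stop("invalid mechanism: ", paste(bad, collapse = "; "))
  for (w in issues$message[issues$level == "warning"]) warning(w, call. = FALSE)
  m
}

#' @export
print.mechanism <- function(x, ...) {
  cat(sprintf("<mechanism> %d species, %d steps, %d spectators\n",
              n_species(x), n_steps(x), nrow(x$spectators)))
  cat("species:", paste(x$species$name, collapse = ", "), "\n")
  cat("steps:  ", paste(step_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Number of species / steps in a mechanism
#'
#' @param m a [mechanism()].
#' @return integer count.
#' @export
n_species <- function(m) nrow(m$species)

#' @rdname n_species
#' @export
n_steps <- function(m) nrow(m$steps)

#' Step labels of the form "from->to"
#' @param m a [mechanism()].
#' @return character vector, one label per step.
#' @export
step_labels <- function(m) paste0(m$steps$from, "->", m$steps$to)

# steps touching species j (starting or ending there); the minimum number of
# Phi-order terms expected in that species' trace model
.n_phi_j <- function(m, name) {
  sum(m$steps$from == name | m$steps$to == name)
}

#' Validate a mechanism
#'
#' Checks every structural invariant of a mechanism and reports problems
#' instead of raising. Errors (duplicate names, steps referencing unknown
#' species, non-positive quantum yields, spectators appearing in steps, ...)
#' are distinguished from warnings (quantum yield above one, which is
#' physically possible for chain processes; species not connected to the
#' reactant through any step).
#'
#' Template mechanisms (from [scheme1_template()]) may carry `NA` epsilons,
#' quantum yields or initial concentrations as placeholders; these are
#' reported as warnings so a template validates structurally but is flagged
#' as incomplete.
#'
#' @param m a [mechanism()] (or a bare list with the same fields).
#' @return data frame with columns `level` ("error" or "warning") and
#'   `message`; zero rows when every invariant holds.
#' @export
validate_mechanism <- function(m) {
  issues <- list()
  add <- function(level, msg) issues[[length(issues) + 1L]] <<- data.frame(
    level = level, message = msg, stringsAsFactors = FALSE)

  sp <- m$species; st <- m$steps; spm <- m$spectators
  if (anyDuplicated(sp$name)) add("error", "duplicate species name")
  if (nrow(spm) && anyDuplicated(spm$name)) add("error", "duplicate spectator name")
  if (any(sp$name %in% spm$name)) add("error", "name used for both a species and a spectator")
  if (!nrow(st)) add("error", "mechanism has no reaction step")

  unknown <- setdiff(c(st$from, st$to), sp$name)
  if (length(unknown)) {
    add("error", paste0("unknown species referenced in a step: ",
                        paste(unique(unknown), collapse = ", ")))
  }
  if (any(spm$name %in% c(st$from, st$to))) {
    add("error", "spectator named in a reaction step")
  }
  if (any(st$from == st$to)) add("error", "step with identical source and target")
  if (anyDuplicated(paste(st$from, st$to))) add("error", "duplicate identical step")

  if (any(!is.na(st$phi) & st$phi <= 0)) add("error", "non-positive quantum yield")
  if (any(!is.na(st$phi) & st$phi > 1)) {
    add("warning", "quantum yield above 1 (possible for chain processes)")
  }
  if (any(!is.na(sp$epsilon) & sp$epsilon < 0)) add("error", "negative absorption coefficient")
  if (any(!is.na(sp$c0) & sp$c0 < 0)) add("error", "negative initial concentration")
  if (nrow(spm) && any(!is.na(spm$absorbance) & spm$absorbance < 0)) {
    add("error", "negative spectator absorbance")
  }
  if (anyNA(st$phi) || anyNA(sp$epsilon) || anyNA(sp$c0)) {
    add("warning", "template placeholders (NA) present; fill before simulating")
  }

  # reachability of every species from the reactant through steps, in either
  # direction (the network must be connected for the mass balance to tie all
  # species to the reactant)
  if (!length(unknown) && nrow(st) && nrow(sp)) {
    reach <- .reachable(sp$name, st)
    if (!all(reach)) {
      add("warning", paste0("species not connected to the reactant: ",
                            paste(sp$name[!reach], collapse = ", ")))
    }
  }

  if (!length(issues)) {
    data.frame(level = character(), message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

# undirected reachability from species 1
.reachable <- function(names, steps) {
  reach <- names == names[1L]
  repeat {
    hit <- (steps$from %in% names[reach]) | (steps$to %in% names[reach])
    new <- reach | names %in% c(steps$from[hit], steps$to[hit])
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

#' Parse a mechanism (and optional irradiation setup) from a YAML config
#'
#' The config declares species, steps and optional spectators under the keys
#' shown below; an optional `setup` block describes the irradiation
#' conditions and is returned as the `setup` attribute of the mechanism
#' (see [irradiation_setup()]).
#'
#' ```yaml
#' species:
#'   X:  {epsilon_M_cm: 12004, c0_M: 1.58e-5}
#'   Y1: {epsilon_M_cm: 23123, c0_M: 0}
#' steps:
#'   - {from: X, to: Y1, phi: 0.062}
#'   - {from: Y1, to: X, phi: 0.034}
#' spectators:
#'   SPM1: {absorbance: 0.5}
#' setup:
#'   lambda_irr_nm: 365
#'   p0_einstein_s_dm3: 1.25e-5
#'   l_irr_cm: 1.65
#' ```
#'
#' @param text YAML text (a single string or character vector of lines).
#' @param file path to a YAML file (used when `text` is missing).
#' @return a validated [mechanism()]; if the config has a `setup` block the
#'   corresponding [irradiation_setup()] is attached as attribute `"setup"`.
#' @export
parse_mechanism <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    if (!file.exists(file)) stop("cannot open mechanism file: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  } else if (length(text) > 1L) {
    text <- paste(text, collapse = "\n")
  }
  cfg <- yaml::yaml.load(text)
  if (is.null(cfg$species) || !length(cfg$species)) stop("config declares no species")
  species <- data.frame(
    name = names(cfg$species),
    epsilon = vapply(cfg$species, function(s) .num_or_na(s$epsilon_M_cm), 0),
    c0 = vapply(cfg$species, function(s) .num_or_na(s$c0_M), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(cfg$steps) || !length(cfg$steps)) stop("config declares no steps")
  steps <- data.frame(
    from = vapply(cfg$steps, function(s) as.character(s$from), ""),
    to = vapply(cfg$steps, function(s) as.character(s$to), ""),
    phi = vapply(cfg$steps, function(s) .num_or_na(s$phi), 0),
    stringsAsFactors = FALSE)
  spectators <- NULL
  if (!is.null(cfg$spectators) && length(cfg$spectators)) {
    spectators <- data.frame(
      name = names(cfg$spectators),
      absorbance = vapply(cfg$spectators, function(s) .num_or_na(s$absorbance), 0),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  m <- mechanism(species, steps, spectators)
  if (!is.null(cfg$setup)) {
    su <- cfg$setup
    attr(m, "setup") <- irradiation_setup(
      lambda_irr = su$lambda_irr_nm,
      p0 = su$p0_einstein_s_dm3,
      l_irr = su$l_irr_cm,
      l_obs = if (is.null(su$l_obs_cm)) su$l_irr_cm else su$l_obs_cm,
      lambda_obs = if (is.null(su$lambda_obs_nm)) su$lambda_irr_nm else su$lambda_obs_nm)
  }
  m
}

.num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Serialize a mechanism back to YAML
#'
#' Inverse of [parse_mechanism()]: `parse_mechanism(serialize_mechanism(m))`
#' reproduces the mechanism (names, values and declaration order).
#'
#' @param m a [mechanism()].
#' @param setup optional [irradiation_setup()] to embed as the `setup` block
#'   (defaults to the mechanism's `setup` attribute when present).
#' @return a single YAML string.
#' @export
serialize_mechanism <- function(m, setup = attr(m, "setup")) {
  sp <- stats::setNames(
    lapply(seq_len(nrow(m$species)), function(i) list(
      epsilon_M_cm = m$species$epsilon[i], c0_M = m$species$c0[i])),
    m$species$name)
  st <- lapply(seq_len(nrow(m$steps)), function(i) list(
    from = m$steps$from[i], to = m$steps$to[i], phi = m$steps$phi[i]))
  cfg <- list(species = sp, steps = st)
  if (nrow(m$spectators)) {
    cfg$spectators <- stats::setNames(
      lapply(m$spectators$absorbance, function(a) list(absorbance = a)),
      m$spectators$name)
  }
  if (!is.null(setup)) {
    cfg$setup <- list(lambda_irr_nm = setup$lambda_irr,
                      p0_einstein_s_dm3 = setup$p0,
                      l_irr_cm = setup$l_irr,
                      l_obs_cm = setup$l_obs,
                      lambda_obs_nm = setup$lambda_obs)
  }
  yaml::as.yaml(cfg, precision = 15L)
}

#' Irradiation setup
#'
#' Describes the monochromatic irradiation conditions: wavelength, incident
#' photon flux P0 entering the (slab-shaped, well-stirred) reactor, and the
#' optical path lengths of the irradiation beam and of the observation beam
#' used to record total absorbance. P0 can be measured by actinometry or
#' computed from a lamp's spectral irradiance with [photon_flux()].
#'
#' @param lambda_irr irradiation wavelength, nm.
#' @param p0 incident photon flux, einstein s^-1 dm^-3; must be positive.
#' @param l_irr optical path length of the irradiation beam, cm.
#' @param l_obs optical path length of the observation beam, cm
#'   (defaults to `l_irr`).
#' @param lambda_obs observation wavelength, nm (defaults to `lambda_irr`).
#' @return an object of class `irradiation_setup`.
#' @export
irradiation_setup <- function(lambda_irr, p0, l_irr,
                              l_obs = l_irr, lambda_obs = lambda_irr) {
  stopifnot(is.numeric(p0), p0 > 0, is.numeric(l_irr), l_irr > 0,
            is.numeric(l_obs), l_obs > 0)
  structure(list(lambda_irr = as.numeric(lambda_irr), p0 = as.numeric(p0),
                 l_irr = as.numeric(l_irr), l_obs = as.numeric(l_obs),
                 lambda_obs = as.numeric(lambda_obs)),
            class = "irradiation_setup")
}

#' @export
print.irradiation_setup <- function(x, ...) {
  cat(sprintf(
    "<irradiation_setup> lambda_irr=%g nm, P0=%g einstein/s/dm^3, l_irr=%g cm, l_obs=%g cm\n",
    x$lambda_irr, x$p0, x$l_irr, x$l_obs))
  invisible(x)
}

#' The package's Phi-shaped template mechanism
#'
#' A representative eight-species network (the reactant X and photoproducts
#' Y1..Y7) interlinked by 14 photoreaction steps, from which sub-mechanisms
#' are carved by selecting step labels. The template covers the classic
#' cases: the primary photoprocess (X->Y1), the photoreversible couple
#' (X->Y1, Y1->X), divergent branching (Y1<-X->Y3), cyclic networks
#' (X->Y1->Y2->Y3->X) and multi-consecutive chains down to Y7.
#'
#' `scheme1_steps()` returns the 14 step labels; `scheme1_template()` builds
#' a mechanism from a selection of them. Epsilons, quantum yields and initial
#' concentrations default to `NA` placeholders to be filled by the caller
#' (the returned object then validates with an "incomplete" warning).
#'
#' @param selection character vector of step labels ("from->to"); must be
#'   non-empty, include the reactant X and induce a connected network.
#' @param epsilon optional named vector of absorption coefficients
#'   (M^-1 cm^-1), names matching the induced species.
#' @param phi optional vector of quantum yields, one per selected step (in
#'   selection order), or named by step label.
#' @param c0 optional named vector of initial concentrations (M); unnamed
#'   scalar sets the reactant and leaves products at zero.
#' @return a [mechanism()].
#' @export
#' @examples
#' scheme1_steps()
#' m <- scheme1_template(c("X->Y1", "Y1->X"),
#'                       epsilon = c(X = 12004, Y1 = 23123),
#'                       phi = c(0.062, 0.034), c0 = 1.58e-5)
scheme1_template <- function(selection, epsilon = NULL, phi = NULL, c0 = NULL) {
  all_steps <- scheme1_steps()
  if (!length(selection)) stop("empty step selection")
  bad <- setdiff(selection, all_steps)
  if (length(bad)) stop("unknown step label(s): ", paste(bad, collapse = ", "))
  parts <- strsplit(selection, "->", fixed = TRUE)
  st <- data.frame(from = vapply(parts, `[`, "", 1L),
                   to = vapply(parts, `[`, "", 2L),
                   phi = NA_real_, stringsAsFactors = FALSE)
  involved <- unique(c("X", rbind(st$from, st$to)))
  order_all <- c("X", paste0("Y", 1:7))
  involved <- order_all[order_all %in% involved]
  if (!"X" %in% c(st$from, st$to)) stop("selection omits the reactant X")
  reach <- .reachable(involved, st)
  if (!all(reach)) stop("selection induces a disconnected mechanism")

  sp <- data.frame(name = involved, epsilon = NA_real_, c0 = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(epsilon)) sp$epsilon <- unname(epsilon[sp$name])
  sp$c0 <- c(NA_real_, rep(0, nrow(sp) - 1L))
  if (!is.null(c0)) {
    if (is.null(names(c0))) sp$c0[1L] <- c0 else sp$c0 <- unname(c0[sp$name])
  }
  if (!is.null(phi)) {
    st$phi <- if (is.null(names(phi))) phi else unname(phi[selection])
  }
  suppressWarnings(mechanism(sp, st))
}

#' @rdname scheme1_template
#' @export
scheme1_steps <- function() {
  c("X->Y1", "Y1->X", "X->Y3", "Y3->X",
    "Y1->Y2", "Y2->Y1", "Y2->Y3", "Y3->Y2",
    "Y3->Y4", "Y4->Y5", "Y5->Y4", "Y5->Y6", "Y6->Y5", "Y6->Y7")
}
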
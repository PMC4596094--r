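#' Gating-curve parameters
#'
#' A sigmoidal (Boltzmann) gate is described by its half-(in)activation
#' voltage and slope; gates with first-order kinetics additionally carry the
#' peak time constant of their bell-shaped voltage dependence.
#'
#' @param V_half half-activation voltage (mV).
#' @param slope slope factor (mV, signed; negative for curves that increase
#'   with depolarisation).
#' @param tau_bar peak time constant (ms) for dynamic gates, or `NULL` for
#'   instantaneous gates.
#' @return An object of class `gating_params`.
#' @seealso [steady_state()], [time_constant()]
#' @export
#' @examples
#' gating_params(-40, -6)               # NaP/Ca activation, instantaneous
#' gating_params(-48, 5, tau_bar = 1e4) # NaP inactivation, slow
gating_params <- function(V_half, slope, tau_bar = NULL) {
  stopifnot(is.numeric(V_half), length(V_half) == 1L, is.finite(V_half),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope == 0) stop("gating slope must be non-zero")
  if (!is.null(tau_bar)) {
    stopifnot(is.numeric(tau_bar), length(tau_bar) == 1L, is.finite(tau_bar))
    if (tau_bar <= 0) stop("tau_bar must be positive")
  }
  structure(list(V_half = V_half, slope = slope, tau_bar = tau_bar),
            class = "gating_params")
}

# canonical scalar field order of one compartment's parameter block; the C
# right-hand side (src/prebotc.c) indexes the flattened vector by position,
# so this order must not change.
.param_order <- c(
  "Cm", "gNaP", "gK", "gCaN", "gCa", "gh", "gsyn",
  "VNaP", "VK", "VCa", "Vsyn", "Eh", "KCaN",
  "m_gate.V_half", "m_gate.slope",
  "h_gate.V_half", "h_gate.slope", "h_gate.tau_bar",
  "n_gate.V_half", "n_gate.slope",
  "s_gate.V_half", "s_gate.slope", "s_gate.tau_bar",
  "ksyn", "s_tau_voltage_dep",
  "alpha", "VPMCA", "KPMCA", "lam", "f_i", "sigma",
  "IP3", "A_ip3", "Kd", "KI", "Ka",
  "VSERCA", "KSERCA", "LIP3R", "PIP3R"
)

#' Default parameter set for one subpopulation
#'
#' Returns the published parameterisation of one model compartment. The two
#' subpopulations are identical except for the persistent sodium conductance
#' (`gNaP`), the half-activation of the hyperpolarisation-activated current
#' (`n_gate$V_half`), the ER-to-plasma-membrane surface ratio (`lam`), and
#' the synapse each compartment receives: the eupnea compartment receives the
#' excitatory synapse (9 nS, reversal 0 mV, driven by sigh) and the sigh
#' compartment the inhibitory synapse (3 nS, reversal -70 mV, driven by
#' eupnea).
#'
#' Units: voltages mV, times ms, conductances nS, capacitance pF, calcium
#' concentrations uM. The calcium-flux rate constants (`VSERCA`, `VPMCA`,
#' `LIP3R`, `PIP3R`) are taken as rate parameters in the uM/ms balance
#' exactly as tabulated.
#'
#' @param population `"eupnea"` or `"sigh"`.
#' @return A named list of class `prebotc_params`; gate entries are
#'   [gating_params()] objects.
#' @export
#' @examples
#' eup <- default_parameters("eupnea")
#' sgh <- default_parameters("sigh")
#' eup$gNaP  # 2.5 nS
#' sgh$lam   # 0.1
default_parameters <- function(population = c("eupnea", "sigh")) {
  population <- match.arg(population)
  ps <- list(
    Cm = 21,
    gNaP = 2.5, gK = 2.7, gCaN = 1.5, gCa = 0.02, gh = 2, gsyn = 9,
    VNaP = 50, VK = -60, VCa = 150, Vsyn = 0, Eh = 30,
    KCaN = 0.74,
    m_gate = gating_params(-40, -6),
    h_gate = gating_params(-48, 5, tau_bar = 10000),
    n_gate = gating_params(-90, 8),
    s_gate = gating_params(-10, -5, tau_bar = 5),
    ksyn = 1,
    s_tau_voltage_dep = FALSE,
    alpha = 0.055, VPMCA = 2, KPMCA = 0.3,
    lam = 1e-4, f_i = 2.5e-5, sigma = 0.185,
    IP3 = 1, A_ip3 = 5e-4, Kd = 0.4, KI = 1, Ka = 0.4,
    VSERCA = 400, KSERCA = 0.2, LIP3R = 0.37, PIP3R = 31000
  )
  if (population == "sigh") {
    # 1.0 nS: below the NaP oscillation threshold, so the current only
    # amplifies calcium-driven depolarisations; this is also the 100%
    # condition of the gNaP knockdown protocol
    ps$gNaP <- 1.0
    ps$n_gate <- gating_params(-70, 8)
    ps$lam <- 0.1
    ps$gsyn <- 3
    ps$Vsyn <- -70
  }
  class(ps) <- "prebotc_params"
  validate_params(ps)
  ps
}

#' @rdname default_parameters
#' @param ps a `prebotc_params` object to validate.
#' @export
validate_params <- function(ps) {
  need <- c("Cm", "gNaP", "gK", "gCaN", "gCa", "gh", "gsyn", "VNaP", "VK",
            "VCa", "Vsyn", "Eh", "KCaN", "m_gate", "h_gate", "n_gate",
            "s_gate", "ksyn", "s_tau_voltage_dep", "alpha", "VPMCA", "KPMCA",
            "lam", "f_i", "sigma", "IP3", "A_ip3", "Kd", "KI", "Ka",
            "VSERCA", "KSERCA", "LIP3R", "PIP3R")
  missing <- setdiff(need, names(ps))
  if (length(missing))
    stop("parameter set is missing fields: ", paste(missing, collapse = ", "))
  g <- function(nm) ps[[nm]]
  if (any(vapply(c("gNaP", "gK", "gCaN", "gCa", "gh", "gsyn"), g, 0) < 0))
    stop("conductances must be non-negative")
  if (any(vapply(c("KCaN", "KPMCA", "Kd", "KI", "Ka", "KSERCA"), g, 0) <= 0))
    stop("half-activation constants must be positive")
  if (g("lam") <= 0 || g("sigma") <= 0)
    stop("lam and sigma must be positive")
  if (g("f_i") <= 0 || g("f_i") > 1)
    stop("f_i must lie in (0, 1]")
  if (is.null(ps$h_gate$tau_bar) || is.null(ps$s_gate$tau_bar))
    stop("h_gate and s_gate require tau_bar")
  invisible(ps)
}

#' @export
print.prebotc_params <- function(x, ...) {
  cat("<prebotc_params>\n")
  cat(sprintf("  gNaP %.3g nS, gK %.3g nS, gCaN %.3g nS, gCa %.3g nS, gh %.3g nS\n",
              x$gNaP, x$gK, x$gCaN, x$gCa, x$gh))
  cat(sprintf("  VK %.3g mV, I_h half-activation %.3g mV, lam %.3g\n",
              x$VK, x$n_gate$V_half, x$lam))
  cat(sprintf("  incoming synapse: %.3g nS, reversal %.3g mV\n", x$gsyn, x$Vsyn))
  invisible(x)
}

# flatten one parameter set into the canonical numeric vector the C code reads
flatten_params <- function(ps) {
  get_path <- function(path) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    v <- ps
    for (p in parts) v <- v[[p]]
    as.numeric(v)
  }
  out <- vapply(.param_order, get_path, 0)
  names(out) <- .param_order
  out
}

#' Network configuration
#'
#' Bundles the two compartments' parameter sets, the coupling switch, and the
#' weights used for the population-average voltage.
#'
#' @param eupnea,sigh parameter sets (see [default_parameters()]).
#' @param coupling_on if `FALSE`, both cross-synaptic conductances are treated
#'   as zero and the compartments evolve independently.
#' @param avg_weights two non-negative weights (eupnea, sigh) for the
#'   population-average voltage; normalised to sum to one.
#' @return An object of class `prebotc_config`.
#' @export
#' @examples
#' cfg <- network_config()
#' cfg$sigh$gsyn  # inhibitory synapse onto sigh, 3 nS
network_config <- function(eupnea = default_parameters("eupnea"),
                           sigh = default_parameters("sigh"),
                           coupling_on = TRUE,
                           avg_weights = c(0.5, 0.5)) {
  validate_params(eupnea)
  validate_params(sigh)
  stopifnot(is.logical(coupling_on), length(coupling_on) == 1L,
            is.numeric(avg_weights), length(avg_weights) == 2L,
            all(avg_weights >= 0), sum(avg_weights) > 0)
  avg_weights <- avg_weights / sum(avg_weights)
  structure(list(eupnea = eupnea, sigh = sigh,
                 coupling_on = coupling_on, avg_weights = avg_weights),
            class = "prebotc_config")
}

#' @export
print.prebotc_config <- function(x, ...) {
  cat("<prebotc_config> coupling", if (x$coupling_on) "on" else "off", "\n")
  cat("eupnea compartment:\n"); print(x$eupnea)
  cat("sigh compartment:\n"); print(x$sigh)
  invisible(x)
}

# full parameter vector for the compiled right-hand side
pack_parms <- function(config) {
  c(flatten_params(config$eupnea), flatten_params(config$sigh),
    coupling_on = as.numeric(config$coupling_on))
}

#' Apply named parameter edits to a configuration
#'
#' The uniform perturbation mechanism behind every in-silico experiment. Each
#' edit is addressed by a dotted path whose first element selects the target:
#' `"eupnea."`, `"sigh."`, or `"both."` (both compartments), plus the
#' top-level switch `"coupling_on"`. The remainder names a parameter field,
#' descending into gates where needed (e.g. `"sigh.n_gate.V_half"`). An edit
#' value that is a plain number sets the field; a one-argument function (such
#' as [scale_by()]) transforms it.
#'
#' @param config a [network_config()].
#' @param edits named list of edits (may be empty).
#' @return A new `prebotc_config`; the input is not modified.
#' @export
#' @examples
#' cfg <- network_config()
#' half_gca <- perturb(cfg, list(both.gCa = scale_by(0.5)))
#' half_gca$eupnea$gCa  # 0.01 nS
#' no_inh <- perturb(cfg, list(sigh.gsyn = 0))
perturb <- function(config, edits = list()) {
  stopifnot(inherits(config, "prebotc_config"))
  if (length(edits) == 0L) return(config)
  if (is.null(names(edits)) || any(!nzchar(names(edits))))
    stop("every edit must be named by a dotted parameter path")
  for (path in names(edits)) {
    value <- edits[[path]]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (identical(parts, "coupling_on")) {
      if (is.function(value)) value <- value(config$coupling_on)
      config$coupling_on <- as.logical(value)
      next
    }
    target <- parts[1]
    if (!target %in% c("eupnea", "sigh", "both"))
      stop("unknown edit target '", target, "' in path '", path, "'")
    comps <- if (target == "both") c("eupnea", "sigh") else target
    field <- parts[-1]
    if (length(field) == 0L) stop("edit path '", path, "' names no field")
    for (comp in comps) {
      old <- config[[comp]]
      cur <- old
      for (f in field) {
        if (is.null(cur[[f]]))
          stop("unknown parameter field '", paste(field, collapse = "."),
               "' in path '", path, "'")
        cur <- cur[[f]]
      }
      new <- if (is.function(value)) value(cur) else value
      if (!is.numeric(new) && !is.logical(new))
        stop("edit for '", path, "' does not yield a numeric value")
      if (length(field) == 1L) {
        old[[field]] <- new
      } else {
        old[[field[1]]][[field[2]]] <- new
      }
      config[[comp]] <- old
    }
  }
  validate_params(config$eupnea)
  validate_params(config$sigh)
  config
}

#' @rdname perturb
#' @param factor non-negative multiplicative factor.
#' @export
scale_by <- function(factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor >= 0)
  function(x) x * factor
}

#' Read or write a configuration override file
#'
#' Configuration files (YAML or JSON, chosen by extension) mirror the
#' parameter-set field names; any subset of fields overrides the defaults.
#' Top level keys: `eupnea`, `sigh`, `coupling_on`, `avg_weights`.
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @param base configuration to override (defaults to [network_config()]).
#' @return `read_config()` returns a `prebotc_config`; `write_config()`
#'   writes `config` and returns `path` invisibly.
#' @export
read_config <- function(path, base = network_config()) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config file must be .yaml, .yml, or .json: ", path)
  cfg <- unclass(base)
  for (comp in c("eupnea", "sigh")) {
    if (!is.null(raw[[comp]])) {
      ov <- raw[[comp]]
      for (nm in names(ov)) {
        if (is.null(cfg[[comp]][[nm]]))
          stop("unknown parameter field '", nm, "' for ", comp)
        if (nm %in% c("m_gate", "h_gate", "n_gate", "s_gate")) {
          gl <- utils::modifyList(unclass(cfg[[comp]][[nm]]), as.list(ov[[nm]]))
          cfg[[comp]][[nm]] <- gating_params(gl$V_half, gl$slope, gl$tau_bar)
        } else {
          cfg[[comp]][[nm]] <- ov[[nm]]
        }
      }
    }
  }
  if (!is.null(raw$coupling_on)) cfg$coupling_on <- as.logical(raw$coupling_on)
  if (!is.null(raw$avg_weights)) cfg$avg_weights <- as.numeric(raw$avg_weights)
  network_config(eupnea = `class<-`(cfg$eupnea, "prebotc_params"),
                 sigh = `class<-`(cfg$sigh, "prebotc_params"),
                 coupling_on = cfg$coupling_on,
                 avg_weights = cfg$avg_weights)
}

#' @rdname read_config
#' @param config a `prebotc_config` to serialise.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "prebotc_config"))
  strip <- function(ps) {
    ps <- unclass(ps)
    for (g in c("m_gate", "h_gate", "n_gate", "s_gate"))
      ps[[g]] <- Filter(Negate(is.null), unclass(ps[[g]]))
    ps
  }
  out <- list(eupnea = strip(config$eupnea), sigh = strip(config$sigh),
              coupling_on = config$coupling_on,
              avg_weights = config$avg_weights)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else stop("config file must be .yaml, .yml, or .json: ", path)
  invisible(path)
}
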
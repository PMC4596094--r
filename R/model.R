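#' Sigmoidal steady-state gating curve
#'
#' Boltzmann curve \eqn{x_\infty(V) = 1 / (1 + \exp((V - V_{1/2})/s))}, used
#' for the activation/inactivation variables m, h, n and for the synaptic
#' release function H(V).
#'
#' @param V membrane voltage (mV); vectorised.
#' @param gate a [gating_params()] object.
#' @return Gating fraction, strictly in (0, 1).
#' @export
#' @examples
#' h <- gating_params(-48, 5, tau_bar = 1e4)
#' steady_state(-48, h)  # 0.5 at the midpoint
steady_state <- function(V, gate) {
  stopifnot(inherits(gate, "gating_params"))
  1 / (1 + exp((V - gate$V_half) / gate$slope))
}

#' Bell-shaped gating time constant
#'
#' \eqn{\tau_x(V) = \bar\tau_x / \cosh((V - V_{1/2}) / (2 s))}: maximal and
#' equal to `tau_bar` at the half-activation voltage, even-symmetric around
#' it.
#'
#' @inheritParams steady_state
#' @return Time constant (ms).
#' @export
time_constant <- function(V, gate) {
  stopifnot(inherits(gate, "gating_params"))
  if (is.null(gate$tau_bar))
    stop("gate has no tau_bar; it is instantaneous")
  gate$tau_bar / cosh((V - gate$V_half) / (2 * gate$slope))
}

#' Compartment state vector
#'
#' The six dynamic variables of one compartment: membrane voltage, NaP
#' inactivation, synaptic activation, cytosolic and ER calcium, and the
#' IP3-receptor gating variable.
#'
#' @param V voltage (mV).
#' @param h NaP inactivation, in \[0, 1\].
#' @param s synaptic activation, in \[0, 1\].
#' @param Ca_i cytosolic calcium (uM), non-negative.
#' @param Ca_ER ER calcium (uM), non-negative.
#' @param l IP3R gate, in \[0, 1\].
#' @return Named numeric vector of length 6.
#' @export
compartment_state <- function(V, h, s, Ca_i, Ca_ER, l) {
  x <- c(V = V, h = h, s = s, Ca_i = Ca_i, Ca_ER = Ca_ER, l = l)
  if (any(!is.finite(x))) stop("state must be finite")
  if (h < 0 || h > 1 || s < 0 || s > 1 || l < 0 || l > 1)
    stop("gating variables h, s, l must lie in [0, 1]")
  if (Ca_i < 0 || Ca_ER < 0) stop("calcium concentrations must be non-negative")
  x
}

#' Default initial state of one compartment
#'
#' The reported statistics are computed after transient discard, so they are
#' insensitive to this choice: V = -60 mV, h at its steady state, s = 0,
#' cytosolic calcium 0.05 uM, ER calcium 2.5 uM, and the IP3R gate at its
#' fixed point for that calcium level.
#'
#' @param params a [default_parameters()] set.
#' @param V,Ca_i,Ca_ER overridable starting values.
#' @return Named state vector (see [compartment_state()]).
#' @export
initial_state <- function(params, V = -60, Ca_i = 0.05, Ca_ER = 2.5) {
  compartment_state(V = V, h = steady_state(V, params$h_gate), s = 0,
                    Ca_i = Ca_i, Ca_ER = Ca_ER,
                    l = params$Kd / (Ca_i + params$Kd))
}

#' Membrane currents of one compartment
#'
#' All six currents (pA) at a given state: persistent sodium, potassium-
#' dominated leak, voltage-gated calcium (sharing the NaP activation curve),
#' calcium-activated nonspecific cation, hyperpolarisation-activated, and
#' synaptic. The synaptic current uses the presynaptic compartment's
#' activation together with the conductance and reversal of the synapse onto
#' this compartment.
#'
#' @param state compartment state (see [compartment_state()]).
#' @param s_pre presynaptic synaptic activation in \[0, 1\].
#' @param params this compartment's parameter set.
#' @param pre_gsyn,pre_Vsyn conductance (nS) and reversal (mV) of the incoming
#'   synapse; default to this compartment's own column values.
#' @return Named numeric vector `c(I_NaP, I_leak, I_Ca, I_CaN, I_h, I_syn)`.
#' @export
membrane_currents <- function(state, s_pre, params,
                              pre_gsyn = params$gsyn, pre_Vsyn = params$Vsyn) {
  V <- state[["V"]]
  minf <- steady_state(V, params$m_gate)
  c(I_NaP = params$gNaP * minf * state[["h"]] * (V - params$VNaP),
    I_leak = params$gK * (V - params$VK),
    I_Ca = params$gCa * minf * (V - params$VCa),
    I_CaN = params$gCaN * state[["Ca_i"]] / (state[["Ca_i"]] + params$KCaN) *
      (V - params$VNaP),
    I_h = params$gh * steady_state(V, params$n_gate) * (V - params$Eh),
    I_syn = pre_gsyn * s_pre * (V - pre_Vsyn))
}

#' Calcium fluxes of the two-pool model
#'
#' ER release through the IP3 receptor plus leak (`J_ER_in`), SERCA reuptake
#' (`J_ER_out`), voltage-gated influx proportional to the calcium current
#' (`J_PM_in`), and PMCA extrusion (`J_PM_out`).
#'
#' @param state compartment state.
#' @param I_Ca voltage-gated calcium current (pA).
#' @param params parameter set.
#' @return Named numeric vector of the four fluxes.
#' @export
calcium_fluxes <- function(state, I_Ca, params) {
  Ca <- state[["Ca_i"]]
  x <- params$IP3 * Ca * state[["l"]] /
    ((params$IP3 + params$KI) * (Ca + params$Ka))
  c(J_ER_in = (params$LIP3R + params$PIP3R * x^3) * (state[["Ca_ER"]] - Ca),
    J_ER_out = params$VSERCA * Ca^2 / (params$KSERCA^2 + Ca^2),
    J_PM_in = -params$alpha * I_Ca,
    J_PM_out = params$VPMCA * Ca^2 / (params$KPMCA^2 + Ca^2))
}

#' Time derivative of one compartment
#'
#' Right-hand side of the six ordinary differential equations of a single
#' compartment. The ER fluxes enter the calcium balance with the physical
#' sign convention: release raises cytosolic calcium and drains the ER (the
#' source equations print the opposite sign, which contradicts their own
#' prose description of the fluxes).
#'
#' @inheritParams membrane_currents
#' @param own this compartment's parameter set.
#' @param syn_in list with `gsyn` and `Vsyn` of the incoming synapse; defaults
#'   to the compartment's own column values.
#' @return Named derivative vector in the state order.
#' @export
compartment_rhs <- function(state, s_pre, own,
                            syn_in = list(gsyn = own$gsyn, Vsyn = own$Vsyn)) {
  V <- state[["V"]]
  cur <- membrane_currents(state, s_pre, own,
                           pre_gsyn = syn_in$gsyn, pre_Vsyn = syn_in$Vsyn)
  flux <- calcium_fluxes(state, cur[["I_Ca"]], own)
  tau_s <- if (isTRUE(own$s_tau_voltage_dep)) {
    time_constant(V, own$s_gate)
  } else own$s_gate$tau_bar
  J_ER <- flux[["J_ER_in"]] - flux[["J_ER_out"]]
  J_PM <- flux[["J_PM_in"]] - flux[["J_PM_out"]]
  c(V = -sum(cur) / own$Cm,
    h = (steady_state(V, own$h_gate) - state[["h"]]) /
      time_constant(V, own$h_gate),
    s = ((1 - state[["s"]]) * steady_state(V, own$s_gate) -
           own$ksyn * state[["s"]]) / tau_s,
    Ca_i = own$f_i * (J_PM / own$lam + J_ER),
    Ca_ER = -(own$f_i / own$sigma) * J_ER,
    l = own$A_ip3 * (own$Kd - state[["l"]] * (state[["Ca_i"]] + own$Kd)))
}

# fixed layout of the 12-dimensional network state
.state_names <- c(paste0(c("V", "h", "s", "Cai", "CaER", "l"), "_eup"),
                  paste0(c("V", "h", "s", "Cai", "CaER", "l"), "_sigh"))

#' Time derivative of the coupled network
#'
#' Stacks two [compartment_rhs()] calls, wiring eupnea's synaptic activation
#' to the inhibitory synapse onto sigh and sigh's activation to the
#' excitatory synapse onto eupnea. This is the pure-R reference for the
#' compiled right-hand side used by [simulate()].
#'
#' @param t time (ms); unused, the system is autonomous.
#' @param flat_state numeric vector of length 12: eupnea state then sigh state,
#'   each ordered (V, h, s, Ca_i, Ca_ER, l).
#' @param config a [network_config()].
#' @return Numeric vector of length 12 of time derivatives.
#' @export
network_rhs <- function(t, flat_state, config) {
  if (length(flat_state) != 12L)
    stop("flat_state must have length 12 (two compartments)")
  cpl <- as.numeric(config$coupling_on)
  nm <- c("V", "h", "s", "Ca_i", "Ca_ER", "l")
  ye <- stats::setNames(flat_state[1:6], nm)
  ys <- stats::setNames(flat_state[7:12], nm)
  de <- compartment_rhs(ye, s_pre = ys[["s"]], own = config$eupnea,
                        syn_in = list(gsyn = cpl * config$eupnea$gsyn,
                                      Vsyn = config$eupnea$Vsyn))
  ds <- compartment_rhs(ys, s_pre = ye[["s"]], own = config$sigh,
                        syn_in = list(gsyn = cpl * config$sigh$gsyn,
                                      Vsyn = config$sigh$Vsyn))
  stats::setNames(c(de, ds), .state_names)
}
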
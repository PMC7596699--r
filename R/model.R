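#' Gating, rate and current functions of the half-center unit
#'
#' The unit follows an activity-based population formalism: the membrane
#' potential \eqn{V} obeys \eqn{C\,dV/dt = -I_L - I_{NaP} - I_{syn}} with
#' a leak current, a persistent sodium current
#' \eqn{I_{NaP} = g_{NaP}\, m_\infty(V)\, h\,(V - E_{Na})} whose
#' activation is instantaneous and whose inactivation gate \eqn{h}
#' relaxes toward \eqn{h_\infty(V)} with voltage-dependent time constant
#' \eqn{\tau_h(V)}, and a synaptic current combining the excitatory
#' drive conductance and inhibitory inputs weighted by the presynaptic
#' normalized firing rates.
#'
#' @param V membrane potential (mV); vectorized.
#' @param params a \code{\link{unit_params}} object.
#' @return \code{m_inf} and \code{h_inf} return values in (0, 1);
#'   \code{tau_h} a positive time constant (ms); \code{rate_fun} the
#'   normalized firing rate in \[0, 1\].
#' @name unit_functions
NULL

#' @rdname unit_functions
#' @export
m_inf <- function(V, params = unit_params()) {
  1 / (1 + exp((V - params$V_mNaP) / params$k_mNaP))
}

#' @rdname unit_functions
#' @export
h_inf <- function(V, params = unit_params()) {
  1 / (1 + exp((V - params$V_hNaP) / params$k_hNaP))
}

#' @rdname unit_functions
#' @export
tau_h <- function(V, params = unit_params()) {
  params$tau_NaP_max / cosh((V - params$V_tauNaP) / params$k_tauNaP)
}

#' @rdname unit_functions
#' @export
rate_fun <- function(V, params = unit_params()) {
  pmin(1, pmax(0, (V - params$V_min) / (params$V_max - params$V_min)))
}

#' Synaptic current of one unit
#'
#' \eqn{I_{syn,i} = d_i (V_i - E_{ex}) + \sum_j b_{ji} f(V_j) (V_i - E_{inh})},
#' where \eqn{d_i} is the excitatory drive conductance of unit \eqn{i}
#' and \eqn{b_{ji}} the inhibitory weight from unit \eqn{j} to unit
#' \eqn{i}.
#'
#' @param unit unit index in 1..4 (LF, RF, LE, RE).
#' @param state a \code{\link{network_state}}.
#' @param net a \code{\link{network_config}}.
#' @param drives length-4 vector of effective drive conductances (nS),
#'   e.g. from \code{\link{effective_drives}}.
#' @return Synaptic current (pA).
#' @export
synaptic_current <- function(unit, state, net, drives) {
  if (!(unit %in% 1:4)) stop("unit index must be in 1..4", call. = FALSE)
  stopifnot(length(drives) == 4, all(drives >= 0))
  V <- state$V
  f <- vapply(1:4, function(j) rate_fun(V[j], net$units[[j]]), numeric(1))
  drives[unit] * (V[unit] - net$E_ex) +
    sum(net$b[, unit] * f) * (V[unit] - net$E_inh)
}

#' Time derivatives of the full network state
#'
#' Evaluates the model's vector field: for each unit
#' \eqn{dV/dt = -(I_L + I_{NaP} + I_{syn})/C} and
#' \eqn{dh/dt = (h_\infty(V) - h)/\tau_h(V)}.  Also returns the per-unit
#' current breakdown.
#'
#' @param state a \code{\link{network_state}}.
#' @param net a \code{\link{network_config}}.
#' @param drives a \code{\link{drive_config}} object or a length-4
#'   numeric vector of effective drives (nS).
#' @return A list with \code{dV} (mV/ms), \code{dh} (1/ms) and
#'   \code{currents}, a data frame with columns \code{I_L},
#'   \code{I_NaP}, \code{I_syn} (pA, one row per unit).
#' @export
cpg_derivatives <- function(state, net, drives) {
  if (inherits(drives, "cpg_drives")) drives <- effective_drives(drives)
  stopifnot(length(drives) == 4)
  V <- state$V; h <- state$h
  if (any(!is.finite(V)) || any(!is.finite(h)))
    stop("non-finite state", call. = FALSE)
  f <- vapply(1:4, function(j) rate_fun(V[j], net$units[[j]]), numeric(1))
  I_L <- I_NaP <- I_syn <- dV <- dh <- numeric(4)
  for (i in 1:4) {
    p <- net$units[[i]]
    I_L[i] <- p$g_L * (V[i] - p$E_L)
    I_NaP[i] <- p$g_NaP * m_inf(V[i], p) * h[i] * (V[i] - p$E_Na)
    I_syn[i] <- drives[i] * (V[i] - net$E_ex) +
      sum(net$b[, i] * f) * (V[i] - net$E_inh)
    dV[i] <- -(I_L[i] + I_NaP[i] + I_syn[i]) / p$C
    dh[i] <- (h_inf(V[i], p) - h[i]) / tau_h(V[i], p)
  }
  list(dV = dV, dh = dh,
       currents = data.frame(unit = .unit_names, I_L = I_L,
                             I_NaP = I_NaP, I_syn = I_syn))
}
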
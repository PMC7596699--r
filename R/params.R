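#' Biophysical parameters of one half-center unit
#'
#' Constructs the parameter set of a single activity-based half-center
#' population: a leaky membrane with a slowly inactivating persistent
#' sodium current (INaP) whose inactivation gate paces intrinsic
#' bursting, and a piecewise-linear voltage-to-rate output.  Defaults are
#' the reference parameter set of the model (identical for flexor and
#' extensor half-centers).
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV).
#' @param g_NaP maximal persistent-sodium conductance (nS).
#' @param E_Na sodium reversal potential (mV).
#' @param V_mNaP,k_mNaP half-activation voltage (mV) and slope (mV) of the
#'   instantaneous INaP activation sigmoid; \code{k_mNaP < 0} so that
#'   activation rises with voltage.
#' @param V_hNaP,k_hNaP half-inactivation voltage (mV) and slope (mV) of
#'   the INaP inactivation sigmoid; \code{k_hNaP > 0} so that
#'   inactivation falls with voltage.
#' @param tau_NaP_max peak inactivation time constant (ms, positive).
#' @param V_tauNaP,k_tauNaP centre (mV) and width (mV) of the sech-shaped
#'   voltage dependence of the inactivation time constant.
#' @param V_min,V_max threshold and saturation voltages (mV) of the
#'   piecewise-linear rate function.
#'
#' @return An object of class \code{cpg_unit_params}.
#' @seealso [m_inf()], [h_inf()], [tau_h()], [rate_fun()]
#' @export
#' @examples
#' p <- unit_params()
#' m_inf(p$V_mNaP, p) # 0.5 at half-activation
unit_params <- function(C = 20, g_L = 2.8, E_L = -65, g_NaP = 5, E_Na = 50,
                        V_mNaP = -40, k_mNaP = -6, V_hNaP = -50, k_hNaP = 10,
                        tau_NaP_max = 1500, V_tauNaP = -100, k_tauNaP = 40,
                        V_min = -50, V_max = 0) {
  p <- list(C = C, g_L = g_L, E_L = E_L, g_NaP = g_NaP, E_Na = E_Na,
            V_mNaP = V_mNaP, k_mNaP = k_mNaP, V_hNaP = V_hNaP,
            k_hNaP = k_hNaP, tau_NaP_max = tau_NaP_max,
            V_tauNaP = V_tauNaP, k_tauNaP = k_tauNaP,
            V_min = V_min, V_max = V_max)
  errs <- character()
  if (!is.finite(C) || C <= 0) errs <- c(errs, "C must be > 0")
  if (g_L < 0) errs <- c(errs, "g_L must be >= 0")
  if (g_NaP < 0) errs <- c(errs, "g_NaP must be >= 0")
  if (!(V_max > V_min)) errs <- c(errs, "V_max must exceed V_min")
  if (tau_NaP_max <= 0) errs <- c(errs, "tau_NaP_max must be > 0")
  if (k_mNaP >= 0) errs <- c(errs, "k_mNaP must be < 0 (rising activation)")
  if (k_hNaP <= 0) errs <- c(errs, "k_hNaP must be > 0 (falling inactivation)")
  if (length(errs)) stop("invalid unit parameters: ",
                         paste(errs, collapse = "; "), call. = FALSE)
  structure(p, class = "cpg_unit_params")
}

#' @export
print.cpg_unit_params <- function(x, ...) {
  cat("Half-center unit parameters\n")
  cat(sprintf("  C = %g pF, g_L = %g nS, E_L = %g mV, g_NaP = %g nS, E_Na = %g mV\n",
              x$C, x$g_L, x$E_L, x$g_NaP, x$E_Na))
  cat(sprintf("  INaP activation: V_mNaP = %g, k_mNaP = %g; inactivation: V_hNaP = %g, k_hNaP = %g\n",
              x$V_mNaP, x$k_mNaP, x$V_hNaP, x$k_hNaP))
  cat(sprintf("  tau_NaP: max = %g ms at V = %g mV (width %g mV)\n",
              x$tau_NaP_max, x$V_tauNaP, x$k_tauNaP))
  cat(sprintf("  rate function: V_min = %g mV, V_max = %g mV\n", x$V_min, x$V_max))
  invisible(x)
}

# unit indexing used throughout: 1 = left flexor, 2 = right flexor,
# 3 = left extensor, 4 = right extensor
.unit_names <- c("LF", "RF", "LE", "RE")

#' Bilateral network configuration
#'
#' Assembles the four-unit network (left/right flexor and extensor
#' half-centers) with its inhibitory connection matrix.  Within each
#' rhythm generator the flexor and extensor half-centers inhibit each
#' other reciprocally; between the two sides the flexor half-centers
#' inhibit each other (F-F inhibition, lumping the V0-mediated
#' commissural pathways) and each extensor half-center inhibits the
#' contralateral flexor (crossed E-F inhibition, lumping the V3/V1
#' pathway).  The weight matrix \code{b} is indexed
#' \code{b[source, target]} over units (1 left flexor, 2 right flexor,
#' 3 left extensor, 4 right extensor), matching the synaptic sum of the
#' voltage equation.
#'
#' @param FF flexor-flexor commissural inhibition weight (nS), applied
#'   symmetrically (\code{b[1,2] = b[2,1]}).
#' @param EF crossed extensor-flexor inhibition weight (nS), applied
#'   symmetrically (\code{b[4,1] = b[3,2]}).
#' @param EF_within within-RG extensor-to-flexor inhibition weight (nS),
#'   \code{b[3,1] = b[4,2]}.
#' @param FE_within within-RG flexor-to-extensor inhibition weight (nS),
#'   \code{b[1,3] = b[2,4]}.
#' @param E_ex,E_inh excitatory and inhibitory synaptic reversal
#'   potentials (mV).
#' @param units a single \code{\link{unit_params}} object applied to all
#'   four units, or a list of four such objects.
#' @param b optional explicit 4x4 weight matrix overriding the
#'   weight arguments; must respect the structural zeros (no
#'   flexor-to-contralateral-extensor, no extensor-extensor coupling)
#'   and have a zero diagonal.
#'
#' @return An object of class \code{cpg_network}.
#' @export
#' @examples
#' net <- network_config(FF = 0.4, EF = 0.2)
#' net$b
network_config <- function(FF = 0.4, EF = 0.2, EF_within = 0.5,
                           FE_within = 1, E_ex = -10, E_inh = -90,
                           units = unit_params(), b = NULL) {
  if (is.null(b)) {
    b <- matrix(0, 4, 4, dimnames = list(.unit_names, .unit_names))
    b[1, 2] <- b[2, 1] <- FF
    b[4, 1] <- b[3, 2] <- EF
    b[3, 1] <- b[4, 2] <- EF_within
    b[1, 3] <- b[2, 4] <- FE_within
  } else {
    b <- as.matrix(b)
    dimnames(b) <- list(.unit_names, .unit_names)
  }
  errs <- character()
  if (any(b < 0)) errs <- c(errs, "all synaptic weights must be >= 0")
  if (any(diag(b) != 0)) errs <- c(errs, "self-connections must be 0")
  # structural zeros: flexors never inhibit contralateral extensors and
  # extensor half-centers are not directly coupled
  zero_idx <- rbind(c(1, 4), c(2, 3), c(3, 4), c(4, 3))
  if (any(b[zero_idx] != 0))
    errs <- c(errs, "structural zeros violated (b[1,4], b[2,3], b[3,4], b[4,3] must be 0)")
  if (length(errs)) stop("invalid network configuration: ",
                         paste(errs, collapse = "; "), call. = FALSE)
  if (inherits(units, "cpg_unit_params")) units <- rep(list(units), 4)
  stopifnot(length(units) == 4)
  structure(list(b = b, E_ex = E_ex, E_inh = E_inh, units = units),
            class = "cpg_network")
}

#' @export
print.cpg_network <- function(x, ...) {
  cat("Bilateral CPG network (units: LF, RF, LE, RE)\n")
  cat(sprintf("  F-F inhibition  = %g nS, crossed E-F inhibition = %g nS\n",
              x$b[1, 2], x$b[4, 1]))
  cat(sprintf("  within-RG: F->E = %g nS, E->F = %g nS\n", x$b[1, 3], x$b[3, 1]))
  cat(sprintf("  E_ex = %g mV, E_inh = %g mV\n", x$E_ex, x$E_inh))
  invisible(x)
}

#' Drive configuration with flexor-to-extensor drive coupling
#'
#' The tonic excitatory drive (an excitatory synaptic conductance, the
#' model's proxy for a locomotor speed command) is set independently for
#' the left and right flexor half-centers.  When \code{coupled = TRUE}
#' the same flexor drive also inhibits the ipsilateral extensor
#' half-center, so the net extensor drive is the constant gross extensor
#' drive \code{D_E0} minus the ipsilateral flexor drive.  When
#' \code{coupled = FALSE} the net extensor drives are set explicitly
#' (the uncoupled control used to isolate the effect of the coupling
#' rule).
#'
#' @param d_F_left,d_F_right flexor drives (nS conductance scale).
#' @param D_E0 gross extensor drive (nS); the net extensor drive on each
#'   side is \code{D_E0 - d_F} when coupled.  The default 1.4 places the
#'   flexor/extensor drive-equality point at flexor drive 0.7.
#' @param coupled logical; apply the drive-coupling rule?
#' @param d_E_left,d_E_right explicit net extensor drives (nS), used only
#'   when \code{coupled = FALSE}.
#'
#' @return An object of class \code{cpg_drives}.
#' @seealso [net_extensor_drives()], [effective_drives()]
#' @export
#' @examples
#' net_extensor_drives(drive_config(0.7, 0.7))  # c(0.7, 0.7)
drive_config <- function(d_F_left = 0.5, d_F_right = d_F_left, D_E0 = 1.4,
                         coupled = TRUE, d_E_left = 0.7, d_E_right = d_E_left) {
  vals <- c(d_F_left, d_F_right, D_E0, d_E_left, d_E_right)
  if (any(!is.finite(vals)) || any(c(d_F_left, d_F_right, d_E_left, d_E_right) < 0))
    stop("drives must be finite and >= 0", call. = FALSE)
  structure(list(d_F_left = d_F_left, d_F_right = d_F_right, D_E0 = D_E0,
                 coupled = isTRUE(coupled),
                 d_E_left = d_E_left, d_E_right = d_E_right),
            class = "cpg_drives")
}

#' @export
print.cpg_drives <- function(x, ...) {
  if (x$coupled)
    cat(sprintf("Drives: flexors (%g, %g); extensors coupled, net = %g - d_F = (%g, %g)\n",
                x$d_F_left, x$d_F_right, x$D_E0,
                max(0, x$D_E0 - x$d_F_left), max(0, x$D_E0 - x$d_F_right)))
  else
    cat(sprintf("Drives: flexors (%g, %g); extensors fixed at (%g, %g) (uncoupled)\n",
                x$d_F_left, x$d_F_right, x$d_E_left, x$d_E_right))
  invisible(x)
}

#' Net drives to the extensor half-centers
#'
#' Under drive coupling the net extensor drive is \code{D_E0 - d_F},
#' floored at zero (a negative conductance is unphysical); a warning is
#' raised whenever flooring occurs.  Without coupling the explicit
#' extensor drives are returned unchanged.
#'
#' @param drives a \code{\link{drive_config}} object.
#' @return Numeric length-2 vector \code{c(left, right)} (nS).
#' @export
net_extensor_drives <- function(drives) {
  stopifnot(inherits(drives, "cpg_drives"))
  if (!drives$coupled) return(c(drives$d_E_left, drives$d_E_right))
  dE <- drives$D_E0 - c(drives$d_F_left, drives$d_F_right)
  if (any(dE < 0)) {
    warning("net extensor drive clamped at 0 (flexor drive exceeds D_E0)",
            call. = FALSE)
    dE <- pmax(dE, 0)
  }
  dE
}

#' Effective drive vector for all four units
#'
#' @param drives a \code{\link{drive_config}} object.
#' @return Numeric length-4 vector of drive conductances (nS) in unit
#'   order (LF, RF, LE, RE).
#' @export
effective_drives <- function(drives) {
  dE <- net_extensor_drives(drives)
  c(drives$d_F_left, drives$d_F_right, dE[1], dE[2])
}

#' Network state
#'
#' @param V length-4 vector of membrane potentials (mV), unit order
#'   (LF, RF, LE, RE).
#' @param h length-4 vector of INaP inactivation gates in \[0, 1\];
#'   defaults to the voltage-matched steady state \code{h_inf(V)}.
#' @param t time (ms).
#' @param params unit parameters used for the \code{h_inf} default.
#' @return An object of class \code{cpg_state}.
#' @export
network_state <- function(V, h = NULL, t = 0, params = unit_params()) {
  stopifnot(length(V) == 4, all(is.finite(V)))
  if (is.null(h)) h <- h_inf(V, params)
  stopifnot(length(h) == 4, all(h >= 0 & h <= 1))
  structure(list(t = t, V = as.numeric(V), h = as.numeric(h)),
            class = "cpg_state")
}

#' Default initial conditions
#'
#' Two canonical seeds are used throughout: the \emph{anti-phase seed}
#' (left flexor depolarized at -30 mV, everything else at -65 mV) and the
#' \emph{in-phase seed} (both flexors depolarized).  The in-phase seed
#' carries a 1 mV left-right asymmetry: exactly symmetric initial
#' conditions lie on the invariant synchrony manifold of a left-right
#' symmetric configuration and could never reveal an instability of the
#' in-phase solution.
#'
#' @param seed \code{"antiphase"} or \code{"inphase"}.
#' @param params unit parameters for the matched \code{h_inf} gates.
#' @return A \code{\link{network_state}}.
#' @export
default_state <- function(seed = c("antiphase", "inphase"),
                          params = unit_params()) {
  seed <- match.arg(seed)
  V <- switch(seed,
              antiphase = c(-30, -65, -65, -65),
              inphase   = c(-30, -31, -65, -65))
  network_state(V, params = params)
}
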
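# pack network + drives into the flat parameter vector expected by the
# compiled right-hand side (see src/cpg_rhs.c for the layout)
.pack_parms <- function(net, d4) {
  up <- unlist(lapply(net$units, function(p)
    c(p$C, p$g_L, p$E_L, p$g_NaP, p$E_Na, p$V_mNaP, p$k_mNaP,
      p$V_hNaP, p$k_hNaP, p$tau_NaP_max, p$V_tauNaP, p$k_tauNaP,
      p$V_min, p$V_max)))
  c(up, net$E_ex, net$E_inh, d4, as.vector(net$b))
}

#' Integrate the bilateral CPG model
#'
#' Integrates the eight-dimensional system (four membrane potentials,
#' four INaP inactivation gates) and returns the solution sampled on a
#' uniform 1 ms grid together with the normalized firing rates.  The
#' default solver is adaptive \code{lsoda} on a right-hand side compiled
#' in C; a fixed-step classical Runge-Kutta integrator
#' (\code{method = "rk4"}) and a pure-R evaluation of the vector field
#' (\code{engine = "R"}) are available as cross-validation paths.
#'
#' @param net a \code{\link{network_config}}.
#' @param drives a \code{\link{drive_config}}.
#' @param duration simulated time (ms).
#' @param init a \code{\link{network_state}} or one of
#'   \code{"antiphase"}, \code{"inphase"} (see
#'   \code{\link{default_state}}).
#' @param method \code{"lsoda"} (adaptive) or \code{"rk4"} (fixed step).
#' @param dt output sampling interval (ms).
#' @param rtol,atol relative/absolute tolerances for the adaptive solver.
#' @param rk_dt internal step (ms) of the fixed-step integrator.
#' @param engine \code{"compiled"} (C right-hand side) or \code{"R"}
#'   (calls \code{\link{cpg_derivatives}}; slow, for validation).
#' @return A \code{cpg_trace}: a data frame with columns \code{t},
#'   \code{V1..V4}, \code{h1..h4}, \code{f1..f4} and attributes
#'   \code{net}, \code{drives} and \code{solver}.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_cpg(network_config(FF = 0, EF = 0), drive_config(0.4),
#'                    duration = 20000)
#' cycle_metrics(detect_bursts(tr, unit = 1))
#' }
simulate_cpg <- function(net = network_config(), drives = drive_config(),
                         duration = 40000, init = "antiphase",
                         method = c("lsoda", "rk4"), dt = 1,
                         rtol = 1e-8, atol = 1e-8, rk_dt = 0.05,
                         engine = c("compiled", "R")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  stopifnot(duration > 0)
  if (is.character(init)) init <- default_state(init, net$units[[1]])
  stopifnot(inherits(init, "cpg_state"))
  d4 <- effective_drives(drives)
  y0 <- c(init$V, init$h)
  times <- seq(0, duration, by = dt)
  if (engine == "compiled") {
    parms <- .pack_parms(net, d4)
    out <- if (method == "lsoda") {
      deSolve::ode(y0, times, func = "cpg_derivs", parms = parms,
                   dllname = "cpgcoord", initfunc = "cpg_initmod",
                   method = "lsoda", rtol = rtol, atol = atol)
    } else {
      deSolve::rk4(y0, seq(0, duration, by = rk_dt), func = "cpg_derivs",
                   parms = parms, dllname = "cpgcoord",
                   initfunc = "cpg_initmod")
    }
  } else {
    rhs <- function(t, y, parms) {
      st <- network_state(y[1:4], pmin(1, pmax(0, y[5:8])))
      dd <- cpg_derivatives(st, net, d4)
      list(c(dd$dV, dd$dh))
    }
    out <- if (method == "lsoda") {
      deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                   rtol = rtol, atol = atol)
    } else {
      deSolve::rk4(y0, seq(0, duration, by = rk_dt), rhs, parms = NULL)
    }
  }
  out <- as.matrix(out)
  if (method == "rk4" && rk_dt != dt) {
    # resample the fine rk4 grid onto the requested output grid
    idx <- match(round(times / rk_dt), round(out[, 1] / rk_dt))
    out <- out[idx, , drop = FALSE]
  }
  if (any(!is.finite(out)))
    stop("non-finite state encountered during integration", call. = FALSE)
  tr <- data.frame(t = out[, 1],
                   V1 = out[, 2], V2 = out[, 3], V3 = out[, 4], V4 = out[, 5],
                   h1 = out[, 6], h2 = out[, 7], h3 = out[, 8], h4 = out[, 9])
  for (i in 1:4)
    tr[[paste0("f", i)]] <- rate_fun(tr[[paste0("V", i)]], net$units[[i]])
  structure(tr,
            net = net, drives = drives,
            solver = list(method = method, engine = engine, dt = dt,
                          rtol = rtol, atol = atol, rk_dt = rk_dt),
            class = c("cpg_trace", "data.frame"))
}

#' @export
print.cpg_trace <- function(x, ...) {
  s <- attr(x, "solver")
  cat(sprintf("CPG trace: %d samples over %g ms (%s, %s engine)\n",
              nrow(x), max(x$t), s$method, s$engine))
  dr <- attr(x, "drives")
  if (!is.null(dr)) print(dr)
  invisible(x)
}

#' Plot a simulated trace
#'
#' Draws the normalized firing rate of the four units (flexors above,
#' extensors below), the standard way the model's activity patterns are
#' displayed.
#'
#' @param x a \code{cpg_trace}.
#' @param units which units to draw (default all four).
#' @param from start time (ms) of the plotted window.
#' @param ... passed to \code{matplot}.
#' @export
plot.cpg_trace <- function(x, units = 1:4, from = 0, ...) {
  keep <- x$t >= from
  cols <- c("navy", "firebrick", "darkgreen", "darkorange")[units]
  graphics::matplot(x$t[keep] / 1000,
                    as.matrix(x[keep, paste0("f", units), drop = FALSE]),
                    type = "l", lty = 1, col = cols,
                    xlab = "time (s)", ylab = "activity f(V)", ...)
  graphics::legend("topright", legend = .unit_names[units], col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}
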
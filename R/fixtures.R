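#' Specification of a synthetic trace with planted bursts
#'
#' Describes a ground-truth burst schedule from which a synthetic
#' activity trace can be generated.  Used to validate the burst
#' detector: at zero noise the planted schedule is recovered exactly.
#'
#' @param bursts a list of data frames (one per unit, up to 4), each
#'   with columns \code{onset} and \code{offset} (ms); missing units
#'   stay silent.
#' @param noise Gaussian noise amplitude on the activity scale
#'   (fraction of the 0..1 rate range).
#' @param dt sample interval (ms).
#' @param duration trace length (ms); defaults to the last offset plus
#'   500 ms.
#' @param level plateau activity level of a planted burst (0..1).
#' @return An object of class \code{cpg_fixture_spec}.
#' @export
fixture_spec <- function(bursts, noise = 0, dt = 1, duration = NULL,
                         level = 0.8) {
  if (is.data.frame(bursts)) bursts <- list(bursts)
  stopifnot(length(bursts) >= 1, length(bursts) <= 4,
            noise >= 0, dt > 0, level > 0, level <= 1)
  for (b in bursts) {
    if (!nrow(b)) next
    stopifnot(all(b$offset > b$onset),
              !is.unsorted(b$onset, strictly = TRUE),
              all(utils::head(b$offset, -1) <= utils::tail(b$onset, -1)))
  }
  if (is.null(duration))
    duration <- max(vapply(bursts, function(b)
      if (nrow(b)) max(b$offset) else 0, numeric(1))) + 500
  structure(list(bursts = bursts, noise = noise, dt = dt,
                 duration = duration, level = level),
            class = "cpg_fixture_spec")
}

#' Generate a synthetic trace from a fixture specification
#'
#' Builds a trace whose activity is \code{level} inside each planted
#' burst interval (half-open, \code{[onset, offset)}) and 0 outside,
#' realized through the voltage channel so that the trace satisfies the
#' pointwise \code{f = rate_fun(V)} invariant; optional Gaussian noise
#' is added to the voltage.  Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param seed integer seed for the noise generator.
#' @param params unit parameters defining the rate function.
#' @return A \code{cpg_trace} data frame.
#' @export
#' @examples
#' sp <- fixture_spec(data.frame(onset = c(100, 500), offset = c(300, 700)))
#' tr <- generate_fixture(sp)
#' detect_bursts(tr, unit = 1, transient = 0)
generate_fixture <- function(spec, seed = 0, params = unit_params()) {
  stopifnot(inherits(spec, "cpg_fixture_spec"))
  set.seed(seed)
  t <- seq(0, spec$duration, by = spec$dt)
  span <- params$V_max - params$V_min
  V_on <- params$V_min + spec$level * span
  V_off <- params$E_L
  tr <- data.frame(t = t)
  for (u in 1:4) {
    V <- rep(V_off, length(t))
    if (u <= length(spec$bursts)) {
      b <- spec$bursts[[u]]
      for (k in seq_len(nrow(b)))
        V[t >= b$onset[k] & t < b$offset[k]] <- V_on
    }
    if (spec$noise > 0)
      V <- V + stats::rnorm(length(t), sd = spec$noise * span)
    tr[[paste0("V", u)]] <- V
  }
  for (u in 1:4) tr[[paste0("h", u)]] <- h_inf(tr[[paste0("V", u)]], params)
  for (u in 1:4) tr[[paste0("f", u)]] <- rate_fun(tr[[paste0("V", u)]], params)
  structure(tr, planted = spec, solver = list(method = "fixture"),
            class = c("cpg_trace", "data.frame"))
}
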
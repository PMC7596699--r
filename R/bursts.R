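#' Detect bursts in a unit's activity trace
#'
#' Burst onsets are upward crossings of the activity \code{f} through
#' \code{on}; offsets are downward crossings through \code{off}.  The
#' hysteresis (\code{on > off}) avoids chatter near the rate threshold.
#' Bursts that are incomplete at either edge of the analysis window are
#' discarded, as is an initial window starting inside a burst.
#'
#' @param trace a \code{cpg_trace} (or any data frame with columns
#'   \code{t} and \code{f<unit>}).
#' @param unit unit index 1..4 (1 left flexor, 2 right flexor, 3 left
#'   extensor, 4 right extensor).
#' @param on,off onset and offset thresholds on the normalized rate;
#'   must satisfy \code{on > off >= 0}.
#' @param transient initial time (ms) discarded before detection.
#' @return A \code{cpg_bursts} object: data frame with columns
#'   \code{onset}, \code{offset} (ms), attribute \code{unit}.  May have
#'   zero rows.
#' @export
detect_bursts <- function(trace, unit = 1, on = 0.10, off = 0.05,
                          transient = 10000) {
  stopifnot(on > off, off >= 0)
  f <- trace[[paste0("f", unit)]]
  t <- trace$t
  keep <- t >= transient
  f <- f[keep]; t <- t[keep]
  onsets <- numeric(0); offsets <- numeric(0)
  inburst <- f[1] >= on     # burst already in progress: discard it
  started <- !inburst       # only count onsets after a clean baseline
  for (i in seq_along(f)) {
    if (!inburst && f[i] >= on) {
      inburst <- TRUE
      if (started) onsets <- c(onsets, t[i])
    } else if (inburst && f[i] <= off) {
      inburst <- FALSE
      started <- TRUE
      if (length(onsets) > length(offsets)) offsets <- c(offsets, t[i])
    }
  }
  n <- min(length(onsets), length(offsets))  # drop trailing partial burst
  res <- data.frame(onset = onsets[seq_len(n)], offset = offsets[seq_len(n)])
  structure(res, unit = unit, thresholds = c(on = on, off = off),
            class = c("cpg_bursts", "data.frame"))
}

#' @export
print.cpg_bursts <- function(x, ...) {
  cat(sprintf("Burst train, unit %d (%s): %d complete bursts\n",
              attr(x, "unit"), .unit_names[attr(x, "unit")], nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 8))
  invisible(x)
}

#' Cycle metrics from a burst train
#'
#' The period is the mean onset-to-onset interval, flexion duration the
#' mean burst length, extension duration their difference (valid for a
#' 1:1 flexor-extensor rhythm read from the flexor), and the duty cycle
#' flexion/period.  Regularity is the coefficient of variation of the
#' last cycles' periods; a rhythm with CV above \code{cv_tol} is flagged
#' irregular.
#'
#' @param bursts a \code{cpg_bursts} object with at least 3 complete
#'   bursts.
#' @param cv_tol regularity tolerance on the coefficient of variation of
#'   the period over the last \code{n_last} cycles.
#' @param n_last number of trailing cycles used for the regularity test.
#' @return A \code{cpg_cycle_metrics} list: \code{period},
#'   \code{flexion_duration}, \code{extension_duration} (ms),
#'   \code{frequency} (Hz), \code{duty_cycle}, \code{n_cycles_used},
#'   \code{regularity} (CV) and \code{regular} (logical).
#' @export
cycle_metrics <- function(bursts, cv_tol = 0.02, n_last = 5) {
  if (nrow(bursts) < 3)
    stop("non-oscillatory: fewer than 3 complete bursts", call. = FALSE)
  periods <- diff(bursts$onset)
  lens <- bursts$offset - bursts$onset
  tail_p <- utils::tail(periods, n_last)
  cv <- stats::sd(tail_p) / mean(tail_p)
  period <- mean(periods)
  flex <- mean(lens)
  structure(list(period = period,
                 flexion_duration = flex,
                 extension_duration = period - flex,
                 frequency = 1000 / period,
                 duty_cycle = flex / period,
                 n_cycles_used = length(periods),
                 regularity = cv,
                 regular = is.finite(cv) && cv < cv_tol),
            class = "cpg_cycle_metrics")
}

#' @export
print.cpg_cycle_metrics <- function(x, ...) {
  cat(sprintf("period %.1f ms (%.3f Hz), flexion %.1f ms, extension %.1f ms, duty %.3f\n",
              x$period, x$frequency, x$flexion_duration,
              x$extension_duration, x$duty_cycle))
  cat(sprintf("%d cycles, period CV %.4f (%s)\n", x$n_cycles_used,
              x$regularity, if (x$regular) "regular" else "irregular"))
  invisible(x)
}

#' Left-right phase difference between two burst trains
#'
#' For each left onset, the phase is the fractional position of the
#' first following right onset within the left cycle.  The circular mean
#' and circular standard deviation over cycles are returned: 0 means
#' synchrony, 0.5 exact alternation.
#'
#' @param left,right \code{cpg_bursts} objects with at least 3 bursts
#'   each.
#' @return A list with \code{phase} (circular mean in \[0, 1)),
#'   \code{dispersion} (circular SD, in cycle fractions), \code{n} and
#'   the per-cycle \code{phases}.
#' @export
phase_difference <- function(left, right) {
  if (nrow(left) < 3 || nrow(right) < 3)
    stop("both trains need at least 3 bursts", call. = FALSE)
  if (max(right$onset) < min(left$onset) || max(left$onset) < min(right$onset))
    stop("burst trains do not overlap in time", call. = FALSE)
  ph <- numeric(0)
  for (i in seq_len(nrow(left) - 1)) {
    per <- left$onset[i + 1] - left$onset[i]
    nxt <- right$onset[right$onset >= left$onset[i]]
    if (length(nxt))
      ph <- c(ph, ((nxt[1] - left$onset[i]) / per) %% 1)
  }
  ang <- 2 * pi * ph
  C <- mean(cos(ang)); S <- mean(sin(ang))
  R <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) / (2 * pi)) %% 1
  list(phase = mu,
       dispersion = sqrt(pmax(0, -2 * log(R))) / (2 * pi),
       n = length(ph), phases = ph)
}

#' Classify the activity mode of an isolated half-center
#'
#' Simulates a single unit (no synaptic input except its excitatory
#' drive) to steady behavior and labels it \code{"quiescent"} (activity
#' stays below the burst-onset threshold), \code{"tonic"} (activity
#' stays above the offset threshold without completing bursts) or
#' \code{"bursting"}.  A unit whose oscillation has not settled at the
#' horizon (one or two complete bursts only) is flagged
#' \code{"indeterminate"}.
#'
#' @param params a \code{\link{unit_params}} object.
#' @param drive excitatory drive conductance (nS).
#' @param duration,transient simulation horizon and discarded initial
#'   time (ms).
#' @param on,off burst detection thresholds.
#' @param E_ex excitatory reversal potential (mV).
#' @return One of \code{"quiescent"}, \code{"bursting"}, \code{"tonic"},
#'   \code{"indeterminate"}.
#' @export
classify_unit_mode <- function(params = unit_params(), drive,
                               duration = 40000, transient = 10000,
                               on = 0.10, off = 0.05, E_ex = -10) {
  net <- network_config(FF = 0, EF = 0, EF_within = 0, FE_within = 0,
                        E_ex = E_ex, units = params)
  drv <- drive_config(d_F_left = drive, d_F_right = 0, coupled = FALSE,
                      d_E_left = 0, d_E_right = 0)
  tr <- simulate_cpg(net, drv, duration = duration,
                     init = network_state(c(-65, -65, -65, -65),
                                          params = params))
  b <- detect_bursts(tr, unit = 1, on = on, off = off,
                     transient = transient)
  f <- tr$f1[tr$t >= transient]
  if (nrow(b) >= 3) return("bursting")
  if (nrow(b) >= 1) return("indeterminate")
  if (max(f) < on) return("quiescent")
  if (min(f) > off) return("tonic")
  "indeterminate"
}

#' Interlimb coordination ratio (1:n phase locking)
#'
#' Counts fast-side flexor bursts whose onsets fall strictly within each
#' slow-side flexor cycle (onset-to-onset).  If at least
#' \code{consistency} of the cycles carry the same integer count
#' \eqn{n}, the coordination is labeled \code{1:n}; otherwise it is
#' intermittent.
#'
#' @param slow,fast \code{cpg_bursts} of the slow and fast flexor; the
#'   slow train needs at least \code{min_cycles} complete cycles.
#' @param min_cycles minimum number of slow cycles required.
#' @param consistency fraction of cycles that must share the modal
#'   count.
#' @return A list with \code{label} (\code{"1:n"} or
#'   \code{"intermittent"}), \code{n} (integer, \code{NA} if
#'   intermittent), \code{counts} per cycle and \code{consistency}
#'   achieved.
#' @export
coordination_ratio <- function(slow, fast, min_cycles = 10,
                               consistency = 0.9) {
  if (nrow(slow) < min_cycles + 1)
    stop(sprintf("need at least %d complete slow cycles (got %d)",
                 min_cycles, max(0, nrow(slow) - 1)), call. = FALSE)
  counts <- vapply(seq_len(nrow(slow) - 1), function(i)
    sum(fast$onset >= slow$onset[i] & fast$onset < slow$onset[i + 1]),
    integer(1))
  tab <- table(counts)
  frac <- max(tab) / length(counts)
  if (frac >= consistency) {
    n <- as.integer(names(tab)[which.max(tab)])
    list(label = sprintf("1:%d", n), n = n, counts = counts,
         consistency = frac)
  } else {
    list(label = "intermittent", n = NA_integer_, counts = counts,
         consistency = frac)
  }
}
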
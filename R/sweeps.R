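# reference commissural weights: F-F inhibition 0.4, crossed E-F 0.2 --
# a point inside the monostable anti-phase region at all drives
.ref_net <- function() network_config(FF = 0.4, EF = 0.2)

# isolated single rhythm generator: commissural weights zero
.single_rg_net <- function() network_config(FF = 0, EF = 0)

.metrics_or_na <- function(tr, unit, transient, on = 0.10, off = 0.05) {
  b <- detect_bursts(tr, unit, on = on, off = off, transient = transient)
  if (nrow(b) < 3)
    return(list(period = NA_real_, flexion_duration = NA_real_,
                extension_duration = NA_real_, frequency = NA_real_,
                duty_cycle = NA_real_, n_cycles_used = nrow(b),
                regularity = NA_real_, regular = FALSE))
  cycle_metrics(b)
}

#' Drive sweep of the isolated single rhythm generator
#'
#' Simulates one flexor-extensor rhythm generator (commissural weights
#' zero) across a grid of flexor drives under the drive-coupling rule
#' (net extensor drive \code{D_E0 - d_F}) and measures period, flexion
#' and extension durations and burst frequency from the flexor burst
#' train.
#'
#' @param drive_grid flexor drive values (nS).
#' @param D_E0 gross extensor drive (nS).
#' @param duration,transient simulation horizon and discarded transient
#'   (ms).
#' @param coupled logical; if \code{FALSE} the net extensor drive is
#'   held at \code{fixed_E} for every grid point (control experiment).
#' @param fixed_E net extensor drive (nS) used when
#'   \code{coupled = FALSE}.
#' @param net network configuration; defaults to the isolated RG.
#' @return A \code{cpg_sweep} data frame with one row per drive value:
#'   \code{drive}, \code{period}, \code{flexion}, \code{extension} (ms),
#'   \code{frequency} (Hz), \code{duty}, \code{cv}, \code{regular}.
#' @export
#' @examples
#' \donttest{
#' sw <- single_rg_sweep(seq(0.2, 0.8, 0.1))
#' plot(sw)
#' }
single_rg_sweep <- function(drive_grid = seq(0.2, 0.8, by = 0.01),
                            D_E0 = 1.4, duration = 40000,
                            transient = 10000, coupled = TRUE,
                            fixed_E = 0.7, net = .single_rg_net()) {
  rows <- lapply(drive_grid, function(dF) {
    drv <- if (coupled)
      drive_config(dF, dF, D_E0 = D_E0)
    else
      drive_config(dF, dF, coupled = FALSE, d_E_left = fixed_E)
    tr <- simulate_cpg(net, drv, duration = duration)
    m <- .metrics_or_na(tr, 1, transient)
    data.frame(drive = dF, period = m$period, flexion = m$flexion_duration,
               extension = m$extension_duration, frequency = m$frequency,
               duty = m$duty_cycle, cv = m$regularity,
               regular = m$regular)
  })
  structure(do.call(rbind, rows),
            swept = "flexor drive", coupled = coupled, D_E0 = D_E0,
            class = c("cpg_sweep", "data.frame"))
}

#' @export
plot.cpg_sweep <- function(x, ...) {
  ok <- stats::complete.cases(x[, c("period", "flexion", "extension")])
  graphics::matplot(x$drive[ok],
                    cbind(x$period, x$flexion, x$extension)[ok, ],
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "navy", "darkgreen"),
                    xlab = attr(x, "swept"), ylab = "duration (ms)", ...)
  graphics::legend("topright", c("period", "flexion", "extension"),
                   col = c("black", "navy", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}

#' Drive at which flexion and extension durations are equal
#'
#' Locates the crossover of the flexion and extension duration curves of
#' the single-RG drive sweep by linear interpolation between the two
#' grid points bracketing the sign change of their difference.
#'
#' @param sweep an existing \code{\link{single_rg_sweep}} result, or
#'   \code{NULL} to compute one.
#' @param ... passed to \code{\link{single_rg_sweep}} when
#'   \code{sweep} is \code{NULL}.
#' @param tol_degenerate if the flexion-extension difference never
#'   exceeds this value (ms) anywhere on the grid, the configuration is
#'   flagged degenerate and the first grid point is returned with a
#'   warning.
#' @return The drive value (nS) at the crossover.
#' @export
equal_phase_drive <- function(sweep = NULL, ..., tol_degenerate = 1) {
  if (is.null(sweep)) sweep <- single_rg_sweep(...)
  d <- sweep$flexion - sweep$extension
  ok <- is.finite(d)
  if (all(abs(d[ok]) < tol_degenerate)) {
    warning("flexion and extension equal everywhere (degenerate configuration)",
            call. = FALSE)
    return(sweep$drive[ok][1])
  }
  s <- sign(d)
  idx <- which(ok[-length(ok)] & ok[-1] & s[-length(s)] * s[-1] < 0)
  if (!length(idx))
    stop("no flexion-extension crossover on the sweep interval", call. = FALSE)
  i <- idx[1]
  x0 <- sweep$drive[i]; x1 <- sweep$drive[i + 1]
  y0 <- d[i]; y1 <- d[i + 1]
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

#' Two-parameter frequency map of the isolated rhythm generator
#'
#' Computes the bursting frequency of the single RG on a grid of flexor
#' drive x net extensor drive with the two drives set independently
#' (no drive coupling), and classifies the isolated flexor's intrinsic
#' activity mode along the flexor-drive axis.  The largest flexor drive
#' at which the isolated flexor still bursts intrinsically marks the
#' boundary between flexor-driven and classical half-center
#' rhythmogenesis.
#'
#' @param flexor_grid,extensor_grid drive grids (nS).
#' @param duration,transient horizon and transient (ms).
#' @return A \code{cpg_freq_map}: list with \code{frequency} (matrix,
#'   flexor drives in rows, 0 where non-oscillatory), \code{flexor_mode}
#'   (per flexor drive), and \code{rhythmic_boundary} (largest flexor
#'   drive with intrinsic bursting, \code{NA} if none).
#' @export
frequency_map <- function(flexor_grid = seq(0.1, 1.1, by = 0.1),
                          extensor_grid = seq(0.1, 1.1, by = 0.1),
                          duration = 40000, transient = 10000) {
  net <- .single_rg_net()
  freq <- matrix(0, length(flexor_grid), length(extensor_grid),
                 dimnames = list(flexor_grid, extensor_grid))
  for (i in seq_along(flexor_grid)) {
    for (j in seq_along(extensor_grid)) {
      drv <- drive_config(flexor_grid[i], flexor_grid[i], coupled = FALSE,
                          d_E_left = extensor_grid[j])
      tr <- simulate_cpg(net, drv, duration = duration)
      m <- .metrics_or_na(tr, 1, transient)
      freq[i, j] <- if (is.finite(m$frequency)) m$frequency else 0
    }
  }
  modes <- vapply(flexor_grid, function(dF)
    classify_unit_mode(net$units[[1]], dF, duration = duration,
                       transient = transient), character(1))
  rb <- if (any(modes == "bursting"))
    max(flexor_grid[modes == "bursting"]) else NA_real_
  structure(list(frequency = freq, flexor_grid = flexor_grid,
                 extensor_grid = extensor_grid, flexor_mode = modes,
                 rhythmic_boundary = rb),
            class = "cpg_freq_map")
}

#' @export
print.cpg_freq_map <- function(x, ...) {
  cat(sprintf("Frequency map: %d x %d cells, %.0f%% oscillatory\n",
              nrow(x$frequency), ncol(x$frequency),
              100 * mean(x$frequency > 0)))
  cat(sprintf("flexor intrinsically rhythmic up to drive %s\n",
              format(x$rhythmic_boundary)))
  invisible(x)
}

#' @export
plot.cpg_freq_map <- function(x, ...) {
  graphics::image(x$flexor_grid, x$extensor_grid, x$frequency,
                  xlab = "flexor drive (nS)",
                  ylab = "net extensor drive (nS)",
                  col = grDevices::hcl.colors(24, "viridis"), ...)
  if (is.finite(x$rhythmic_boundary))
    graphics::abline(v = x$rhythmic_boundary, lty = 2, col = "white")
  invisible(x)
}

# label one simulated run by its left-right flexor phase relation
.label_run <- function(tr, transient, cv_tol = 0.02) {
  bl <- detect_bursts(tr, 1, transient = transient)
  br <- detect_bursts(tr, 2, transient = transient)
  if (nrow(bl) < 3 || nrow(br) < 3) {
    f <- c(tr$f1[tr$t >= transient], tr$f2[tr$t >= transient])
    return(list(label = if (max(f) < 0.10) "quiescent" else "tonic",
                phase = NA_real_))
  }
  ml <- cycle_metrics(bl, cv_tol = cv_tol)
  if (!ml$regular)
    return(list(label = "intermittent", phase = NA_real_))
  ph <- phase_difference(bl, br)$phase
  lag <- min(ph, 1 - ph)
  label <-
    if (abs(ph - 0.5) < 0.05) "anti_phase"
    else if (lag < 0.05) "in_phase"
    else if (lag < 0.2) "small_phase_lag"
    else "asymmetric_alternation"
  list(label = label, phase = ph)
}

#' Classify the left-right coordination regime at one parameter point
#'
#' Runs the symmetric two-RG model (equal left and right drives) from
#' both the anti-phase and the in-phase seed and labels each outcome by
#' its steady left-right flexor phase difference: \code{anti_phase}
#' (phase within 0.05 of 0.5), \code{in_phase} (lag below 0.05),
#' \code{small_phase_lag} (lag in \[0.05, 0.2)),
#' \code{asymmetric_alternation} otherwise; runs failing the
#' steady-state regularity test are \code{intermittent} and
#' non-oscillatory runs \code{quiescent}/\code{tonic}.  If the two seeds
#' settle to distinct classes the point is \code{bistable}.
#'
#' @param drive common flexor drive (nS).
#' @param FF,EF commissural flexor-flexor and crossed extensor-flexor
#'   inhibition weights (nS).
#' @param D_E0 gross extensor drive (nS).
#' @param duration,transient horizon and transient (ms).
#' @return A \code{cpg_regime} list: \code{label}, and \code{seeds}, a
#'   per-seed list of labels and measured phases.
#' @export
#' @examples
#' \donttest{
#' classify_symmetric(0.3, FF = 0.4, EF = 0.3)$label  # "anti_phase"
#' }
classify_symmetric <- function(drive, FF, EF, D_E0 = 1.4,
                               duration = 40000, transient = 10000) {
  net <- network_config(FF = FF, EF = EF)
  drv <- drive_config(drive, drive, D_E0 = D_E0)
  seeds <- lapply(c(antiphase = "antiphase", inphase = "inphase"),
                  function(s) {
    tr <- simulate_cpg(net, drv, duration = duration, init = s)
    .label_run(tr, transient)
  })
  labs <- unname(vapply(seeds, `[[`, character(1), "label"))
  label <- if (labs[1] == labs[2]) labs[1] else "bistable"
  structure(list(label = label, seeds = seeds, drive = drive,
                 FF = FF, EF = EF), class = "cpg_regime")
}

#' @export
print.cpg_regime <- function(x, ...) {
  cat(sprintf("Regime at drive %g, F-F %g, E-F %g: %s\n",
              x$drive, x$FF, x$EF, x$label))
  for (s in names(x$seeds))
    cat(sprintf("  %s seed: %s (phase %s)\n", s, x$seeds[[s]]$label,
                format(x$seeds[[s]]$phase, digits = 3)))
  invisible(x)
}

#' Regime map over the commissural-inhibition plane
#'
#' Labels every cell of an F-F x E-F inhibition grid at a fixed
#' symmetric drive via \code{\link{classify_symmetric}}.
#'
#' @param drive common flexor drive (nS).
#' @param FF_grid,EF_grid inhibition weight grids (nS).
#' @param ... passed to \code{\link{classify_symmetric}}.
#' @return A \code{cpg_regime_map}: list with \code{labels} (character
#'   matrix, FF in rows), the grids, and \code{drive}.
#' @export
symmetric_regime_map <- function(drive, FF_grid = seq(0.05, 0.45, by = 0.05),
                                 EF_grid = seq(0.05, 0.45, by = 0.05), ...) {
  labels <- matrix(NA_character_, length(FF_grid), length(EF_grid),
                   dimnames = list(FF_grid, EF_grid))
  for (i in seq_along(FF_grid))
    for (j in seq_along(EF_grid))
      labels[i, j] <- classify_symmetric(drive, FF_grid[i], EF_grid[j],
                                         ...)$label
  structure(list(labels = labels, FF_grid = FF_grid, EF_grid = EF_grid,
                 drive = drive), class = "cpg_regime_map")
}

#' @export
print.cpg_regime_map <- function(x, ...) {
  cat(sprintf("Regime map at drive %g (%d x %d cells)\n", x$drive,
              nrow(x$labels), ncol(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Area and boundary readouts of a regime map
#'
#' \code{region_area} counts cells carrying a label;
#' \code{label_boundary} returns, for each E-F column, the smallest F-F
#' grid value whose cell carries the label (e.g. the lower edge of the
#' pure anti-phase region, whose position against the bistable region is
#' expected to be drive-invariant).
#'
#' @param map a \code{cpg_regime_map}.
#' @param label regime label to locate.
#' @return \code{region_area}: integer count. \code{label_boundary}:
#'   numeric vector over the E-F grid (NA where the label is absent).
#' @export
region_area <- function(map, label) sum(map$labels == label, na.rm = TRUE)

#' @rdname region_area
#' @export
label_boundary <- function(map, label) {
  vapply(seq_along(map$EF_grid), function(j) {
    i <- which(map$labels[, j] == label)
    if (length(i)) map$FF_grid[min(i)] else NA_real_
  }, numeric(1))
}

# one asymmetric-drive run at the reference commissural point,
# returning the fast:slow burst-count ratio (n; 0 = fast silent/tonic,
# -1 = intermittent, NA = slow side not resolvable)
.ratio_cell <- function(slow_drive, fast_drive, net, D_E0, duration,
                        transient, min_cycles) {
  drv <- drive_config(slow_drive, fast_drive, D_E0 = D_E0)
  tr <- simulate_cpg(net, drv, duration = duration)
  bl <- detect_bursts(tr, 1, transient = transient)
  br <- detect_bursts(tr, 2, transient = transient)
  if (nrow(bl) < min_cycles + 1) return(NA_integer_)
  cr <- coordination_ratio(bl, br, min_cycles = min_cycles)
  if (is.na(cr$n)) -1L else cr$n
}

#' Sweep the fast-side drive and record the coordination ratio
#'
#' With the slow-side flexor drive fixed, the fast-side drive is
#' increased stepwise and the fast:slow flexor burst-count ratio is
#' measured at every point, until the fast flexor stops bursting
#' (tonic saturation) or the drive reaches \code{fast_max}.
#'
#' @param slow_drive slow-side flexor drive (nS).
#' @param fast_step drive increment (nS).
#' @param fast_max upper bound of the fast drive (nS).
#' @param net network configuration (reference commissural point by
#'   default).
#' @param D_E0 gross extensor drive (nS).
#' @param duration,transient horizon and transient (ms); the long
#'   default horizon guarantees at least 10 slow cycles at the lowest
#'   drives.
#' @param min_cycles slow cycles required per measurement.
#' @return A \code{cpg_ratio_sweep} data frame (\code{fast_drive},
#'   \code{n}, \code{label}) with attribute \code{max_n}, the largest
#'   integer ratio observed.
#' @export
max_ratio_sweep <- function(slow_drive, fast_step = 0.02, fast_max = 1.3,
                            net = .ref_net(), D_E0 = 1.4,
                            duration = 80000, transient = 10000,
                            min_cycles = 10) {
  fast <- seq(slow_drive, fast_max, by = fast_step)
  rows <- list()
  for (fd in fast) {
    n <- .ratio_cell(slow_drive, fd, net, D_E0, duration, transient,
                     min_cycles)
    rows[[length(rows) + 1]] <- data.frame(
      fast_drive = fd, n = n,
      label = if (is.na(n)) "unresolved"
              else if (n == -1) "intermittent"
              else if (n == 0) "fast_silent" else sprintf("1:%d", n))
    # fast flexor no longer bursting: tonic saturation reached
    if (!is.na(n) && n == 0) break
  }
  res <- do.call(rbind, rows)
  ns <- res$n[!is.na(res$n) & res$n >= 1]
  structure(res, slow_drive = slow_drive,
            max_n = if (length(ns)) max(ns) else NA_integer_,
            class = c("cpg_ratio_sweep", "data.frame"))
}

#' Coordination-ratio map over the asymmetric drive plane
#'
#' Labels the (slow drive, fast drive) plane, fast drive running from
#' the slow value up to \code{fast_max}, by the fast:slow flexor
#' burst-count ratio (1:n regions, intermittent cells between them).
#'
#' @param slow_grid slow-side flexor drives (nS).
#' @param fast_step,fast_max fast-drive increment and upper bound (nS).
#' @param ... passed to \code{\link{max_ratio_sweep}}.
#' @return A \code{cpg_ratio_map} data frame in long format
#'   (\code{slow_drive}, \code{fast_drive}, \code{n}, \code{label}).
#' @export
asymmetric_ratio_map <- function(slow_grid = seq(0.2, 0.6, by = 0.05),
                                 fast_step = 0.05, fast_max = 1.3, ...) {
  rows <- lapply(slow_grid, function(sd) {
    sw <- max_ratio_sweep(sd, fast_step = fast_step, fast_max = fast_max,
                          ...)
    cbind(slow_drive = sd, as.data.frame(sw))
  })
  structure(do.call(rbind, rows),
            class = c("cpg_ratio_map", "data.frame"))
}

#' @export
plot.cpg_ratio_map <- function(x, ...) {
  n <- ifelse(is.na(x$n) | x$n < 1, NA, x$n)
  graphics::plot(x$slow_drive, x$fast_drive, pch = 15, cex = 1.4,
                 col = ifelse(is.na(n), "grey80",
                              grDevices::hcl.colors(max(n, na.rm = TRUE),
                                                    "viridis")[n]),
                 xlab = "slow flexor drive (nS)",
                 ylab = "fast flexor drive (nS)", ...)
  invisible(x)
}

#' Split-belt-like asymmetric drive sweep
#'
#' Keeps the slow-side flexor drive constant and increases the
#' fast-side drive, recording cycle metrics of both rhythm generators
#' and the coordination ratio at every point.  With
#' \code{coupled = FALSE} the drive-coupling rule is removed and both
#' net extensor drives are fixed (the control showing that without the
#' coupling the fast-side flexion no longer lengthens and both periods
#' fall).
#'
#' @param slow_drive fixed slow-side flexor drive (nS).
#' @param fast_grid fast-side flexor drives (nS).
#' @param coupled apply the drive-coupling rule?
#' @param fixed_E net extensor drive (nS) on both sides when uncoupled.
#' @param net network configuration (reference commissural point).
#' @param D_E0 gross extensor drive (nS).
#' @param duration,transient horizon and transient (ms).
#' @param min_cycles slow cycles required for the ratio.
#' @return A \code{cpg_split_sweep} data frame with per-point metrics
#'   for the slow and fast RG and the burst-count ratio \code{n}.
#' @export
split_belt_sweep <- function(slow_drive = 0.5,
                             fast_grid = seq(0.5, 0.8, by = 0.05),
                             coupled = TRUE, fixed_E = 0.7,
                             net = .ref_net(), D_E0 = 1.4,
                             duration = 40000, transient = 10000,
                             min_cycles = 10) {
  rows <- lapply(fast_grid, function(fd) {
    drv <- if (coupled)
      drive_config(slow_drive, fd, D_E0 = D_E0)
    else
      drive_config(slow_drive, fd, coupled = FALSE, d_E_left = fixed_E)
    tr <- simulate_cpg(net, drv, duration = duration)
    bl <- detect_bursts(tr, 1, transient = transient)
    br <- detect_bursts(tr, 2, transient = transient)
    ms <- .metrics_or_na(tr, 1, transient)
    mf <- .metrics_or_na(tr, 2, transient)
    n <- if (nrow(bl) >= min_cycles + 1) {
      cr <- coordination_ratio(bl, br, min_cycles = min_cycles)
      if (is.na(cr$n)) -1L else cr$n
    } else NA_integer_
    data.frame(fast_drive = fd,
               period_slow = ms$period, flexion_slow = ms$flexion_duration,
               extension_slow = ms$extension_duration,
               period_fast = mf$period, flexion_fast = mf$flexion_duration,
               extension_fast = mf$extension_duration, n = n)
  })
  structure(do.call(rbind, rows),
            slow_drive = slow_drive, coupled = coupled,
            class = c("cpg_split_sweep", "data.frame"))
}

#' @export
plot.cpg_split_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (side in c("slow", "fast")) {
    cols <- paste0(c("period_", "flexion_", "extension_"), side)
    graphics::matplot(x$fast_drive, as.matrix(x[, cols]), type = "l",
                      lty = 1, lwd = 2,
                      col = c("black", "navy", "darkgreen"),
                      xlab = "fast flexor drive (nS)",
                      ylab = "duration (ms)", main = paste(side, "RG"), ...)
  }
  graphics::legend("topright", c("period", "flexion", "extension"),
                   col = c("black", "navy", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}
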
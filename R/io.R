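# canonical flat parameter names, mirroring the model's symbol table
.model_keys <- c("C", "gL", "gNaP", "EL", "ENa", "Eex", "Einh",
                 "VmNaP", "kmNaP", "VhNaP", "khNaP", "tauNaP",
                 "VtauNaP", "ktauNaP", "Vmin", "Vmax",
                 "b12", "b21", "b31", "b42", "b13", "b24", "b41", "b32",
                 "DE0")

#' Default run configuration
#'
#' The model section carries the reference parameter values under their
#' conventional symbol names; the drives, solver and experiment sections
#' hold the defaults used across the package.
#'
#' @return A nested list of class \code{cpg_config}.
#' @export
default_config <- function() {
  structure(list(
    model = list(C = 20, gL = 2.8, gNaP = 5, EL = -65, ENa = 50,
                 Eex = -10, Einh = -90, VmNaP = -40, kmNaP = -6,
                 VhNaP = -50, khNaP = 10, tauNaP = 1500, VtauNaP = -100,
                 ktauNaP = 40, Vmin = -50, Vmax = 0,
                 b12 = 0.4, b21 = 0.4, b31 = 0.5, b42 = 0.5,
                 b13 = 1, b24 = 1, b41 = 0.2, b32 = 0.2, DE0 = 1.4),
    drives = list(dF_left = 0.5, dF_right = 0.5, coupled = TRUE,
                  dE_left = 0.7, dE_right = 0.7),
    solver = list(method = "lsoda", dt = 1, rtol = 1e-8, atol = 1e-8,
                  rk_dt = 0.05, duration = 40000, transient = 10000),
    experiment = list(name = "simulate"),
    seed = 0L), class = "cpg_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, merges it over the defaults
#' (an empty file yields the pure default configuration) and validates
#' it.  Flat model parameter keys may appear either at the top level or
#' inside a \code{model} section.  Unknown keys and invariant violations
#' are reported exhaustively in a single error.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{cpg_config} with attribute \code{hash}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  errs <- character()
  sections <- c("model", "drives", "solver", "experiment", "output")
  for (key in names(raw)) {
    if (key %in% .model_keys) {
      cfg$model[[key]] <- raw[[key]]
    } else if (key == "seed") {
      cfg$seed <- as.integer(raw$seed)
    } else if (key %in% sections) {
      sub <- raw[[key]]
      known <- if (key == "model") .model_keys else names(cfg[[key]])
      bad <- setdiff(names(sub), known)
      if (key %in% c("experiment", "output")) bad <- character(0)
      if (length(bad))
        errs <- c(errs, sprintf("unknown key(s) in '%s': %s", key,
                                paste(bad, collapse = ", ")))
      for (k in setdiff(names(sub), bad)) cfg[[key]][[k]] <- sub[[k]]
    } else {
      errs <- c(errs, sprintf("unknown top-level key: '%s'", key))
    }
  }
  m <- cfg$model
  if (m$tauNaP < 0) {
    warning("tauNaP given as a negative value; using its magnitude",
            call. = FALSE)
    cfg$model$tauNaP <- m$tauNaP <- abs(m$tauNaP)
  }
  # exhaustive invariant checks, naming each offending field
  if (!is.numeric(m$C) || m$C <= 0) errs <- c(errs, "C must be > 0")
  if (m$gL < 0) errs <- c(errs, "gL must be >= 0")
  if (m$gNaP < 0) errs <- c(errs, "gNaP must be >= 0")
  if (m$Vmax <= m$Vmin) errs <- c(errs, "Vmax must exceed Vmin")
  if (m$kmNaP >= 0) errs <- c(errs, "kmNaP must be < 0")
  if (m$khNaP <= 0) errs <- c(errs, "khNaP must be > 0")
  for (w in c("b12", "b21", "b31", "b42", "b13", "b24", "b41", "b32"))
    if (m[[w]] < 0) errs <- c(errs, paste(w, "must be >= 0"))
  if (m$b12 != m$b21) errs <- c(errs, "b12 must equal b21 (F-F symmetry)")
  if (m$b41 != m$b32) errs <- c(errs, "b41 must equal b32 (E-F symmetry)")
  if (m$b31 != m$b42) errs <- c(errs, "b31 must equal b42")
  if (m$b13 != m$b24) errs <- c(errs, "b13 must equal b24")
  d <- cfg$drives
  if (any(unlist(d[c("dF_left", "dF_right", "dE_left", "dE_right")]) < 0))
    errs <- c(errs, "drives must be >= 0")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Write a configuration file
#'
#' @param config a \code{cpg_config}.
#' @param path output path; the extension selects YAML or JSON.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  attr(x, "hash") <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

#' Deterministic content hash of a configuration
#'
#' 31-based polynomial rolling hash (mod 2^31) over the canonical
#' key=value serialization; embedded in run outputs so results can be
#' traced to the exact configuration.
#'
#' @param config a \code{cpg_config} (or any list).
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  flat <- unlist(unclass(config))
  txt <- paste(names(flat), vapply(flat, format, character(1),
                                   digits = 15), sep = "=", collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build model objects from a configuration
#'
#' @param config a \code{cpg_config}.
#' @return \code{config_network}: a \code{\link{network_config}};
#'   \code{config_drives}: a \code{\link{drive_config}};
#'   \code{config_units}: a \code{\link{unit_params}}.
#' @export
config_network <- function(config) {
  m <- config$model
  network_config(FF = m$b12, EF = m$b41, EF_within = m$b31,
                 FE_within = m$b13, E_ex = m$Eex, E_inh = m$Einh,
                 units = config_units(config))
}

#' @rdname config_network
#' @export
config_drives <- function(config) {
  d <- config$drives; m <- config$model
  drive_config(d$dF_left, d$dF_right, D_E0 = m$DE0,
               coupled = isTRUE(d$coupled),
               d_E_left = d$dE_left, d_E_right = d$dE_right)
}

#' @rdname config_network
#' @export
config_units <- function(config) {
  m <- config$model
  unit_params(C = m$C, g_L = m$gL, E_L = m$EL, g_NaP = m$gNaP,
              E_Na = m$ENa, V_mNaP = m$VmNaP, k_mNaP = m$kmNaP,
              V_hNaP = m$VhNaP, k_hNaP = m$khNaP,
              tau_NaP_max = m$tauNaP, V_tauNaP = m$VtauNaP,
              k_tauNaP = m$ktauNaP, V_min = m$Vmin, V_max = m$Vmax)
}

#' Export and import a trace as CSV
#'
#' Columns are \code{t_ms, V1..V4, h1..h4, f1..f4}; plain '.' decimal
#' notation, full double precision.
#'
#' @param trace a \code{cpg_trace}.
#' @param path output/input CSV path.
#' @return \code{read_trace_csv} returns a \code{cpg_trace} (without
#'   solver provenance).
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df)[1] <- "t_ms"
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df)[1] <- "t"
  structure(df, class = c("cpg_trace", "data.frame"))
}

#' Serialize sweep and map results
#'
#' Writes any of the package's tabular results (sweeps, ratio maps,
#' split-belt sweeps) to tidy CSV or JSON, with attributes preserved in
#' a JSON metadata block.
#'
#' @param x a result data frame.
#' @param path output path; extension selects the format.
#' @export
write_results <- function(x, path) {
  meta <- attributes(x)
  meta <- meta[setdiff(names(meta), c("names", "row.names", "class"))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(meta = meta, data = as.data.frame(x)),
                         path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
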
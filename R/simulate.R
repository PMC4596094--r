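#' Solver settings
#'
#' @param duration total integration time (ms of model time).
#' @param transient initial span (ms) discarded from the returned trace; the
#'   model's published protocol discards the first 6 s.
#' @param rel_tol,abs_tol lsoda tolerances.
#' @param max_step maximal internal step (ms); `NULL` leaves lsoda free.
#' @param output_dt sampling interval of the returned trace (ms).
#' @param seed reserved for future stochastic extensions; the dynamics are
#'   deterministic and the integrator never consumes random numbers.
#' @return An object of class `solver_settings`.
#' @export
#' @examples
#' solver_settings(duration = mins(2))
solver_settings <- function(duration, transient = 6000,
                            rel_tol = 1e-8, abs_tol = 1e-8,
                            max_step = NULL, output_dt = 1, seed = NULL) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(transient), length(transient) == 1L, transient >= 0,
            rel_tol > 0, abs_tol > 0, output_dt > 0)
  if (duration <= transient)
    stop("duration must exceed the transient: nothing would remain")
  structure(list(duration = duration, transient = transient,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, output_dt = output_dt, seed = seed),
            class = "solver_settings")
}

#' Convert minutes of model time to milliseconds
#' @param x minutes.
#' @return Milliseconds.
#' @export
mins <- function(x) x * 60000

.comp_cols <- c("V", "h", "s", "Cai", "CaER", "l")

new_trace <- function(t, eup, sigh, v_avg, config, settings) {
  colnames(eup) <- .comp_cols
  colnames(sigh) <- .comp_cols
  structure(list(t = t, eupnea = eup, sigh = sigh, v_avg = v_avg,
                 config = config, settings = settings),
            class = "prebotc_trace")
}

#' @export
print.prebotc_trace <- function(x, ...) {
  cat(sprintf("<prebotc_trace> %.1f-%.1f s model time, dt = %g ms, %d samples\n",
              min(x$t) / 1000, max(x$t) / 1000, x$settings$output_dt,
              length(x$t)))
  invisible(x)
}

run_lsoda <- function(y0, settings, func, parms) {
  times <- seq(0, settings$duration, by = settings$output_dt)
  hmax <- if (is.null(settings$max_step)) Inf else settings$max_step
  out <- deSolve::ode(y = y0, times = times, func = func, parms = parms,
                      dllname = "prebotc", initfunc = "prebotc_init",
                      method = "lsoda", rtol = settings$rel_tol,
                      atol = settings$abs_tol, hmax = hmax,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed (step-size collapse) near t = ",
         max(out[, 1]), " ms")
  if (any(!is.finite(out)))
    stop("non-finite state encountered near t = ",
         min(out[rowSums(!is.finite(out)) > 0, 1]), " ms")
  out
}

#' Simulate the coupled two-compartment network
#'
#' Integrates the 12-dimensional system with lsoda (adaptive, stiff-capable)
#' and returns the post-transient trajectory sampled at `output_dt`, together
#' with the population-average voltage.
#'
#' @param config a [network_config()].
#' @param settings a [solver_settings()].
#' @param y0 optional initial 12-vector (eupnea state then sigh state);
#'   defaults to [initial_state()] of each compartment.
#' @return A `prebotc_trace`: time vector `t` (ms), per-compartment state
#'   matrices `eupnea` and `sigh` (columns V, h, s, Cai, CaER, l), the
#'   weighted population-average voltage `v_avg`, and the resolved
#'   `config`/`settings` as metadata.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate(network_config(), solver_settings(duration = mins(2)))
#' range(tr$v_avg)
#' }
simulate <- function(config, settings, y0 = NULL) {
  stopifnot(inherits(config, "prebotc_config"),
            inherits(settings, "solver_settings"))
  if (is.null(y0))
    y0 <- c(initial_state(config$eupnea), initial_state(config$sigh))
  if (length(y0) != 12L) stop("y0 must have length 12")
  out <- run_lsoda(unname(y0), settings, "prebotc_deriv_network",
                   pack_parms(config))
  keep <- out[, 1] >= settings$transient
  if (!any(keep)) stop("empty trace: transient spans the whole simulation")
  eup <- out[keep, 2:7, drop = FALSE]
  sigh <- out[keep, 8:13, drop = FALSE]
  w <- config$avg_weights
  new_trace(out[keep, 1], eup, sigh,
            w[1] * eup[, 1] + w[2] * sigh[, 1], config, settings)
}

#' Simulate one compartment in isolation
#'
#' Integrates the 6-dimensional single-compartment system with zero synaptic
#' input (the uncoupled condition, g_syn = 0).
#'
#' @param params a compartment parameter set.
#' @param settings a [solver_settings()].
#' @param y0 optional initial 6-vector; defaults to [initial_state()].
#' @return A `prebotc_trace` whose `eupnea` and `sigh` slots both hold the
#'   single compartment's states and whose `v_avg` is its voltage.
#' @export
single_compartment <- function(params, settings, y0 = NULL) {
  validate_params(params)
  stopifnot(inherits(settings, "solver_settings"))
  if (is.null(y0)) y0 <- initial_state(params)
  if (length(y0) != 6L) stop("y0 must have length 6")
  parms <- c(flatten_params(params), flatten_params(params), coupling_on = 0)
  out <- run_lsoda(unname(y0), settings, "prebotc_deriv_single", parms)
  keep <- out[, 1] >= settings$transient
  if (!any(keep)) stop("empty trace: transient spans the whole simulation")
  comp <- out[keep, 2:7, drop = FALSE]
  cfg <- network_config(eupnea = params, sigh = params, coupling_on = FALSE)
  new_trace(out[keep, 1], comp, comp, comp[, 1], cfg, settings)
}

#' Convert a trace to a data frame
#'
#' Columns follow the on-disk schema: `t`, the six eupnea states, the six
#' sigh states, and `v_avg`.
#'
#' @param x a `prebotc_trace`.
#' @param ... unused.
#' @return A `data.frame` with 14 columns.
#' @export
as.data.frame.prebotc_trace <- function(x, ...) {
  df <- data.frame(t = x$t, x$eupnea, x$sigh, v_avg = x$v_avg)
  names(df) <- c("t", paste0(.comp_cols, "_eup"), paste0(.comp_cols, "_sigh"),
                 "v_avg")
  df
}

#' Write or read a trace as CSV plus a JSON sidecar
#'
#' The CSV holds the sampled states (schema of
#' [as.data.frame.prebotc_trace()]); a `<path>.json` sidecar stores the
#' resolved configuration and solver settings so the simulation can be re-run
#' bit-comparably.
#'
#' @param trace a `prebotc_trace`.
#' @param path CSV file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   `prebotc_trace` (with metadata when the sidecar is present).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "prebotc_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  strip <- function(ps) {
    ps <- unclass(ps)
    for (g in c("m_gate", "h_gate", "n_gate", "s_gate"))
      ps[[g]] <- Filter(Negate(is.null), unclass(ps[[g]]))
    ps
  }
  meta <- list(config = list(eupnea = strip(trace$config$eupnea),
                             sigh = strip(trace$config$sigh),
                             coupling_on = trace$config$coupling_on,
                             avg_weights = trace$config$avg_weights),
               settings = unclass(trace$settings))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", paste0(.comp_cols, "_eup"), paste0(.comp_cols, "_sigh"),
            "v_avg")
  if (!all(need %in% names(df)))
    stop("trace CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  sidecar <- paste0(path, ".json")
  config <- NULL
  settings <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mk <- function(ov) {
      ps <- unclass(default_parameters("eupnea"))
      for (nm in names(ov)) {
        if (nm %in% c("m_gate", "h_gate", "n_gate", "s_gate")) {
          gl <- as.list(ov[[nm]])
          ps[[nm]] <- gating_params(gl$V_half, gl$slope, gl$tau_bar)
        } else ps[[nm]] <- ov[[nm]]
      }
      `class<-`(ps, "prebotc_params")
    }
    config <- network_config(eupnea = mk(meta$config$eupnea),
                             sigh = mk(meta$config$sigh),
                             coupling_on = meta$config$coupling_on,
                             avg_weights = meta$config$avg_weights)
    s <- meta$settings
    settings <- solver_settings(duration = s$duration, transient = s$transient,
                                rel_tol = s$rel_tol, abs_tol = s$abs_tol,
                                max_step = s$max_step, output_dt = s$output_dt,
                                seed = s$seed)
  } else {
    settings <- solver_settings(duration = max(df$t),
                                transient = min(df$t),
                                output_dt = stats::median(diff(df$t)))
    # placeholder settings reconstructed from the sampling grid; transient
    # equals the first retained sample so nothing further is discarded
    settings$transient <- min(df$t)
  }
  new_trace(df$t, as.matrix(df[, 2:7]), as.matrix(df[, 8:13]), df$v_avg,
            config, settings)
}
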
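#' Full analysis of a simulated trace
#'
#' Runs the standard analysis chain on a trace: burst detection on the
#' population-average voltage (or a single compartment's voltage), amplitude
#' classification, per-burst and per-class phase counting, and rhythm
#' statistics. Because the sigh period (around a minute) dwarfs the 6 s
#' integration transient, frequency statistics optionally discard everything
#' before the second detected sigh, which makes them insensitive to the
#' initial conditions.
#'
#' @param trace a `prebotc_trace`.
#' @param signal which voltage to analyse: `"avg"` (population average),
#'   `"eupnea"`, or `"sigh"`.
#' @param single_class labelling rule for single-cluster trains passed to
#'   [classify_bursts()]; the experiment drivers use `"auto"` so that a pure
#'   ultra-slow train is recognised as the sigh rhythm.
#' @param guard_sighs if `TRUE` (default) and at least two sighs are
#'   detected, restrict the measurement window to start at the second sigh's
#'   onset.
#' @param baseline_quantile,threshold_fraction,min_gap detector settings
#'   (see [detect_bursts()]).
#' @param gap_factor amplitude-split setting (see [classify_bursts()]).
#' @param window_pre,window_post profile span around burst peaks (ms).
#' @param prominence_fraction phase-counting cutoff (see [count_phases()]).
#' @param convention apnea measurement convention (see [rhythm_summary()]).
#' @return A list of class `trace_analysis`: `bursts` (labelled, with
#'   `n_phases` filled), `summary` (a [rhythm_summary()]), `profiles`
#'   (per-class mean waveforms), and `flags` (`sigh_present`,
#'   `eupnea_present`, `sigh_n_phases`, `eupnea_n_phases`).
#' @export
summarize_trace <- function(trace,
                            signal = c("avg", "eupnea", "sigh"),
                            single_class = "auto",
                            guard_sighs = TRUE,
                            baseline_quantile = 0.2,
                            threshold_fraction = 0.15,
                            min_gap = 100,
                            gap_factor = 0.5,
                            window_pre = 2500, window_post = 2500,
                            prominence_fraction = 0.2,
                            convention = "onset") {
  stopifnot(inherits(trace, "prebotc_trace"))
  signal <- match.arg(signal)
  v <- switch(signal, avg = trace$v_avg,
              eupnea = trace$eupnea[, "V"], sigh = trace$sigh[, "V"])
  dt <- trace$settings$output_dt
  bursts <- detect_bursts(v, dt = dt, t0 = trace$t[1],
                          baseline_quantile = baseline_quantile,
                          threshold_fraction = threshold_fraction,
                          min_gap = min_gap)
  bursts <- classify_bursts(bursts, gap_factor = gap_factor,
                            single_class = single_class)

  # per-burst phase counts from the raw waveform around each peak
  if (nrow(bursts)) {
    npre <- round(window_pre / dt); npost <- round(window_post / dt)
    bursts$n_phases <- vapply(seq_len(nrow(bursts)), function(i) {
      ctr <- round((bursts$peak_time[i] - trace$t[1]) / dt) + 1L
      a <- max(1L, ctr - npre); b <- min(length(v), ctr + npost)
      count_phases(v[a:b], prominence_fraction)
    }, 0L)
  }

  t_start <- trace$t[1]
  t_end <- trace$t[length(trace$t)]
  sighs <- bursts$onset[bursts$label == "sigh"]
  if (guard_sighs && length(sighs) >= 2L) {
    # open the window at the second sigh's onset and count strictly after it:
    # counting the anchoring event itself would bias rates upward by one event
    t_start <- sort(sighs)[2L]
    bursts <- bursts[bursts$onset > t_start, , drop = FALSE]
  }
  summary <- rhythm_summary(bursts, window = t_end - t_start,
                            convention = convention)

  profiles <- burst_profile(trace, bursts, window_pre, window_post)
  flags <- list(
    sigh_present = summary$n_sigh > 0L,
    eupnea_present = summary$n_eupnea > 0L,
    sigh_n_phases = if (!is.null(profiles$sigh)) {
      count_phases(profiles$sigh$v, prominence_fraction)
    } else NA_integer_,
    eupnea_n_phases = if (!is.null(profiles$eupnea)) {
      count_phases(profiles$eupnea$v, prominence_fraction)
    } else NA_integer_)

  structure(list(bursts = bursts, summary = summary,
                 profiles = profiles, flags = flags, signal = signal),
            class = "trace_analysis")
}

# one experiment condition
condition <- function(label, edits = list(), duration = mins(20),
                      signal = "avg", ...) {
  list(label = label, edits = edits, duration = duration, signal = signal,
       extra = list(...))
}

.registry <- function() {
  vk_conditions <- lapply(c(-64, -62, -60, -58), function(vk) {
    condition(sprintf("VK=%d mV", vk), list(both.VK = vk),
              duration = if (vk == -64) mins(30) else mins(20),
              VK = vk)
  })
  list(
    baseline = list(
      description = "Coupled model with default parameters: concurrent eupnea (~14/min) and large-amplitude sighs (~0.85/min).",
      conditions = list(condition("baseline"))),
    uncoupled = list(
      description = "Both synapses off (gsyn = 0): each compartment expresses its intrinsic rhythm.",
      conditions = list(
        condition("eupnea compartment", list(coupling_on = FALSE),
                  signal = "eupnea"),
        condition("sigh compartment", list(coupling_on = FALSE),
                  signal = "sigh"))),
    inhibition_block = list(
      description = "Inhibitory synapse onto sigh removed (gsynINH = 0): sighs persist but become monophasic.",
      conditions = list(
        condition("baseline"),
        condition("gsynINH=0", list(sigh.gsyn = 0)))),
    gca_reduction = list(
      description = "Voltage-gated calcium conductance halved (gCa = 0.01 nS in both compartments): sighs abolished.",
      conditions = list(
        condition("baseline"),
        condition("gCa x0.5", list(both.gCa = scale_by(0.5))))),
    serca_reduction = list(
      description = "SERCA pump rate reduced to 10%: ER store cannot refill, sighs abolished, eupnea persists.",
      conditions = list(
        condition("baseline"),
        condition("VSERCA x0.1", list(both.VSERCA = scale_by(0.1))))),
    gnap_sweep = list(
      description = "Persistent sodium conductance at 100/80/0% of (2.5, 1.0) nS for (eupnea, sigh).",
      conditions = list(
        condition("gNaP 100%", list(eupnea.gNaP = 2.5, sigh.gNaP = 1.0),
                  level = 1),
        condition("gNaP 80%", list(eupnea.gNaP = 2.0, sigh.gNaP = 0.8),
                  level = 0.8),
        condition("gNaP 0%", list(eupnea.gNaP = 0, sigh.gNaP = 0),
                  level = 0))),
    vk_sweep = list(
      description = "Leak reversal (proxy for extracellular potassium) swept over -64..-58 mV in both compartments.",
      conditions = vk_conditions),
    low_vk_compartments = list(
      description = "Hyperpolarised regime (VK = -64 mV): per-compartment activity, both compartments phase-locked to the sigh rhythm.",
      conditions = list(
        condition("VK=-64 mV (avg)", list(both.VK = -64), mins(30)),
        condition("VK=-64 mV (eupnea)", list(both.VK = -64), mins(30),
                  signal = "eupnea"),
        condition("VK=-64 mV (sigh)", list(both.VK = -64), mins(30),
                  signal = "sigh"))),
    ih_distribution = list(
      description = "I_h restricted to the eupnea compartment, the sigh compartment, both, or neither.",
      conditions = list(
        condition("eupnea only", list(sigh.gh = 0)),
        condition("sigh only", list(eupnea.gh = 0)),
        condition("both", list()),
        condition("neither", list(both.gh = 0)))),
    ih_halfact_grid = list(
      description = "Sigh-compartment I_h half-activation (-90/-80/-70 mV) crossed with the VK sweep; sigh period sensitivity to excitability.",
      conditions = {
        grid <- expand.grid(Vn = c(-90, -80, -70), VK = c(-64, -62, -60, -58))
        lapply(seq_len(nrow(grid)), function(i) {
          condition(sprintf("Vn=%d, VK=%d", grid$Vn[i], grid$VK[i]),
                    list(sigh.n_gate.V_half = grid$Vn[i],
                         both.VK = grid$VK[i]),
                    duration = if (grid$VK[i] == -64) mins(30) else mins(20),
                    Vn = grid$Vn[i], VK = grid$VK[i])
        })
      })
  )
}

#' List the shipped in-silico experiments
#'
#' @return Data frame of experiment names and descriptions.
#' @export
list_experiments <- function() {
  reg <- .registry()
  data.frame(name = names(reg),
             n_conditions = vapply(reg, function(e) length(e$conditions), 0L),
             description = vapply(reg, function(e) e$description, ""),
             row.names = NULL)
}

#' Run a named in-silico experiment
#'
#' Simulates every condition of a registered protocol (or a user-supplied
#' spec with the same structure), analyses each trace with
#' [summarize_trace()], and assembles a sweep table. A condition whose
#' simulation fails is reported in the table (`error` column) without
#' aborting the remaining conditions.
#'
#' @param experiment registry name (see [list_experiments()]) or a list with
#'   elements `description` and `conditions` (each built like the registry's:
#'   `label`, `edits`, `duration`, `signal`).
#' @param base_config configuration the per-condition edits apply to.
#' @param duration optional override (ms) of every condition's duration,
#'   used to scale runs down.
#' @param rel_tol,abs_tol,output_dt solver settings applied to all conditions.
#' @param keep_traces if `TRUE`, the traces are returned (memory-heavy for
#'   long runs).
#' @param out_dir if non-`NULL`, one trace CSV per condition plus the sweep
#'   table (CSV) and summaries (JSON) are written there.
#' @param single_class passed to [summarize_trace()].
#' @param quiet suppress per-condition progress messages.
#' @return An object of class `sweep_result`: `table` (one row per condition
#'   with frequencies, periods, apnea and shape flags), `analyses` (the
#'   [summarize_trace()] results), and optionally `traces`.
#' @export
#' @examples
#' \donttest{
#' res <- run_experiment("baseline", duration = mins(8))
#' res$table[, c("condition", "freq_eupnea", "freq_sigh")]
#' }
run_experiment <- function(experiment, base_config = network_config(),
                           duration = NULL,
                           rel_tol = 1e-8, abs_tol = 1e-8, output_dt = 1,
                           keep_traces = FALSE, out_dir = NULL,
                           single_class = "auto", quiet = TRUE) {
  if (is.character(experiment)) {
    reg <- .registry()
    if (!experiment %in% names(reg))
      stop("unknown experiment '", experiment, "'; see list_experiments()")
    name <- experiment
    experiment <- reg[[experiment]]
  } else {
    name <- if (!is.null(experiment$name)) experiment$name else "custom"
  }
  stopifnot(is.list(experiment$conditions), length(experiment$conditions) > 0)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rows <- list(); analyses <- list(); traces <- list()
  for (cond in experiment$conditions) {
    if (!quiet) message("condition: ", cond$label)
    dur <- if (is.null(duration)) cond$duration else duration
    res <- tryCatch({
      cfg <- perturb(base_config, cond$edits)
      st <- solver_settings(duration = dur, rel_tol = rel_tol,
                            abs_tol = abs_tol, output_dt = output_dt)
      tr <- simulate(cfg, st)
      an <- summarize_trace(tr, signal = cond$signal,
                            single_class = single_class)
      list(trace = tr, analysis = an, error = NA_character_)
    }, error = function(e) list(trace = NULL, analysis = NULL,
                                error = conditionMessage(e)))
    s <- res$analysis$summary
    f <- res$analysis$flags
    row <- data.frame(
      experiment = name, condition = cond$label,
      freq_eupnea = if (is.null(s)) NA_real_ else s$freq_eupnea,
      freq_sigh = if (is.null(s)) NA_real_ else s$freq_sigh,
      n_eupnea = if (is.null(s)) NA_integer_ else s$n_eupnea,
      n_sigh = if (is.null(s)) NA_integer_ else s$n_sigh,
      period_sigh = if (is.null(s)) NA_real_ else s$period_sigh,
      period_post_sigh = if (is.null(s)) NA_real_ else s$period_post_sigh,
      period_post_eupnea = if (is.null(s)) NA_real_ else s$period_post_eupnea,
      apnea_increase = if (is.null(s)) NA_real_ else s$apnea_increase,
      sigh_present = if (is.null(f)) NA else f$sigh_present,
      eupnea_present = if (is.null(f)) NA else f$eupnea_present,
      sigh_n_phases = if (is.null(f)) NA_integer_ else f$sigh_n_phases,
      error = res$error)
    for (nm in names(cond$extra)) row[[nm]] <- cond$extra[[nm]]
    rows[[length(rows) + 1L]] <- row
    analyses[[cond$label]] <- res$analysis
    if (keep_traces) traces[[cond$label]] <- res$trace
    if (!is.null(out_dir) && !is.null(res$trace)) {
      slug <- gsub("[^A-Za-z0-9._-]+", "_", cond$label)
      write_trace(res$trace, file.path(out_dir, paste0(slug, ".csv")))
      if (!is.null(res$analysis))
        write_summary(res$analysis$summary,
                      file.path(out_dir, paste0(slug, "_summary.json")))
    }
  }
  table <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(table, file.path(out_dir, paste0(name, "_sweep.csv")),
                     row.names = FALSE)
  structure(list(experiment = name, table = table, analyses = analyses,
                 traces = if (keep_traces) traces else NULL),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$experiment, "\n")
  print(x$table[, setdiff(names(x$table), "experiment")], digits = 3)
  invisible(x)
}

#' Excitability sweep over the leak reversal potential
#'
#' Runs the coupled model at VK in \{-64, -62, -60, -58\} mV (both
#' compartments) and reports per-condition eupnea and sigh frequencies. At
#' -64 mV the eupnea compartment sits below its oscillatory threshold and the
#' network expresses only the ultra-slow sigh rhythm.
#'
#' @inheritParams run_experiment
#' @param ... passed to [run_experiment()].
#' @return A `sweep_result` with columns `VK`, `freq_eupnea`, `freq_sigh`.
#' @export
vk_sweep <- function(...) run_experiment("vk_sweep", ...)

#' Persistent-sodium conductance knockdown
#'
#' Conditions at 100%, 80% and 0% of (2.5, 1.0) nS for (eupnea, sigh).
#' Reducing gNaP slows eupnea with little effect on sigh frequency; complete
#' removal abolishes eupneic oscillations and leaves residual slow events
#' that are no longer separable in amplitude from eupneic bursts.
#'
#' @inheritParams vk_sweep
#' @return A `sweep_result`.
#' @export
gnap_sweep <- function(...) run_experiment("gnap_sweep", ...)

#' Distribution of the hyperpolarisation-activated current
#'
#' I_h restricted to the eupnea compartment only, the sigh compartment only,
#' both (control), or neither (gh = 0). Sigh activity requires I_h in the
#' sigh compartment and is biphasic only when I_h is present in both.
#'
#' @inheritParams vk_sweep
#' @return A `sweep_result`.
#' @export
ih_distribution <- function(...) run_experiment("ih_distribution", ...)

#' Grid over I_h half-activation and leak reversal
#'
#' Sigh-compartment I_h half-activation voltage (-90, -80, -70 mV; eupnea
#' fixed at -90 mV) crossed with the VK sweep. With a depolarised
#' half-activation the sigh period becomes insensitive to VK, while the
#' eupnea period is independent of the sigh compartment's I_h gate.
#'
#' @inheritParams vk_sweep
#' @return A `sweep_result` with columns `Vn`, `VK`, `period_sigh`,
#'   `period_post_eupnea`.
#' @export
ih_halfact_grid <- function(...) run_experiment("ih_halfact_grid", ...)

#' Per-compartment activity in the hyperpolarised regime
#'
#' Runs the coupled model at VK = -64 mV and measures the phase relation of
#' the two compartments' voltages by cross-correlation. In this regime the
#' eupnea compartment is below its intrinsic threshold but is recruited by
#' the excitatory synapse from sigh, so both compartments deflect in phase.
#'
#' @param duration run length (ms).
#' @param max_lag largest cross-correlation lag examined (ms).
#' @param ... passed to [solver_settings()] via defaults.
#' @return List with the trace analysis of each compartment, `lag_ms` (lag of
#'   the cross-correlation peak) and `phase_locked` (`TRUE` when the peak lag
#'   is under 1 s).
#' @export
low_vk_compartments <- function(duration = mins(30), max_lag = 5000, ...) {
  cfg <- perturb(network_config(), list(both.VK = -64))
  tr <- simulate(cfg, solver_settings(duration = duration, ...))
  # decimate to 10 ms before the cross-correlation: lags of interest are
  # hundreds of ms, and the full 1 ms grid makes ccf needlessly slow
  dt <- tr$settings$output_dt
  dec <- max(1L, round(10 / dt))
  keep <- seq(1L, length(tr$t), by = dec)
  ve <- tr$eupnea[keep, "V"]; vs <- tr$sigh[keep, "V"]
  cc <- stats::ccf(ve, vs, lag.max = round(max_lag / (dt * dec)), plot = FALSE)
  lag_ms <- cc$lag[which.max(cc$acf)] * dt * dec
  list(eupnea = summarize_trace(tr, signal = "eupnea"),
       sigh = summarize_trace(tr, signal = "sigh"),
       lag_ms = lag_ms,
       max_ccf = max(cc$acf),
       phase_locked = abs(lag_ms) < 1000)
}
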
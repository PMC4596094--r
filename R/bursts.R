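#' Detect bursts by threshold crossing
#'
#' The baseline is a low quantile of the series; the detection threshold sits
#' a fixed fraction of the way from the baseline to the series maximum.
#' Contiguous supra-threshold intervals separated by less than `min_gap` are
#' merged into one burst. A constant (or empty) series yields zero bursts.
#'
#' @param series either a numeric voltage vector or a `prebotc_trace` (whose
#'   population-average voltage is analysed).
#' @param dt sampling interval (ms); taken from the trace when one is given.
#' @param t0 time of the first sample (ms); ditto.
#' @param baseline_quantile quantile defining the baseline (default 0.2).
#' @param threshold_fraction fraction of the baseline-to-maximum span placed
#'   above the baseline (default 0.15).
#' @param min_gap sub-threshold gaps shorter than this (ms) are merged
#'   (default 100).
#' @return A `data.frame` with one row per burst: `onset`, `offset`,
#'   `peak_time` (ms), `peak_amplitude` (mV above baseline), `label`
#'   (initially `"unclassified"`), `n_phases` (initially `NA`); the baseline
#'   voltage is attached as attribute `"baseline"`.
#' @export
#' @examples
#' v <- rep(-60, 1000); v[200:230] <- -30; v[600:630] <- -30
#' detect_bursts(v)  # two bursts
detect_bursts <- function(series, dt = 1, t0 = 0,
                          baseline_quantile = 0.2,
                          threshold_fraction = 0.15,
                          min_gap = 100) {
  if (inherits(series, "prebotc_trace")) {
    dt <- series$settings$output_dt
    t0 <- series$t[1]
    series <- series$v_avg
  }
  stopifnot(is.numeric(series),
            baseline_quantile >= 0, baseline_quantile <= 1,
            threshold_fraction > 0, threshold_fraction < 1,
            min_gap >= 0)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), peak_amplitude = numeric(0),
                      label = character(0), n_phases = integer(0))
  if (length(series) == 0L) return(structure(empty, baseline = NA_real_))
  baseline <- unname(stats::quantile(series, baseline_quantile))
  vmax <- max(series)
  if (vmax <= baseline)  # constant (or degenerate) series
    return(structure(empty, baseline = baseline))
  threshold <- baseline + threshold_fraction * (vmax - baseline)
  above <- series > threshold
  if (!any(above)) return(structure(empty, baseline = baseline))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge bursts separated by sub-threshold gaps shorter than min_gap
  if (nrow(seg) > 1L) {
    gap_samples <- (seg$start[-1L] - seg$end[-nrow(seg)] - 1L) * dt
    grp <- cumsum(c(0L, as.integer(gap_samples >= min_gap)))
    seg <- data.frame(start = tapply(seg$start, grp, min),
                      end = tapply(seg$end, grp, max))
  }
  peak_idx <- mapply(function(a, b) a - 1L + which.max(series[a:b]),
                     seg$start, seg$end)
  out <- data.frame(onset = t0 + (seg$start - 1L) * dt,
                    offset = t0 + (seg$end - 1L) * dt,
                    peak_time = t0 + (peak_idx - 1L) * dt,
                    peak_amplitude = series[peak_idx] - baseline,
                    label = "unclassified",
                    n_phases = NA_integer_)
  rownames(out) <- NULL
  structure(out[order(out$onset), , drop = FALSE], baseline = baseline)
}

#' Classify bursts into sigh and eupnea by amplitude
#'
#' One-dimensional two-class split: if the largest gap between consecutive
#' sorted peak amplitudes exceeds `gap_factor` times the median amplitude,
#' bursts above the gap are sighs and the rest eupnea. Otherwise the train is
#' a single-rhythm regime: by default every burst is labelled eupnea;
#' `single_class = "auto"` instead labels the whole train sigh when its
#' median inter-onset interval exceeds `slow_period` (the ultra-slow regime
#' seen when the fast oscillator is below threshold), and `"sigh"` forces the
#' sigh label.
#'
#' @param bursts a burst table from [detect_bursts()].
#' @param gap_factor amplitude-gap threshold relative to the median amplitude
#'   (default 0.5).
#' @param single_class labelling rule for a single-cluster train:
#'   `"eupnea"` (default), `"auto"`, or `"sigh"`.
#' @param slow_period inter-onset cutoff (ms) for the `"auto"` rule
#'   (default 20000: eupneic periods are a few seconds, sigh periods about a
#'   minute).
#' @return The burst table with `label` filled in.
#' @export
classify_bursts <- function(bursts, gap_factor = 0.5,
                            single_class = c("eupnea", "auto", "sigh"),
                            slow_period = 20000) {
  single_class <- match.arg(single_class)
  if (nrow(bursts) == 0L) return(bursts)
  amps <- sort(bursts$peak_amplitude)
  two_clusters <- FALSE
  if (nrow(bursts) > 1L) {
    gaps <- diff(amps)
    k <- which.max(gaps)
    two_clusters <- gaps[k] > gap_factor * stats::median(amps)
  }
  if (two_clusters) {
    split <- (amps[k] + amps[k + 1L]) / 2
    bursts$label <- ifelse(bursts$peak_amplitude > split, "sigh", "eupnea")
  } else {
    lab <- switch(single_class,
      eupnea = "eupnea",
      sigh = "sigh",
      auto = {
        med_ioi <- if (nrow(bursts) > 1L) {
          stats::median(diff(sort(bursts$onset)))
        } else Inf
        if (med_ioi > slow_period) "sigh" else "eupnea"
      })
    bursts$label <- lab
  }
  bursts
}

#' Per-class rhythm statistics
#'
#' Frequencies are event counts divided by the observation window, in
#' bursts/min. The post-sigh apnea is the eupneic interval immediately
#' following each sigh; by the default onset-to-onset convention it runs from
#' the sigh onset to the next eupneic onset (`"offset"` measures from the
#' sigh offset instead). The ordinary eupneic period is the mean onset
#' interval between consecutive bursts that are both eupneic. The apnea
#' increase is `100 * (period_post_sigh / period_post_eupnea - 1)`.
#'
#' @param bursts a labelled burst table (see [classify_bursts()]).
#' @param window observation window (ms).
#' @param convention `"onset"` (default) or `"offset"` apnea measurement.
#' @return An object of class `rhythm_summary`: `freq_eupnea`, `freq_sigh`
#'   (bursts/min), `period_sigh` (mean sigh-to-sigh onset interval, s),
#'   `period_post_sigh`, `period_post_eupnea` (s), `apnea_increase`
#'   (percent), `sigh_biphasic_fraction`, and the counts. Sigh-dependent
#'   fields are `NA` when the train has no sighs.
#' @export
rhythm_summary <- function(bursts, window, convention = c("onset", "offset")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(window), length(window) == 1L, window > 0)
  bursts <- bursts[order(bursts$onset), , drop = FALSE]
  is_sigh <- bursts$label == "sigh"
  is_eup <- bursts$label == "eupnea"
  n_sigh <- sum(is_sigh)
  n_eup <- sum(is_eup)
  per_min <- function(n) n * 60000 / window

  post_sigh <- NA_real_
  if (n_sigh > 0L && n_eup > 0L) {
    iv <- vapply(which(is_sigh), function(i) {
      nxt <- which(is_eup & bursts$onset > bursts$onset[i])
      if (!length(nxt)) return(NA_real_)
      from <- if (convention == "onset") bursts$onset[i] else bursts$offset[i]
      bursts$onset[nxt[1L]] - from
    }, 0)
    post_sigh <- mean(iv, na.rm = TRUE) / 1000
  }

  post_eup <- NA_real_
  if (n_eup > 1L) {
    both_eup <- is_eup[-length(is_eup)] & is_eup[-1L]
    if (any(both_eup))
      post_eup <- mean(diff(bursts$onset)[both_eup]) / 1000
  }

  apnea <- if (is.finite(post_sigh) && is.finite(post_eup)) {
    100 * (post_sigh / post_eup - 1)
  } else NA_real_

  biphasic <- if (n_sigh > 0L && !all(is.na(bursts$n_phases[is_sigh]))) {
    mean(bursts$n_phases[is_sigh] >= 2L, na.rm = TRUE)
  } else NA_real_

  period_sigh <- if (n_sigh > 1L) {
    mean(diff(bursts$onset[is_sigh])) / 1000
  } else NA_real_

  structure(list(freq_eupnea = per_min(n_eup),
                 freq_sigh = if (n_sigh > 0L) per_min(n_sigh) else NA_real_,
                 n_eupnea = n_eup, n_sigh = n_sigh,
                 period_sigh = period_sigh,
                 period_post_sigh = post_sigh,
                 period_post_eupnea = post_eup,
                 apnea_increase = apnea,
                 sigh_biphasic_fraction = biphasic,
                 window = window),
            class = "rhythm_summary")
}

#' @export
print.rhythm_summary <- function(x, ...) {
  cat(sprintf("<rhythm_summary> window %.1f min\n", x$window / 60000))
  cat(sprintf("  eupnea: %d bursts, %.2f /min\n", x$n_eupnea, x$freq_eupnea))
  cat(sprintf("  sigh:   %d bursts, %s /min\n", x$n_sigh,
              if (is.na(x$freq_sigh)) "-" else sprintf("%.3f", x$freq_sigh)))
  if (!is.na(x$period_post_sigh))
    cat(sprintf("  post-sigh period %.2f s vs ordinary %.2f s (+%.1f%%)\n",
                x$period_post_sigh, x$period_post_eupnea, x$apnea_increase))
  invisible(x)
}

#' Peak-aligned average burst waveform per class
#'
#' @param trace a `prebotc_trace`.
#' @param bursts labelled burst table for that trace.
#' @param window_pre,window_post span (ms) before and after the burst peak.
#' @param classes classes to average (those present are returned).
#' @return Named list per class with `t` (ms relative to the peak), `v`
#'   (mean voltage), and `n` (bursts averaged). Classes without bursts are
#'   absent from the result.
#' @export
burst_profile <- function(trace, bursts, window_pre = 2500,
                          window_post = 2500,
                          classes = c("eupnea", "sigh")) {
  stopifnot(inherits(trace, "prebotc_trace"))
  dt <- trace$settings$output_dt
  npre <- round(window_pre / dt)
  npost <- round(window_post / dt)
  out <- list()
  for (cl in classes) {
    pk <- bursts$peak_time[bursts$label == cl]
    idx <- round((pk - trace$t[1]) / dt) + 1L
    idx <- idx[idx - npre >= 1L & idx + npost <= length(trace$v_avg)]
    if (!length(idx)) next
    mat <- vapply(idx, function(i) trace$v_avg[(i - npre):(i + npost)],
                  numeric(npre + npost + 1L))
    out[[cl]] <- list(t = seq(-npre, npost) * dt, v = rowMeans(mat),
                      n = length(idx))
  }
  out
}

#' Count prominent phases of a burst waveform
#'
#' A waveform is monophasic (1) or biphasic (2) according to the number of
#' local maxima whose topographic prominence exceeds `prominence_fraction` of
#' the waveform's global amplitude. A flat waveform has zero phases.
#'
#' @param waveform numeric voltage vector (one averaged burst).
#' @param prominence_fraction prominence cutoff relative to the global
#'   amplitude (default 0.2).
#' @return Integer number of prominent peaks.
#' @export
#' @examples
#' t <- seq(-3, 3, by = 0.01)
#' count_phases(exp(-t^2))                          # 1
#' count_phases(exp(-(t + 1.5)^2) + exp(-(t - 1.5)^2))  # 2
count_phases <- function(waveform, prominence_fraction = 0.2) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)),
            prominence_fraction > 0, prominence_fraction < 1)
  n <- length(waveform)
  amp <- max(waveform) - min(waveform)
  if (n < 3L || amp == 0) return(0L)
  d <- diff(waveform)
  # strict local maxima, robust to flat tops: last rise before a fall
  rising <- which(d > 0)
  peaks <- integer(0)
  for (i in rising) {
    j <- i + 1L
    while (j <= n - 1L && d[j] == 0) j <- j + 1L
    if (j <= n - 1L && d[j] < 0) peaks <- c(peaks, i + 1L)
  }
  peaks <- unique(peaks)
  if (!length(peaks)) return(0L)
  prominence <- vapply(peaks, function(p) {
    left <- waveform[seq_len(p - 1L)]
    higher_l <- which(left > waveform[p])
    lmin <- if (length(higher_l)) {
      min(waveform[(max(higher_l) + 1L):(p - 1L)])
    } else min(left)
    right <- waveform[(p + 1L):n]
    higher_r <- which(right > waveform[p])
    rmin <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r) - 1L)])
    } else min(right)
    waveform[p] - max(lmin, rmin)
  }, 0)
  sum(prominence > prominence_fraction * amp)
}

#' Synthetic bursty voltage trace with known ground truth
#'
#' Generates a deterministic (given `seed`) test trace whose true burst train
#' is exactly the supplied events: Gaussian bumps of the given amplitudes and
#' widths on a flat baseline, optionally biphasic (a leading bump of 40% of
#' the amplitude, one width ahead of the main peak), plus white noise.
#'
#' @param event_times sorted event (peak) times, ms.
#' @param amplitudes positive peak heights (mV above baseline), recycled.
#' @param widths Gaussian sigma per event (ms), recycled (default 150).
#' @param n_phases 1 (monophasic) or 2 (biphasic) per event, recycled.
#' @param noise_sd white-noise standard deviation (mV).
#' @param seed integer seed used for the noise (local RNG state).
#' @param dt sampling interval (ms).
#' @param duration total length (ms); defaults to the last event plus margin.
#' @param baseline resting level (mV).
#' @return Numeric voltage vector with attributes `dt` and `baseline`.
#' @export
make_fixture <- function(event_times, amplitudes, widths = 150,
                         n_phases = 1L, noise_sd = 0, seed = 1L,
                         dt = 1, duration = NULL, baseline = -60) {
  stopifnot(!is.unsorted(event_times), all(amplitudes > 0), all(widths > 0),
            noise_sd >= 0)
  n <- length(event_times)
  amplitudes <- rep_len(amplitudes, n)
  widths <- rep_len(widths, n)
  n_phases <- rep_len(as.integer(n_phases), n)
  if (n > 1L && any(diff(event_times) < 3 * (widths[-n] + widths[-1L])))
    stop("events overlap: peaks must be at least 3 widths apart")
  if (is.null(duration)) duration <- max(event_times) + 6 * max(widths)
  t <- seq(0, duration, by = dt)
  v <- rep(baseline, length(t))
  for (i in seq_len(n)) {
    v <- v + amplitudes[i] * exp(-(t - event_times[i])^2 / (2 * widths[i]^2))
    if (n_phases[i] >= 2L)
      v <- v + 0.4 * amplitudes[i] *
        exp(-(t - event_times[i] + 3 * widths[i])^2 / (2 * (widths[i] / 2)^2))
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  structure(v, dt = dt, baseline = baseline)
}

#' Write a burst table or rhythm summary to disk
#'
#' @param bursts labelled burst table.
#' @param path output file (CSV for bursts, JSON for summaries).
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path) {
  out <- data.frame(onset_ms = bursts$onset, offset_ms = bursts$offset,
                    peak_ms = bursts$peak_time,
                    amplitude_mV = bursts$peak_amplitude,
                    label = bursts$label, n_phases = bursts$n_phases)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @param summary a `rhythm_summary`.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "rhythm_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
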
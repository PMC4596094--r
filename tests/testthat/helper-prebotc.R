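# shared fixtures; long simulations are cached so several test files can
# reuse the same baseline run within one session

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

baseline_trace <- function() {
  cached("baseline20", simulate(network_config(),
                                solver_settings(duration = mins(20))))
}

baseline_analysis <- function() {
  cached("baseline20_an", summarize_trace(baseline_trace()))
}

# random 12-dim network state inside physiological ranges
random_network_state <- function() {
  one <- function() c(runif(1, -60, -20), runif(1, 0.1, 0.9), runif(1, 0, 0.6),
                      runif(1, 0.02, 0.8), runif(1, 1, 5), runif(1, 0.2, 0.9))
  c(one(), one())
}

# reduced I_h half-activation grid (two gates x two excitability levels,
# shorter runs) exercising the same driver as the full registry protocol
grid_subset_spec <- function(duration = mins(12)) {
  grid <- expand.grid(Vn = c(-90, -70), VK = c(-60, -58))
  list(name = "ih_grid_subset",
       conditions = lapply(seq_len(nrow(grid)), function(i) {
         list(label = sprintf("Vn=%d, VK=%d", grid$Vn[i], grid$VK[i]),
              edits = list(sigh.n_gate.V_half = grid$Vn[i],
                           both.VK = grid$VK[i]),
              duration = duration, signal = "avg",
              extra = list(Vn = grid$Vn[i], VK = grid$VK[i]))
       }))
}

# rectangular-pulse series for detector unit tests
rect_series <- function(pulses, width = 50, amp = 30, n = 5000, base = -60) {
  v <- rep(base, n)
  for (p in pulses) v[p:(p + width - 1L)] <- base + amp
  v
}
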
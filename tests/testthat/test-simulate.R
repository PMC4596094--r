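test_that("simulation is deterministic and respects state invariants", {
  st <- solver_settings(duration = 90000)
  a <- simulate(network_config(), st)
  b <- simulate(network_config(), st)
  expect_identical(a$t, b$t)
  expect_identical(a$eupnea, b$eupnea)
  expect_identical(a$sigh, b$sigh)

  for (m in list(a$eupnea, a$sigh)) {
    expect_true(all(is.finite(m)))
    for (col in c("h", "s", "l")) {
      expect_true(all(m[, col] >= 0 & m[, col] <= 1))
    }
    expect_true(all(m[, c("Cai", "CaER")] >= 0))
  }
  # transient removed, uniform sampling
  expect_gte(min(a$t), st$transient)
  expect_equal(unique(diff(a$t)), st$output_dt)
})

test_that("degenerate solver settings are rejected", {
  expect_error(solver_settings(duration = 6000, transient = 6000), "transient")
  expect_error(solver_settings(duration = 0), "duration")
  expect_error(simulate(network_config(),
                        solver_settings(duration = 1000, transient = 0),
                        y0 = rep(0, 5)), "length 12")
})

test_that("uncoupled network reproduces independent single-compartment runs", {
  st <- solver_settings(duration = 60000, transient = 0,
                        rel_tol = 1e-12, abs_tol = 1e-14)
  un <- simulate(network_config(coupling_on = FALSE), st)
  se <- single_compartment(default_parameters("eupnea"), st)
  ss <- single_compartment(default_parameters("sigh"), st)
  expect_lt(max(abs(un$eupnea[, "V"] - se$eupnea[, "V"])), 1e-6)
  expect_lt(max(abs(un$sigh[, "V"] - ss$sigh[, "V"])), 1e-6)
})

test_that("two-pool calcium is conserved when membrane fluxes are disabled", {
  cfg <- perturb(network_config(), list(both.alpha = 0, both.VPMCA = 0))
  st <- solver_settings(duration = 66000, transient = 0,
                        rel_tol = 1e-10, abs_tol = 1e-12)
  tr <- simulate(cfg, st)
  for (comp in c("eupnea", "sigh")) {
    tot <- tr[[comp]][, "Cai"] + cfg[[comp]]$sigma * tr[[comp]][, "CaER"]
    expect_lt(max(abs(tot - tot[1])), 1e-6)
  }
})

test_that("analytic derivatives match finite differences along trajectories", {
  cfg <- network_config()
  set.seed(42)
  d <- 0.01
  st <- solver_settings(duration = 2 * d, transient = 0, rel_tol = 1e-12,
                        abs_tol = 1e-14, output_dt = d)
  num <- ana <- matrix(NA_real_, 100, 12)
  for (i in 1:100) {
    tr <- simulate(cfg, st, y0 = random_network_state())
    y <- cbind(tr$eupnea, tr$sigh)
    num[i, ] <- (y[3, ] - y[1, ]) / (2 * d)
    ana[i, ] <- network_rhs(0, y[2, ], cfg)
  }
  # relative tolerance 1e-4 with a per-component scale so that components
  # passing through zero do not blow up the ratio
  scale <- apply(abs(ana), 2, max)
  for (j in 1:12) {
    expect_lt(max(abs(num[, j] - ana[, j])), 1e-4 * (max(abs(ana[, j])) + scale[j]))
  }
})

test_that("single compartments express their intrinsic rhythms", {
  st <- solver_settings(duration = mins(8))
  sg <- summarize_trace(single_compartment(default_parameters("sigh"), st),
                        signal = "sigh")
  # slow calcium-driven oscillation with a cycle period around 1.2 min
  expect_gt(sg$summary$n_sigh, 2)
  expect_gt(sg$summary$period_sigh, 50)
  expect_lt(sg$summary$period_sigh, 90)

  eu <- summarize_trace(single_compartment(default_parameters("eupnea"), st),
                        signal = "eupnea")
  # fast NaP-driven oscillation, an order of magnitude faster
  expect_gt(eu$summary$freq_eupnea, 8)
  exp_amp <- max(eu$bursts$peak_amplitude)
  sg_amp <- max(sg$bursts$peak_amplitude)
  expect_lt(exp_amp, sg_amp)

  # removing the persistent sodium current silences the eupnea compartment
  p0 <- default_parameters("eupnea")
  p0$gNaP <- 0
  quiet <- single_compartment(p0, st)
  v <- quiet$eupnea[, "V"]
  late <- v[quiet$t > mins(4)]
  expect_lt(max(late) - min(late), 1)   # converged to a fixed point
  # nothing resembling a burst: any supra-threshold blip on the settling
  # trace is far below a real oscillation's amplitude
  b0 <- detect_bursts(quiet)
  if (nrow(b0)) expect_lt(max(b0$peak_amplitude), 2)
})

test_that("traces round-trip through CSV with their metadata sidecar", {
  tr <- simulate(perturb(network_config(), list(sigh.gNaP = 0.9)),
                 solver_settings(duration = 20000, output_dt = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trace(path)
  expect_equal(back$t, tr$t)
  expect_equal(back$v_avg, tr$v_avg, tolerance = 1e-12)
  expect_equal(back$config$sigh$gNaP, 0.9)
  expect_equal(back$settings$output_dt, 5)

  # metadata is sufficient to re-run the simulation bit-comparably
  again <- simulate(back$config, back$settings)
  expect_equal(again$eupnea, tr$eupnea, tolerance = 1e-12)
})

test_that("halving solver tolerances leaves burst frequencies unchanged", {
  tr1 <- cached("tol_a", simulate(network_config(),
                                  solver_settings(duration = mins(10))))
  tr2 <- cached("tol_b", simulate(network_config(),
                                  solver_settings(duration = mins(10),
                                                  rel_tol = 5e-9,
                                                  abs_tol = 5e-9)))
  s1 <- summarize_trace(tr1)$summary
  s2 <- summarize_trace(tr2)$summary
  expect_lt(abs(s1$freq_eupnea - s2$freq_eupnea) / s1$freq_eupnea, 0.01)
  expect_lt(abs(s1$freq_sigh - s2$freq_sigh) / s1$freq_sigh, 0.01)
})

test_that("post-transient statistics are insensitive to initial conditions", {
  st <- solver_settings(duration = mins(12))
  y_alt <- c(-55, 0.3, 0.1, 0.1, 3.5, 0.5, -65, 0.6, 0, 0.03, 2.0, 0.8)
  s1 <- summarize_trace(simulate(network_config(), st))$summary
  s2 <- summarize_trace(simulate(network_config(), st, y0 = y_alt))$summary
  expect_lt(abs(s1$freq_eupnea - s2$freq_eupnea) / s1$freq_eupnea, 0.05)
  expect_lt(abs(s1$freq_sigh - s2$freq_sigh) / s1$freq_sigh, 0.05)
})
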
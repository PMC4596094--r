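test_that("threshold detector finds rectangular pulses exactly", {
  v <- rect_series(c(500, 2000, 4000))
  b <- detect_bursts(v)
  expect_equal(nrow(b), 3)
  expect_equal(b$onset, c(499, 1999, 3999))   # t0 = 0, dt = 1
  expect_true(all(b$peak_amplitude > 0))
  expect_true(all(b$onset < b$offset))

  # constant and empty series give zero bursts, not an error
  expect_equal(nrow(detect_bursts(rep(-60, 1000))), 0)
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
})

test_that("sub-threshold gaps shorter than min_gap are merged", {
  # two 50-sample pulses separated by a 60 ms gap
  v <- rect_series(c(1000, 1110))
  expect_equal(nrow(detect_bursts(v, min_gap = 100)), 1)
  expect_equal(nrow(detect_bursts(v, min_gap = 10)), 2)

  # merged burst spans both pulses
  b <- detect_bursts(v, min_gap = 100)
  expect_equal(b$onset, 999)
  expect_equal(b$offset, 1158)
})

test_that("detection is offset-invariant and shift-equivariant", {
  v <- rect_series(c(700, 2500, 4200), amp = 20)
  b0 <- detect_bursts(v)

  b_up <- detect_bursts(v + 17.3)
  expect_equal(b_up$onset, b0$onset)
  expect_equal(b_up$peak_amplitude, b0$peak_amplitude)

  shift <- 250
  b_sh <- detect_bursts(c(rep(v[1], shift), v[1:(length(v) - shift)]))
  expect_equal(b_sh$onset, b0$onset + shift)
})

test_that("amplitude split classifies sighs above the largest gap", {
  mk <- function(amps) data.frame(onset = seq_along(amps) * 4000,
                                  offset = seq_along(amps) * 4000 + 500,
                                  peak_time = seq_along(amps) * 4000 + 100,
                                  peak_amplitude = amps,
                                  label = "unclassified",
                                  n_phases = NA_integer_)
  b <- classify_bursts(mk(c(1, 1, 1, 5)))
  expect_equal(b$label, c("eupnea", "eupnea", "eupnea", "sigh"))

  # single cluster: all eupnea by default
  b2 <- classify_bursts(mk(c(1, 1.05, 0.95, 1.02)))
  expect_true(all(b2$label == "eupnea"))

  # labels are a deterministic function of the amplitude multiset
  b3 <- classify_bursts(mk(c(5, 1, 1, 1)))
  expect_equal(sort(b3$label), sort(b$label))

  # no burst below the split is ever called a sigh
  amps <- c(rep(1, 10), rep(4, 2))
  b4 <- classify_bursts(mk(amps))
  split_amp <- min(b4$peak_amplitude[b4$label == "sigh"])
  expect_true(all(b4$peak_amplitude[b4$label == "eupnea"] < split_amp))

  # auto rule: a slow single-cluster train is the sigh rhythm
  slow <- mk(c(3, 3, 3, 3))
  slow$onset <- c(0, 70, 140, 210) * 1000
  expect_true(all(classify_bursts(slow, single_class = "auto")$label == "sigh"))
  fast <- mk(c(3, 3, 3, 3))   # 4 s apart: eupneic
  expect_true(all(classify_bursts(fast, single_class = "auto")$label == "eupnea"))
})

test_that("rhythm summary computes count rates and post-sigh intervals", {
  # synthetic train: 4 events of one class in 2 minutes -> 2 bursts/min
  b <- data.frame(onset = c(10, 40, 70, 100) * 1000,
                  offset = c(11, 41, 71, 101) * 1000,
                  peak_time = c(10.5, 40.5, 70.5, 100.5) * 1000,
                  peak_amplitude = 10, label = "eupnea",
                  n_phases = 1L)
  s <- rhythm_summary(b, window = mins(2))
  expect_equal(s$freq_eupnea, 2)

  # frequencies scale exactly inversely with the window
  s2 <- rhythm_summary(b, window = mins(4))
  expect_equal(s2$freq_eupnea, 1)

  # a sigh at 50 s: post-sigh interval runs to the next eupneic onset;
  # ordinary eupneic intervals exclude the pair spanning the sigh
  b2 <- rbind(b, data.frame(onset = 50000, offset = 52000, peak_time = 51000,
                            peak_amplitude = 30, label = "sigh",
                            n_phases = 2L))
  s3 <- rhythm_summary(b2, window = mins(2))
  expect_equal(s3$period_post_sigh, 20)          # 50 s -> 70 s
  expect_equal(s3$period_post_eupnea, 30)        # 10-40 and 70-100
  expect_equal(s3$apnea_increase, 100 * (20 / 30 - 1))
  expect_equal(s3$sigh_biphasic_fraction, 1)

  # offset-to-onset convention measures from the sigh's end
  s4 <- rhythm_summary(b2, window = mins(2), convention = "offset")
  expect_equal(s4$period_post_sigh, 18)

  # no sighs: sigh fields are absent, not zero-divided
  s5 <- rhythm_summary(b, window = mins(2))
  expect_true(is.na(s5$freq_sigh))
  expect_true(is.na(s5$apnea_increase))
})

test_that("phase counting obeys the prominence rule", {
  t <- seq(-3000, 3000)
  one <- exp(-(t / 300)^2)
  expect_equal(count_phases(one), 1L)

  two <- exp(-((t + 1200) / 250)^2) + 0.8 * exp(-((t - 1200) / 250)^2)
  expect_equal(count_phases(two), 2L)

  # second bump at 5% relative prominence does not count as a phase
  shallow <- exp(-(t / 400)^2) + 0.05 * exp(-((t - 1500) / 150)^2)
  expect_equal(count_phases(shallow), 1L)

  expect_equal(count_phases(rep(0, 100)), 0L)
})

test_that("synthetic fixtures reproduce their ground truth exactly", {
  ev <- c(2000, 6000, 10000, 14000, 18000)
  v <- make_fixture(ev, amplitudes = 10, widths = 120, noise_sd = 0)
  b <- detect_bursts(v)
  expect_equal(nrow(b), 5)
  expect_true(all(abs(b$peak_time - ev) <= 1))

  # classification recovers the 4 large-amplitude events as one class
  # (the small event sits above the detection threshold at 20% of the max)
  amps <- c(2, 9, 9, 9, 9)
  v2 <- make_fixture(ev, amplitudes = amps, widths = 120)
  b2 <- classify_bursts(detect_bursts(v2))
  expect_equal(sum(b2$label == "sigh"), 4)

  # average profile of identical bursts equals the single-burst shape
  tr <- structure(list(t = seq_along(v) - 1,
                       eupnea = matrix(0, length(v), 6,
                                       dimnames = list(NULL, c("V","h","s","Cai","CaER","l"))),
                       sigh = matrix(0, length(v), 6,
                                     dimnames = list(NULL, c("V","h","s","Cai","CaER","l"))),
                       v_avg = as.numeric(v),
                       config = NULL,
                       settings = solver_settings(duration = length(v),
                                                  transient = 0)),
                  class = "prebotc_trace")
  b$label <- "eupnea"
  pr <- burst_profile(tr, b, window_pre = 1000, window_post = 1000)
  single <- 10 * exp(-(seq(-1000, 1000))^2 / (2 * 120^2)) - 60
  expect_equal(pr$eupnea$v, single, tolerance = 1e-6)

  expect_error(make_fixture(c(1000, 1100), 10, widths = 200), "overlap")
})

test_that("detection recall is at least 0.99 under 5% noise", {
  ev <- seq(3000, 60000, by = 3000)
  hits <- 0L; total <- 0L
  for (seed in 1:100) {
    v <- make_fixture(ev, amplitudes = 10, widths = 120, noise_sd = 0.5,
                      seed = seed)
    b <- detect_bursts(v)
    total <- total + length(ev)
    hits <- hits + sum(vapply(ev, function(e)
      any(abs(b$peak_time - e) < 500), TRUE))
  }
  expect_gte(hits / total, 0.99)
})

test_that("fixture noise is reproducible and leaves the RNG state alone", {
  v1 <- make_fixture(c(2000), 10, noise_sd = 0.3, seed = 5)
  v2 <- make_fixture(c(2000), 10, noise_sd = 0.3, seed = 5)
  expect_identical(v1, v2)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_fixture(c(2000), 10, noise_sd = 0.3, seed = 5))
  expect_identical(runif(1), before)
})
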
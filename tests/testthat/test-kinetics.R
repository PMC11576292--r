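test_that("percent change normalizes to the baseline window", {
  tt <- seq(-300, 1800, by = 1)
  const <- fluorescence_trace(tt, rep(42, length(tt)))
  pc <- percent_change(const)
  expect_true(all(pc$pct == 0))
  expect_equal(pc$baseline_mean, 42)
  # doubling over baseline reads 100 %
  dbl <- fluorescence_trace(tt, ifelse(tt < 0, 100, 200))
  expect_equal(percent_change(dbl)$pct[tt == 500], 100)
  # invariance to multiplicative rescaling of the raw trace
  tr <- simulate_trace(make_default_parameters("lps", "microglia"),
                       "soma", seed = 2)
  tr2 <- fluorescence_trace(tr$time, tr$intensity * 3.7)
  expect_equal(percent_change(tr)$pct, percent_change(tr2)$pct,
               tolerance = 1e-9)
  # baseline-window mean of pct is zero on noise-free input
  pc3 <- canonical_pct()
  expect_lt(abs(mean(pc3$pct[pc3$time >= -300 & pc3$time < 0])), 1e-9)
  expect_error(percent_change(const, c(5000, 6000)), "fewer than 3")
  neg <- fluorescence_trace(tt, rep(0, length(tt)))
  expect_error(percent_change(neg), "positive")
})

test_that("canonical whole-cell percent change reaches 253.12 % at 30 min", {
  pc <- canonical_pct()
  expect_equal(pc$pct[pc$time == 1800], 253.12, tolerance = 1e-9)
})

test_that("rate of change differentiates exactly on lines and plateaus", {
  pc <- ramp_pct_trace(0, 60, 60, dt = 1, t_min = -300, t_max = 700)
  rt <- rate_of_change(pc)
  interior <- rt$time > 20 & rt$time < 40
  expect_equal(rt$rate[interior], rep(1, sum(interior)), tolerance = 1e-9)
  flat <- rt$time > 200 & rt$time < 600
  expect_equal(max(abs(rt$rate[flat])), 0, tolerance = 1e-12)
  # canonical S1 interior rate equals amplitude / duration of the defaults
  p <- make_default_parameters("lps", "microglia")
  rt2 <- rate_of_change(canonical_pct())
  inS1 <- rt2$time > 363.6 + 20 & rt2$time < 363.6 + 100
  expect_equal(mean(rt2$rate[inS1]),
               unname(p$state_amplitudes[1, "whole_cell"]) /
                 p$state_durations[1],
               tolerance = 1e-6)
  short <- percent_change(fluorescence_trace(seq(-10, 9), rep(100, 20)),
                          c(-10, 0))
  expect_error(rate_of_change(short, smooth_window = 30), "shorter")
})

test_that("slope angle is the arctangent of the %-per-minute slope", {
  tt <- seq(-300, 1800)
  one_per_min <- fluorescence_trace(tt, 100 * (1 + pmax(tt, 0) / 60 / 100))
  pc <- percent_change(one_per_min)
  expect_equal(slope_angle(pc, c(60, 600)), 45, tolerance = 1e-6)
  flat <- percent_change(fluorescence_trace(tt, rep(100, length(tt))))
  expect_equal(slope_angle(flat, c(0, 600)), 0)
  expect_error(slope_angle(pc, c(100, 100)), "fewer than 2|zero time")
  # canonical S1 steeper than S3
  pc2 <- canonical_pct()
  a1 <- slope_angle(pc2, c(363.6, 363.6 + 121.2))
  a3 <- slope_angle(pc2, c(1410, 1410 + 180))
  expect_gt(a1, a3)
})

test_that("state detection recovers constructed ramps", {
  # flat trace: no states
  flat <- percent_change(
    fluorescence_trace(seq(-300, 1800), rep(100, 2101)))
  expect_equal(nrow(detect_states(flat)$states), 0)
  # single ramp, no smoothing: onset and duration within one sample
  pc1 <- ramp_pct_trace(200, 100, 100, dt = 1)
  st1 <- detect_states(pc1, smooth_window = 1)$states
  expect_equal(nrow(st1), 1)
  expect_lt(abs(st1$onset - 200), 1 + 1e-9)
  expect_lt(abs(st1$duration - 100), 1 + 1e-9)
  # brute-force grid of noise-free piecewise-linear constructions:
  # detected onsets and durations match construction within one smoothing
  # window (30 s)
  for (o1 in c(120, 300)) for (d1 in c(90, 150)) for (gap in c(200, 400)) {
    on <- c(o1, o1 + d1 + gap)
    du <- c(d1, 120)
    pc <- ramp_pct_trace(on, du, amplitudes = du * 0.8)
    st <- detect_states(pc)$states
    expect_equal(nrow(st), 2)
    expect_true(all(abs(st$onset - on) <= 30))
    expect_true(all(abs(st$duration - du) <= 30))
  }
})

test_that("sub-threshold rises and short runs are not states", {
  # 0.1 %/s is below the 0.25 %/s default threshold
  pc <- ramp_pct_trace(300, 300, 30)
  expect_equal(nrow(detect_states(pc)$states), 0)
  # a steep but 20 s long run fails the minimum state duration
  pc2 <- ramp_pct_trace(300, 20, 40)
  expect_equal(nrow(detect_states(pc2)$states), 0)
})

test_that("state cap keeps the largest responses in chronological order", {
  on <- c(100, 400, 800, 1300)
  du <- c(100, 100, 100, 100)
  amp <- c(60, 150, 40, 90)
  pc <- ramp_pct_trace(on, du, amp)
  st <- detect_states(pc, max_states = 3)$states
  expect_equal(nrow(st), 3)
  # the weakest response (40 %) is dropped, order stays chronological
  expect_true(all(abs(st$onset - on[c(1, 2, 4)]) <= 30))
  expect_true(all(diff(st$onset) > 0))
})

test_that("per-state percent change sums below the total response", {
  pc <- canonical_pct()
  st <- detect_states(pc)$states
  expect_lte(sum(st$pct_change), pc$pct[pc$time == 1800] + 1e-9)
})

test_that("noisy canonical traces are recovered near the generative onsets", {
  res <- t(vapply(1:10, function(s) {
    st <- detect_states(canonical_pct(noise_sd = 2, seed = s))$states
    c(n = nrow(st), o = st$onset[seq_len(min(3, nrow(st)))])
  }, numeric(4)))
  expect_gte(sum(res[, 1] == 3), 9)
  expect_true(all(abs(colMeans(res[, 2:4]) - canonical_onsets) <= 30))
})

test_that("compartment metrics follow the soma-to-endfoot progression", {
  p <- make_default_parameters("lps", "microglia")
  pcs <- lapply(compartments(), function(cp)
    percent_change(simulate_trace(p, cp, noise_sd = 0)))
  names(pcs) <- compartments()
  st <- detect_states(pcs$whole_cell)$states
  soma <- state_metrics(pcs$soma, st)
  endf <- state_metrics(pcs$endfeet, st)
  bran <- state_metrics(pcs$branches, st)
  expect_equal(which.max(soma$pct_change), 1)
  expect_equal(which.max(endf$pct_change), 3)
  expect_equal(which.max(bran$max_slope_angle), 2)
})

test_that("summaries aggregate absent states as absent, identical cells with zero SEM", {
  p <- make_default_parameters("lps", "microglia")
  traces <- lapply(compartments(), function(cp)
    simulate_trace(p, cp, noise_sd = 0))
  names(traces) <- compartments()
  m <- do.call(rbind, lapply(1:10, function(i)
    analyze_cell(traces, cell_id = paste0("c", i), condition = "lps",
                 cell_class = "microglia")))
  s <- summarize_states(m)
  expect_true(all(s$sem == 0))
  expect_true(all(s$n == 10))
  # a flat cell contributes no state rows, only overall rows
  p0 <- make_default_parameters("baseline", "microglia")
  t0 <- lapply(compartments(), function(cp) simulate_trace(p0, cp, noise_sd = 0))
  names(t0) <- compartments()
  m0 <- analyze_cell(t0, cell_id = "flat", condition = "baseline",
                     cell_class = "microglia")
  expect_true(all(m0$state == "overall"))
})
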
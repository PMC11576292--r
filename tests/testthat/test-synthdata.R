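test_that("canonical LPS microglia parameters carry the reported kinetics", {
  p <- make_default_parameters("lps", "microglia")
  expect_equal(p$state_onsets, canonical_onsets)
  expect_equal(p$state_durations, canonical_durations)
  expect_equal(sum(p$state_amplitudes[, "whole_cell"]), 253.12,
               tolerance = 1e-12)
  # whole-cell slope decreases from S1 to S3
  slopes <- p$state_amplitudes[, "whole_cell"] / p$state_durations
  expect_true(all(diff(slopes) < 0))
  # subcellular pattern: soma-dominant S1, steepest branch rise in S2,
  # endfoot-dominant S3
  A <- p$state_amplitudes
  expect_equal(unname(which.max(A[, "soma"])), 1)
  expect_equal(unname(which.max(A[, "branches"] / p$state_durations)), 2)
  expect_equal(unname(which.max(A[, "endfeet"])), 3)
  expect_equal(unname(which.max(A[1, c("soma", "branches", "endfeet")])), 1)
  expect_equal(unname(which.max(A[3, c("soma", "branches", "endfeet")])), 3)
})

test_that("untreated and emapunil-only conditions are null models", {
  for (cond in c("baseline", "emapunil_only")) {
    p <- make_default_parameters(cond, "microglia")
    expect_true(all(p$state_amplitudes == 0))
    expect_true(all(p$attenuation == 1))
  }
  expect_error(make_default_parameters("lipofuscin", "microglia"))
  expect_error(make_default_parameters("lps", "astrocyte"))
})

test_that("emapunil attenuates soma strongly and branches weakly", {
  lps <- effective_amplitudes(make_default_parameters("lps", "microglia"))
  ema <- effective_amplitudes(
    make_default_parameters("lps_emapunil", "microglia"))
  expect_lt(ema[1, "soma"], lps[1, "soma"])
  expect_lt(ema[3, "endfeet"], lps[3, "endfeet"])
  # branch amplitudes within 20 % of LPS values
  expect_true(all(abs(ema[, "branches"] / lps[, "branches"] - 1) <= 0.2))
})

test_that("whole-cell amplitudes equal the documented compartment combination", {
  for (cond in c("lps", "lps_emapunil")) {
    p <- make_default_parameters(cond, "microglia")
    w <- p$compartment_weights
    A <- effective_amplitudes(p)
    implied <- A[, "soma"] * w[["soma"]] + A[, "branches"] * w[["branches"]] +
      A[, "endfeet"] * w[["endfeet"]]
    expect_equal(unname(implied), unname(A[, "whole_cell"]), tolerance = 1e-9)
  }
})

test_that("parameter validation rejects malformed models", {
  expect_error(kinetic_parameters("lps", "microglia", baseline_intensity = 0),
               "positive")
  expect_error(kinetic_parameters("lps", "microglia", noise_sd = -1),
               "non-negative")
  expect_error(kinetic_parameters("lps", "microglia",
                                  state_onsets = c(100, 90),
                                  state_durations = c(10, 10)),
               "increasing")
  # overlapping states (onset + duration exceeds next onset)
  expect_error(kinetic_parameters("lps", "microglia",
                                  state_onsets = c(100, 150),
                                  state_durations = c(80, 10)),
               "plateau")
})

test_that("noise-free traces are exact: endpoint, plateaus, null model", {
  p <- make_default_parameters("lps", "microglia")
  tr <- simulate_trace(p, "whole_cell", noise_sd = 0)
  expect_equal(tail(tr$intensity, 1),
               p$baseline_intensity * (1 + 253.12 / 100), tolerance = 1e-12)
  # flat during baseline and between states
  flat_in <- function(a, b) {
    v <- tr$intensity[tr$time >= a & tr$time <= b]
    diff(range(v))
  }
  expect_equal(flat_in(-300, 0), 0)
  expect_equal(flat_in(363.6 + 121.2, 843.6), 0)
  expect_equal(flat_in(843.6 + 124.2, 1410), 0)
  # endpoint percent change equals the amplitude sum for every compartment
  for (cp in compartments()) {
    trc <- simulate_trace(p, cp, noise_sd = 0)
    expect_equal(100 * (tail(trc$intensity, 1) / p$baseline_intensity - 1),
                 sum(effective_amplitudes(p)[, cp]), tolerance = 1e-9)
  }
  # null model: constant at baseline
  p0 <- make_default_parameters("baseline", "microglia")
  tr0 <- simulate_trace(p0, "whole_cell", noise_sd = 0)
  expect_true(all(tr0$intensity == p0$baseline_intensity))
})

test_that("neuron trace rises to its plateau and never increases afterwards", {
  p <- make_default_parameters("lps", "neuron")
  tr <- simulate_trace(p, noise_sd = 0)
  pct <- 100 * (tr$intensity / p$baseline_intensity - 1)
  post <- tr$time >= 0
  expect_equal(max(pct[post]), 50, tolerance = 1e-9)
  after <- tr$time >= p$neuron_plateau_onset
  expect_true(all(diff(pct[after]) <= 1e-12))
  # plateau holds between plateau onset and decline onset
  hold <- tr$time >= p$neuron_plateau_onset & tr$time <= p$neuron_decline_onset
  expect_equal(diff(range(pct[hold])), 0)
})

test_that("trace simulation is seed-deterministic", {
  p <- make_default_parameters("lps", "microglia")
  a <- simulate_trace(p, "soma", seed = 7)
  b <- simulate_trace(p, "soma", seed = 7)
  c <- simulate_trace(p, "soma", seed = 8)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
  expect_error(simulate_trace(p, "soma", noise_sd = -1), "non-negative")
  expect_error(simulate_trace(p, "soma", frame_interval = 0), "positive")
})

test_that("cohorts are reproducible and reflect treatment attenuation", {
  d1 <- withr_like_tempdir()
  d2 <- withr_like_tempdir()
  co1 <- generate_cohort("lps", 10, seed = 5, out_dir = d1,
                         duration = 900, frame_interval = 2)
  co2 <- generate_cohort("lps", 10, seed = 5, out_dir = d2,
                         duration = 900, frame_interval = 2)
  expect_equal(nrow(co1$manifest), 10)
  expect_length(list.files(d1, pattern = "^microglia.*csv$"), 10)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # non-empty directory guard
  expect_error(generate_cohort("lps", 2, seed = 5, out_dir = d1,
                               duration = 900), "not empty")
  # soma attenuation visible in raw group means of final percent change
  co <- generate_cohort(c("lps", "lps_emapunil"), 10, seed = 1)
  final_soma <- vapply(co$cells, function(cl) {
    tr <- cl$traces$soma
    100 * (mean(tail(tr$intensity, 60)) / 100 - 1)
  }, 0)
  cond <- vapply(co$cells, `[[`, "", "condition")
  expect_gt(mean(final_soma[cond == "lps"]),
            mean(final_soma[cond == "lps_emapunil"]))
})

test_that("cohort CSVs round-trip through the trace reader", {
  d <- withr_like_tempdir()
  generate_cohort("lps", 2, seed = 3, out_dir = d, duration = 900,
                  frame_interval = 5)
  f <- list.files(d, pattern = "csv$", full.names = TRUE)[1]
  trs <- read_traces_csv(f)
  expect_setequal(sub(".*/", "", names(trs)), compartments())
  tr <- trs[[1]]
  expect_s3_class(tr, "fluorescence_trace")
  expect_equal(tr$metadata$condition, "lps")
})
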
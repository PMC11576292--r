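# Shared fixtures: canonical parameter sets and traces, built in code.

canonical_onsets <- c(363.6, 843.6, 1410)
canonical_durations <- c(121.2, 124.2, 180)

canonical_pct <- function(compartment = "whole_cell", noise_sd = 0,
                          seed = NULL) {
  p <- make_default_parameters("lps", "microglia")
  percent_change(simulate_trace(p, compartment, seed = seed,
                                noise_sd = noise_sd))
}

# A percent-change trace made directly of linear ramps (independent of the
# simulator): baseline 0 before treatment, each state rising `amp` percent
# over `dur` seconds starting at `onset`.
ramp_pct_trace <- function(onsets, durations, amplitudes, dt = 1,
                           t_min = -300, t_max = 1800) {
  tt <- seq(t_min, t_max, by = dt)
  pct <- numeric(length(tt))
  for (i in seq_along(onsets))
    pct <- pct + amplitudes[i] *
      pmin(pmax((tt - onsets[i]) / durations[i], 0), 1)
  tr <- fluorescence_trace(tt, 100 * (1 + pct / 100))
  percent_change(tr, c(-300, 0))
}

disc_px <- function(n, cy, cx, r) {
  outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+") <= r^2
}

withr_like_tempdir <- function() {
  d <- tempfile("mitoscreen_")
  dir.create(d)
  d
}

small_scene <- function(seed = 1)
  scene_config(duration = 1800, treatment_time = 300, frame_interval = 100,
               seed = seed)
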
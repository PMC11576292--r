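# Seeded synthetic trace generation.

# Run code under a temporary RNG state so package functions do not disturb
# the caller's random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-cell seed derived from a master seed and a cell index.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 65011 * 33013 +
                as.numeric(index) * 7919 + 17) %% 2147483647L)
}

#' Construct a fluorescence trace
#'
#' A time-stamped raw intensity series for one ROI. Time is expressed in
#' seconds relative to treatment application at `t = 0`.
#'
#' @param time Numeric vector of times (s), strictly increasing and uniformly
#'   spaced within tolerance.
#' @param intensity Numeric vector of fluorescence intensities (a.u.), finite.
#' @param metadata Named list (roi_id, compartment, condition, cell_class, ...).
#' @return Object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(time, intensity, metadata = list()) {
  time <- as.numeric(time); intensity <- as.numeric(intensity)
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length")
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * max(dt))
      stop("time must be uniformly spaced")
  }
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  structure(list(time = time, intensity = intensity, metadata = metadata),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  md <- x$metadata
  cat("<fluorescence_trace>", length(x$time), "samples,",
      sprintf("t = [%g, %g] s", min(x$time), max(x$time)), "\n")
  if (length(md))
    cat(" ", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Noise-free percent-change curve of the generative model at times t
# (s relative to treatment). Piecewise-linear ramps for microglia states;
# rise / plateau / slow decline for neurons.
model_pct <- function(p, compartment, t) {
  if (p$cell_class == "neuron") {
    amp <- p$neuron_amplitude
    rise <- pmin(pmax(t, 0), p$neuron_plateau_onset) / p$neuron_plateau_onset
    pct <- amp * rise
    dec <- pmax(t - p$neuron_decline_onset, 0) * p$neuron_decline_rate
    return(pct - ifelse(t > 0, dec, 0))
  }
  compartment <- match.arg(compartment, compartments())
  A <- effective_amplitudes(p)
  pct <- numeric(length(t))
  for (s in seq_along(p$state_onsets)) {
    o <- p$state_onsets[s]; d <- p$state_durations[s]
    ramp <- pmin(pmax((t - o) / d, 0), 1)
    pct <- pct + A[s, compartment] * ramp
  }
  pct
}

#' Simulate a single-compartment fluorescence trace
#'
#' The noise-free component is
#' `baseline_intensity * (1 + sum_s A[s, compartment]/100 * ramp_s(t))`,
#' where each `ramp_s` is 0 before the state onset, rises linearly over the
#' state duration, and is 1 afterwards (neurons follow their
#' rise/plateau/decline model instead). Independent Gaussian noise of
#' standard deviation `noise_sd` is added per frame. The same seed yields a
#' bit-identical trace.
#'
#' @param params A [kinetic_parameters()] object.
#' @param compartment Compartment token (see [compartments()]); ignored for
#'   neurons, which are modelled as a soma trace.
#' @param frame_interval Sampling interval (s), > 0.
#' @param duration Total recorded duration (s); the trace spans
#'   `[-treatment_time, duration - treatment_time]`.
#' @param treatment_time Time of treatment application after recording start
#'   (s); defines the baseline window length.
#' @param seed Integer seed for the noise realization, or `NULL`.
#' @param noise_sd Noise standard deviation (a.u.); defaults to
#'   `params$noise_sd`.
#' @param amplitude_scale Multiplier applied to all state amplitudes (and the
#'   neuron amplitude); models cell-to-cell variability in response strength.
#' @return A [fluorescence_trace()].
#' @examples
#' p <- make_default_parameters("lps", "microglia")
#' tr <- simulate_trace(p, "whole_cell", seed = 1, noise_sd = 0)
#' tail(tr$intensity, 1) / p$baseline_intensity  # 3.5312
#' @export
simulate_trace <- function(params, compartment = "whole_cell",
                           frame_interval = 1, duration = 2100,
                           treatment_time = 300, seed = NULL,
                           noise_sd = params$noise_sd,
                           amplitude_scale = 1) {
  validate_kinetic_parameters(params)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be non-negative")
  if (params$baseline_intensity <= 0) stop("baseline_intensity must be positive")
  if (duration <= treatment_time) stop("duration must exceed treatment_time")
  t <- seq(0, duration, by = frame_interval) - treatment_time
  pct <- model_pct(params, compartment, t) * amplitude_scale
  clean <- params$baseline_intensity * (1 + pct / 100)
  noisy <- with_seed(seed, clean + rnorm(length(t), 0, noise_sd))
  fluorescence_trace(t, noisy, metadata = list(
    compartment = if (params$cell_class == "neuron") "soma" else compartment,
    condition = params$condition, cell_class = params$cell_class))
}

#' Generate a seeded cohort of synthetic traces
#'
#' Simulates `n_per_group` cells per condition with per-cell seeds derived
#' deterministically from the master seed. Each cell carries a log-normal
#' amplitude multiplier (median 1, `sdlog = cell_cv`) shared across its
#' compartments, modelling cell-to-cell variability in response strength;
#' measurement noise is drawn independently per compartment and frame.
#' Microglia contribute traces for all four compartments, neurons a single
#' soma trace.
#'
#' If `out_dir` is given, one CSV per cell (columns `time_s, intensity,
#' roi_id, compartment, condition, cell_class`) plus a JSON manifest
#' describing every file are written; an existing non-empty directory is an
#' error unless `overwrite = TRUE`.
#'
#' @param conditions Character vector of condition tokens.
#' @param n_per_group Cells per condition, >= 2.
#' @param cell_class Class of the generated cells.
#' @param seed Master seed (integer).
#' @param frame_interval,duration,treatment_time Passed to [simulate_trace()].
#' @param noise_sd Noise standard deviation (a.u.); default 2 (2 % of the
#'   canonical baseline of 100 a.u.).
#' @param cell_cv Log-scale standard deviation of the per-cell amplitude
#'   multiplier (0 disables biological variability).
#' @param out_dir Optional output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with `cells` (list of per-cell records holding
#'   `traces` keyed by compartment, the applied `amplitude_scale`, seed and
#'   metadata) and `manifest` (data.frame, one row per cell).
#' @export
generate_cohort <- function(conditions, n_per_group = 10,
                            cell_class = "microglia", seed = 1,
                            frame_interval = 1, duration = 2100,
                            treatment_time = 300, noise_sd = 2,
                            cell_cv = 0.25, out_dir = NULL,
                            overwrite = FALSE) {
  conditions <- vapply(conditions, function(co) match.arg(co, .conditions), "")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
      stop("output directory ", out_dir, " is not empty (use overwrite = TRUE)")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  comps <- if (cell_class == "microglia") compartments() else "soma"
  cells <- list()
  rows <- list()
  idx <- 0
  for (cond in conditions) {
    p <- make_default_parameters(cond, cell_class)
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1
      cell_seed <- derive_seed(seed, idx)
      scale <- with_seed(cell_seed,
                         if (cell_cv > 0) exp(rnorm(1, 0, cell_cv)) else 1)
      cell_id <- sprintf("%s_%s_%02d", cell_class, cond, i)
      traces <- list()
      for (k in seq_along(comps)) {
        traces[[comps[k]]] <- simulate_trace(
          p, comps[k], frame_interval, duration, treatment_time,
          seed = derive_seed(cell_seed, k), noise_sd = noise_sd,
          amplitude_scale = scale)
        traces[[comps[k]]]$metadata$roi_id <- cell_id
      }
      file <- if (!is.null(out_dir)) paste0(cell_id, ".csv") else NA_character_
      if (!is.null(out_dir))
        write_traces_csv(traces, file.path(out_dir, file))
      cells[[cell_id]] <- list(cell_id = cell_id, condition = cond,
                               cell_class = cell_class, seed = cell_seed,
                               amplitude_scale = scale, traces = traces)
      rows[[idx]] <- data.frame(cell_id = cell_id, condition = cond,
                                cell_class = cell_class, seed = cell_seed,
                                amplitude_scale = scale, file = file,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(master_seed = seed, n_per_group = n_per_group,
           conditions = conditions, cell_class = cell_class,
           frame_interval = frame_interval, duration = duration,
           treatment_time = treatment_time, noise_sd = noise_sd,
           cell_cv = cell_cv, cells = manifest),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cells = cells, manifest = manifest))
}
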
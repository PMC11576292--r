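# Canonical tokens used throughout the package.
.conditions <- c("baseline", "lps", "lps_emapunil", "emapunil_only")
.cell_classes <- c("microglia", "neuron")

#' Compartment tokens
#'
#' The subcellular compartments resolved by the pipeline, in canonical order.
#' `whole_cell` denotes the union of soma, branches and endfeet and is the
#' trace on which depolarization states are detected.
#'
#' @return Character vector of compartment names.
#' @export
compartments <- function() c("whole_cell", "soma", "branches", "endfeet")

#' Construct a kinetic parameter set for the generative TMRE response model
#'
#' A `kinetic_parameters` object fully specifies the noise-free fluorescence
#' response of one cell class under one treatment condition: a stable baseline,
#' and (for microglia) up to three progressive depolarization states, each a
#' linear rise of the percent change from baseline between its onset and
#' onset + duration, separated from its neighbours by flat plateaus. Neurons
#' instead follow a gradual rise to a plateau followed by a slow decline.
#'
#' The `state_amplitudes` matrix holds the percent-change contribution of each
#' state (rows) per compartment (columns, see [compartments()]). The
#' `whole_cell` column is not free: it must equal the area-weighted mean of the
#' soma/branches/endfeet columns under `compartment_weights`, so that the
#' whole-cell trace is consistent with its parts.
#'
#' @param condition Treatment condition token.
#' @param cell_class `"microglia"` or `"neuron"`.
#' @param baseline_intensity Baseline fluorescence (a.u.), > 0.
#' @param state_onsets Numeric vector of state onset times (s post-treatment),
#'   strictly increasing.
#' @param state_durations Numeric vector of state durations (s), same length.
#' @param state_amplitudes Matrix `[state x compartment]` of percent-change
#'   contributions (%), columns named as [compartments()].
#' @param compartment_weights Named weights (soma, branches, endfeet) summing
#'   to 1; the documented combination defining the whole-cell amplitude.
#' @param neuron_amplitude Plateau percent change for neuron somas (%).
#' @param neuron_plateau_onset Time (s) the neuron trace stops rising.
#' @param neuron_decline_onset Time (s) the slow post-plateau decline begins.
#' @param neuron_decline_rate Decline rate (%/s), >= 0.
#' @param attenuation Matrix `[state x compartment]` of multiplicative factors
#'   in `[0, 1]` applied to `state_amplitudes` (identity for untreated
#'   conditions).
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.).
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(condition, cell_class,
                               baseline_intensity = 100,
                               state_onsets = numeric(0),
                               state_durations = numeric(0),
                               state_amplitudes = NULL,
                               compartment_weights = c(soma = 0.45,
                                                       branches = 0.40,
                                                       endfeet = 0.15),
                               neuron_amplitude = 0,
                               neuron_plateau_onset = 540,
                               neuron_decline_onset = 960,
                               neuron_decline_rate = 0.02,
                               attenuation = NULL,
                               noise_sd = 2) {
  condition <- match.arg(condition, .conditions)
  cell_class <- match.arg(cell_class, .cell_classes)
  ns <- length(state_onsets)
  if (is.null(state_amplitudes))
    state_amplitudes <- matrix(0, ns, 4,
                               dimnames = list(NULL, compartments()))
  if (is.null(attenuation))
    attenuation <- matrix(1, ns, 4, dimnames = list(NULL, compartments()))
  p <- structure(list(
    condition = condition,
    cell_class = cell_class,
    baseline_intensity = baseline_intensity,
    state_onsets = as.numeric(state_onsets),
    state_durations = as.numeric(state_durations),
    state_amplitudes = state_amplitudes,
    compartment_weights = compartment_weights,
    neuron_amplitude = neuron_amplitude,
    neuron_plateau_onset = neuron_plateau_onset,
    neuron_decline_onset = neuron_decline_onset,
    neuron_decline_rate = neuron_decline_rate,
    attenuation = attenuation,
    noise_sd = noise_sd
  ), class = "kinetic_parameters")
  validate_kinetic_parameters(p)
  p
}

#' Validate a kinetic parameter set
#'
#' Checks the structural invariants of the generative model: positive
#' baseline, non-negative noise, strictly increasing non-overlapping states,
#' non-negative amplitudes, attenuation factors in `[0, 1]`, and consistency
#' of the whole-cell amplitude column with the area-weighted compartment
#' combination.
#'
#' @param p A `kinetic_parameters` object.
#' @return Invisibly, `p` (errors on violation).
#' @export
validate_kinetic_parameters <- function(p) {
  stopifnot(inherits(p, "kinetic_parameters"))
  if (!is.finite(p$baseline_intensity) || p$baseline_intensity <= 0)
    stop("baseline_intensity must be a positive number")
  if (!is.finite(p$noise_sd) || p$noise_sd < 0)
    stop("noise_sd must be non-negative")
  ns <- length(p$state_onsets)
  if (length(p$state_durations) != ns)
    stop("state_onsets and state_durations must have equal length")
  if (ns > 1) {
    if (any(diff(p$state_onsets) <= 0))
      stop("state_onsets must be strictly increasing")
    if (any(p$state_onsets[-ns] + p$state_durations[-ns] >
            p$state_onsets[-1] + 1e-9))
      stop("states must be separated by plateaus (onset_i + duration_i <= onset_{i+1})")
  }
  if (ns > 0 && any(p$state_durations <= 0))
    stop("state_durations must be positive")
  A <- p$state_amplitudes
  if (!is.matrix(A) || nrow(A) != ns || ncol(A) != 4 ||
      !identical(colnames(A), compartments()))
    stop("state_amplitudes must be a [state x 4] matrix with columns ",
         paste(compartments(), collapse = ", "))
  if (any(A < 0)) stop("state amplitudes must be non-negative")
  w <- p$compartment_weights
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
    stop("compartment_weights must be non-negative and sum to 1")
  if (ns > 0) {
    implied <- A[, "soma"] * w[["soma"]] + A[, "branches"] * w[["branches"]] +
      A[, "endfeet"] * w[["endfeet"]]
    if (any(abs(implied - A[, "whole_cell"]) > 1e-6))
      stop("whole_cell amplitudes must equal the area-weighted compartment combination")
  }
  At <- p$attenuation
  if (!is.matrix(At) || nrow(At) != ns || ncol(At) != 4)
    stop("attenuation must be a [state x 4] matrix")
  if (any(At < 0 | At > 1)) stop("attenuation entries must lie in [0, 1]")
  if (p$neuron_decline_rate < 0) stop("neuron_decline_rate must be >= 0")
  if (p$neuron_decline_onset < p$neuron_plateau_onset)
    stop("neuron_decline_onset must be >= neuron_plateau_onset")
  invisible(p)
}

#' Canonical parameter sets for each condition and cell class
#'
#' Packages the calibrated generative model of the TMRE response. For
#' LPS-treated microglia the model has exactly three progressive states with
#' onsets 363.6, 843.6 and 1410 s (6.06, 14.06, 23.50 min) and durations
#' 121.2, 124.2 and 180 s; the whole-cell percent-change contributions
#' 120 / 80 / 53.12 % sum to the reported 253.12 % total and decrease in slope
#' from S1 to S3. Compartment amplitudes are calibrated so that S1 is
#' soma-dominant, S2 carries the steepest branch rise and S3 is
#' endfoot-dominant, while their area-weighted mean (weights soma 0.45,
#' branches 0.40, endfeet 0.15) reproduces the whole-cell split exactly.
#' LPS-treated neurons rise to a 50 % plateau by 540 s, hold until 960 s,
#' then decline slowly. Untreated (`baseline`) and `emapunil_only` conditions
#' have all state amplitudes zero. Under `lps_emapunil` the amplitudes are
#' multiplied by an attenuation matrix: strong attenuation in the soma (S1-S2)
#' and endfeet (S2-S3), weak (0.9) in the branches.
#'
#' @param condition One of `"baseline"`, `"lps"`, `"lps_emapunil"`,
#'   `"emapunil_only"`.
#' @param cell_class `"microglia"` or `"neuron"`.
#' @return A validated [kinetic_parameters()] object.
#' @examples
#' p <- make_default_parameters("lps", "microglia")
#' sum(p$state_amplitudes[, "whole_cell"])  # 253.12
#' @export
make_default_parameters <- function(condition = c("baseline", "lps",
                                                  "lps_emapunil",
                                                  "emapunil_only"),
                                    cell_class = c("microglia", "neuron")) {
  condition <- match.arg(condition)
  cell_class <- match.arg(cell_class)
  w <- c(soma = 0.45, branches = 0.40, endfeet = 0.15)

  if (cell_class == "neuron") {
    amp <- if (condition %in% c("lps", "lps_emapunil")) 50 else 0
    return(kinetic_parameters(condition, cell_class,
                              neuron_amplitude = amp,
                              compartment_weights = w))
  }

  if (condition %in% c("baseline", "emapunil_only")) {
    return(kinetic_parameters(condition, cell_class,
                              state_onsets = c(363.6, 843.6, 1410),
                              state_durations = c(121.2, 124.2, 180),
                              compartment_weights = w))
  }

  # LPS microglia: compartment amplitudes calibrated so the area-weighted
  # mean equals the whole-cell split 120 / 80 / 53.12 (sums to 253.12).
  soma <- c(220, 40, 12)
  branches <- c(45, 140, 30)
  whole <- c(120, 80, 53.12)
  endfeet <- (whole - w[["soma"]] * soma - w[["branches"]] * branches) /
    w[["endfeet"]]
  A <- cbind(whole_cell = whole, soma = soma, branches = branches,
             endfeet = endfeet)

  At <- matrix(1, 3, 4, dimnames = list(NULL, compartments()))
  if (condition == "lps_emapunil") {
    At[, "soma"] <- c(0.40, 0.40, 0.90)
    At[, "branches"] <- c(0.90, 0.90, 0.90)
    At[, "endfeet"] <- c(0.90, 0.35, 0.35)
    # whole-cell attenuation is implied by the compartment combination
    att_whole <- (A[, "soma"] * At[, "soma"] * w[["soma"]] +
                    A[, "branches"] * At[, "branches"] * w[["branches"]] +
                    A[, "endfeet"] * At[, "endfeet"] * w[["endfeet"]]) /
      A[, "whole_cell"]
    At[, "whole_cell"] <- att_whole
  }

  kinetic_parameters(condition, cell_class,
                     state_onsets = c(363.6, 843.6, 1410),
                     state_durations = c(121.2, 124.2, 180),
                     state_amplitudes = A,
                     compartment_weights = w,
                     attenuation = At)
}

#' Effective (attenuated) state amplitudes
#'
#' Element-wise product of the state amplitude matrix and the attenuation
#' matrix; this is the matrix the trace simulator actually uses. Under
#' non-emapunil conditions the attenuation is the identity and the result
#' equals `state_amplitudes`.
#'
#' @param p A `kinetic_parameters` object.
#' @return Matrix `[state x compartment]` of effective amplitudes (%).
#' @export
effective_amplitudes <- function(p) {
  stopifnot(inherits(p, "kinetic_parameters"))
  p$state_amplitudes * p$attenuation
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters>", x$cell_class, "/", x$condition, "\n")
  cat("  baseline:", x$baseline_intensity, "a.u.; noise sd:", x$noise_sd, "\n")
  if (x$cell_class == "neuron") {
    cat("  neuron plateau:", x$neuron_amplitude, "% by",
        x$neuron_plateau_onset, "s; decline", x$neuron_decline_rate,
        "%/s from", x$neuron_decline_onset, "s\n")
  } else if (length(x$state_onsets)) {
    cat("  states (onset s, duration s, whole-cell %):\n")
    for (i in seq_along(x$state_onsets))
      cat(sprintf("   S%d: %8.1f %8.1f %8.2f\n", i, x$state_onsets[i],
                  x$state_durations[i], x$state_amplitudes[i, "whole_cell"]))
  }
  invisible(x)
}
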
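# Trace kinetics: percent change from baseline, rate of change, slope
# angles, and detection of progressive depolarization states.

# Centered moving average with window of k samples (k made odd); partial
# windows at the edges.
smooth_ma <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Percent change from baseline
#'
#' `pct(t) = 100 * (F(t) - F0) / F0` with `F0` the mean intensity over the
#' baseline window. The result is invariant to multiplicative rescaling of
#' the raw intensities.
#'
#' @param trace A [fluorescence_trace()].
#' @param baseline_window Two numbers `(a, b)`: samples with `a <= t < b`
#'   form the baseline; at least 3 are required.
#' @return Object of class `pct_trace`: list with `time`, `pct`,
#'   `baseline_window`, `baseline_mean` and the trace metadata.
#' @export
percent_change <- function(trace, baseline_window = c(-300, 0)) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  a <- baseline_window[1]; b <- baseline_window[2]
  inb <- trace$time >= a & trace$time < b
  if (sum(inb) < 3)
    stop("baseline window [", a, ", ", b, ") contains fewer than 3 samples")
  f0 <- mean(trace$intensity[inb])
  if (f0 <= 0) stop("baseline mean must be positive")
  structure(list(time = trace$time,
                 pct = 100 * (trace$intensity - f0) / f0,
                 baseline_window = c(a, b), baseline_mean = f0,
                 metadata = trace$metadata),
            class = "pct_trace")
}

#' @export
print.pct_trace <- function(x, ...) {
  cat("<pct_trace>", length(x$time), "samples; baseline mean",
      signif(x$baseline_mean, 6), "a.u. over [",
      x$baseline_window[1], ",", x$baseline_window[2], ")\n")
  invisible(x)
}

#' Rate of change of a percent-change trace
#'
#' Centered moving-average smoothing (default 30 s) followed by a central
#' finite difference; one-sided differences at the endpoints. Units are
#' percent per second.
#'
#' @param pct A `pct_trace`.
#' @param smooth_window Smoothing window (s), >= the sampling interval.
#' @return List of class `rate_trace` with `time`, `rate` (%/s) and
#'   `smoothed` (the smoothed percent-change values).
#' @export
rate_of_change <- function(pct, smooth_window = 30) {
  stopifnot(inherits(pct, "pct_trace"))
  n <- length(pct$time)
  dt <- stats::median(diff(pct$time))
  if (smooth_window < dt) stop("smooth_window must be >= the sampling interval")
  k <- round(smooth_window / dt)
  if (n <= k) stop("trace is shorter than the smoothing window")
  s <- smooth_ma(pct$pct, k)
  rate <- numeric(n)
  if (n >= 3)
    rate[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  rate[1] <- (s[2] - s[1]) / dt
  rate[n] <- (s[n] - s[n - 1]) / dt
  structure(list(time = pct$time, rate = rate, smoothed = s, dt = dt,
                 smooth_window = smooth_window),
            class = "rate_trace")
}

#' Slope angle of a percent-change segment
#'
#' Least-squares line fit of percent change versus time in minutes over the
#' interval; returns `atan(slope)` in degrees (slope units %/min). The unit
#' convention (degrees of the %-per-minute slope) is this package's; pass
#' `per = "second"` for %/s.
#'
#' @param pct A `pct_trace`.
#' @param interval Two times `(a, b)` in seconds; samples with
#'   `a <= t <= b` are fitted (at least 2 required).
#' @param per Time unit of the fitted slope, `"minute"` or `"second"`.
#' @return Angle in degrees.
#' @export
slope_angle <- function(pct, interval, per = c("minute", "second")) {
  stopifnot(inherits(pct, "pct_trace"))
  per <- match.arg(per)
  sel <- pct$time >= interval[1] & pct$time <= interval[2]
  if (sum(sel) < 2) stop("interval contains fewer than 2 samples")
  tt <- pct$time[sel] / if (per == "minute") 60 else 1
  if (stats::var(tt) == 0) stop("zero time variance in interval")
  slope <- stats::cov(tt, pct$pct[sel]) / stats::var(tt)
  atan(slope) * 180 / pi
}

# Maximum slope angle over sliding sub-windows of `window` seconds inside
# [a, b]; falls back to the whole-interval fit for short states.
max_slope_angle <- function(pct, interval, window = 60,
                            per = "minute") {
  sel <- which(pct$time >= interval[1] & pct$time <= interval[2])
  if (length(sel) < 2) stop("interval contains fewer than 2 samples")
  dt <- stats::median(diff(pct$time))
  w <- max(2L, round(window / dt) + 1L)
  if (length(sel) <= w)
    return(slope_angle(pct, interval, per = per))
  tt <- pct$time[sel] / if (per == "minute") 60 else 1
  yy <- pct$pct[sel]
  n <- length(sel)
  roll <- function(x, w) {
    cs <- cumsum(c(0, x))
    cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  }
  sx <- roll(tt, w); sy <- roll(yy, w)
  sxx <- roll(tt^2, w); sxy <- roll(tt * yy, w)
  slope <- (w * sxy - sx * sy) / (w * sxx - sx^2)
  atan(max(slope)) * 180 / pi
}

#' Detect progressive depolarization states
#'
#' A state is a maximal post-treatment episode during which the smoothed
#' rate of change exceeds `rate_threshold`. Supra-threshold runs separated
#' by sub-threshold gaps shorter than `min_plateau_dur` are merged (a dip
#' shorter than a plateau does not terminate a state); merged runs shorter
#' than `min_state_dur` are discarded. If more than `max_states` candidates
#' remain, those with the largest within-state percent change are kept
#' (ties broken by earliest onset) and reported in chronological order.
#' Onset is the first supra-threshold sample time; duration the run length.
#'
#' @param pct A `pct_trace` covering at least 600 s post-treatment.
#' @param rate_threshold Rate threshold (%/s).
#' @param min_state_dur Minimum state duration (s).
#' @param min_plateau_dur Minimum plateau duration separating states (s).
#' @param max_states Maximum number of states reported.
#' @param smooth_window Smoothing window for the rate trace (s).
#' @return Object of class `state_segmentation`: data.frame `states` with
#'   columns `state`, `onset`, `duration`, `pct_change` (% gained within the
#'   state, from the smoothed trace), `pct_cumulative` (smoothed % at state
#'   end), `max_slope_angle` (degrees), `mean_rate` (%/s); plus the detection
#'   config. Flat traces yield zero states.
#' @export
detect_states <- function(pct, rate_threshold = 0.25, min_state_dur = 60,
                          min_plateau_dur = 45, max_states = 3,
                          smooth_window = 30) {
  stopifnot(inherits(pct, "pct_trace"))
  if (max(pct$time) < 600)
    stop("trace must cover at least 600 s post-treatment")
  rt <- rate_of_change(pct, smooth_window)
  post <- which(pct$time >= 0)
  supra <- post[rt$rate[post] > rate_threshold]
  cfg <- list(rate_threshold = rate_threshold, min_state_dur = min_state_dur,
              min_plateau_dur = min_plateau_dur, max_states = max_states,
              smooth_window = smooth_window)
  empty <- structure(list(states = data.frame(
    state = integer(0), onset = numeric(0), duration = numeric(0),
    pct_change = numeric(0), pct_cumulative = numeric(0),
    max_slope_angle = numeric(0), mean_rate = numeric(0)),
    config = cfg, metadata = pct$metadata), class = "state_segmentation")
  if (!length(supra)) return(empty)
  dt <- rt$dt
  gap <- diff(pct$time[supra])
  newblock <- c(TRUE, gap >= min_plateau_dur)
  block <- cumsum(newblock)
  rows <- list()
  for (b in unique(block)) {
    ii <- supra[block == b]
    onset <- pct$time[ii[1]]
    end <- pct$time[ii[length(ii)]]
    duration <- end - onset + dt
    if (duration < min_state_dur) next
    i0 <- ii[1]; i1 <- ii[length(ii)]
    pc <- rt$smoothed[i1] - rt$smoothed[i0]
    rows[[length(rows) + 1]] <- data.frame(
      onset = onset, duration = duration, pct_change = pc,
      pct_cumulative = rt$smoothed[i1],
      max_slope_angle = max_slope_angle(pct, c(onset, end)),
      mean_rate = mean(rt$rate[i0:i1]))
  }
  if (!length(rows)) return(empty)
  st <- do.call(rbind, rows)
  if (nrow(st) > max_states) {
    ord <- order(-st$pct_change, st$onset)
    st <- st[sort(ord[seq_len(max_states)]), ]
  }
  st <- st[order(st$onset), ]
  st <- cbind(state = seq_len(nrow(st)), st)
  rownames(st) <- NULL
  structure(list(states = st, config = cfg, metadata = pct$metadata),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("<state_segmentation>", nrow(x$states), "state(s)\n")
  if (nrow(x$states)) print(x$states, digits = 4)
  invisible(x)
}

#' Per-compartment metrics within fixed state windows
#'
#' Evaluates the state metrics (within-state percent change, maximum slope
#' angle, mean rate of change) of a percent-change trace over externally
#' supplied state windows -- typically the states detected on the same
#' cell's whole-cell trace, so that compartments are compared over a common
#' temporal frame.
#'
#' @param pct A `pct_trace`.
#' @param states data.frame with `onset` and `duration` columns (seconds).
#' @param smooth_window Smoothing window (s) for the rate trace.
#' @return data.frame with one row per state and columns `state`,
#'   `pct_change`, `max_slope_angle`, `mean_rate`.
#' @export
state_metrics <- function(pct, states, smooth_window = 30) {
  stopifnot(inherits(pct, "pct_trace"))
  rt <- rate_of_change(pct, smooth_window)
  out <- lapply(seq_len(nrow(states)), function(i) {
    a <- states$onset[i]; b <- a + states$duration[i]
    sel <- which(pct$time >= a & pct$time <= b)
    data.frame(state = i,
               pct_change = rt$smoothed[sel[length(sel)]] - rt$smoothed[sel[1]],
               max_slope_angle = max_slope_angle(pct, c(a, b)),
               mean_rate = mean(rt$rate[sel]))
  })
  do.call(rbind, out)
}

#' Plot a percent-change trace with its detected states
#'
#' Base-graphics trace plot with shaded state intervals.
#'
#' @param pct A `pct_trace`.
#' @param seg Optional `state_segmentation`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_states <- function(pct, seg = NULL, ...) {
  plot(pct$time / 60, pct$pct, type = "l", xlab = "time (min)",
       ylab = "percent change from baseline (%)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  if (!is.null(seg) && nrow(seg$states)) {
    for (i in seq_len(nrow(seg$states))) {
      a <- seg$states$onset[i] / 60
      b <- a + seg$states$duration[i] / 60
      graphics::rect(a, graphics::par("usr")[3], b, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("tomato", 0.2), border = NA)
      graphics::text((a + b) / 2, graphics::par("usr")[4], paste0("S", i),
                     adj = c(0.5, 1.2))
    }
  }
  invisible(NULL)
}
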
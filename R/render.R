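# Rendering synthetic two-channel stacks with ground-truth manifests.

#' Scene configuration for rendered synthetic stacks
#'
#' Geometry and acquisition parameters of a rendered field. Defaults are
#' desk-scale: 256 x 256 px at 0.5 um/px, 2 s frame interval. Morphology
#' parameters are in micrometres.
#'
#' @param field_size Field edge length (px).
#' @param pixel_size Pixel size (um).
#' @param frame_interval Frame interval (s).
#' @param duration Total recorded duration (s).
#' @param treatment_time Treatment application time after recording start (s);
#'   must allow a baseline window of at least 60 s.
#' @param n_microglia,n_neurons Cell counts for default placement.
#' @param soma_radius Microglia soma radius (um).
#' @param branch_count Number of primary branches per microglia.
#' @param branch_length Branch length beyond the soma (um).
#' @param branch_width Branch width (um).
#' @param endfoot_radius Terminal endfoot blob radius (um).
#' @param neuron_radius Neuron soma radius (um).
#' @param background Background intensity (a.u.).
#' @param cell_brightness EGFP morphology-channel brightness inside cells (a.u.).
#' @param noise_sd Per-pixel, per-frame Gaussian noise SD (a.u.).
#' @param seed Integer seed for the pixel noise.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(field_size = 256, pixel_size = 0.5,
                         frame_interval = 2, duration = 2100,
                         treatment_time = 300, n_microglia = 3,
                         n_neurons = 2, soma_radius = 5, branch_count = 4,
                         branch_length = 15, branch_width = 1.5,
                         endfoot_radius = 2.5, neuron_radius = 6,
                         background = 10, cell_brightness = 100,
                         noise_sd = 2, seed = 1) {
  if (treatment_time < 60) stop("treatment_time must allow a >= 60 s baseline")
  if (duration <= treatment_time) stop("duration must exceed treatment_time")
  structure(as.list(environment()), class = "scene_config")
}

disc_mask <- function(ny, nx, cy, cx, r) {
  outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+") <= r^2
}

# Rasterize a microglia: soma disc, gently curved branches (quadratic Bezier),
# terminal endfoot blobs. All arguments in pixels; returns disjoint
# ground-truth compartment masks (priority soma > endfeet > branches).
microglia_masks <- function(ny, nx, cy, cx, soma_r, n_branch, branch_len,
                            branch_w, endfoot_r, rotation = 0) {
  soma <- disc_mask(ny, nx, cy, cx, soma_r)
  line <- matrix(FALSE, ny, nx)
  endf <- matrix(FALSE, ny, nx)
  tips <- NULL
  for (b in seq_len(n_branch)) {
    th <- rotation + 2 * pi * (b - 1) / n_branch
    u <- c(cos(th), sin(th)); perp <- c(-sin(th), cos(th))
    p0 <- c(cy, cx) + soma_r * c(u[2], u[1])
    p2 <- c(cy, cx) + (soma_r + branch_len) * c(u[2], u[1])
    bend <- 0.2 * branch_len * (if (b %% 2) 1 else -1)
    p1 <- (p0 + p2) / 2 + bend * c(perp[2], perp[1])
    tt <- seq(0, 1, length.out = max(40, ceiling(4 * branch_len)))
    pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
      outer(tt^2, p2)
    ys <- round(pts[, 1]); xs <- round(pts[, 2])
    ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    line[cbind(ys[ok], xs[ok])] <- TRUE
    endf <- endf | disc_mask(ny, nx, p2[1], p2[2], endfoot_r)
    tips <- rbind(tips, p2)
  }
  # thicken the branch centerline to the requested width
  if (branch_w > 1) {
    sz <- 2 * floor(branch_w / 2) + 1
    line <- EBImage::dilate(line * 1, EBImage::makeBrush(sz, "disc")) > 0.5
  }
  list(soma = soma,
       endfeet = endf & !soma,
       branches = line & !soma & !endf,
       cell = soma | endf | line,
       tips = tips)
}

# Default non-overlapping cell placement: greedy scan over a candidate grid,
# honouring each cell class's spatial reach. Deterministic.
default_cell_positions <- function(scene, classes) {
  n <- length(classes)
  if (n == 0) return(NULL)
  reach_m <- (scene$soma_radius + scene$branch_length +
                2 * scene$endfoot_radius) / scene$pixel_size
  reach_n <- scene$neuron_radius / scene$pixel_size
  reach <- ifelse(classes == "microglia", reach_m, reach_n)
  fs <- scene$field_size
  cand <- seq(1, fs, by = 8)
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    r <- reach[i]
    found <- FALSE
    for (y in cand) {
      if (y < r + 2 || y > fs - r - 1) next
      for (x in cand) {
        if (x < r + 2 || x > fs - r - 1) next
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          if (sqrt((y - pos[j, 1])^2 + (x - pos[j, 2])^2) <
              r + reach[j] + 4) { ok <- FALSE; break }
        }
        if (ok) { pos[i, ] <- c(y, x); found <- TRUE; break }
      }
      if (found) break
    }
    if (!found) stop("requested cells do not fit in the field")
  }
  pos
}

#' Render a synthetic two-channel time-lapse stack with ground truth
#'
#' Channel 1 (EGFP) is static morphology at constant brightness; channel 2
#' (TMRE) follows, inside each compartment of each cell, that compartment's
#' noise-free simulated kinetic trace, over a uniform background. Independent
#' Gaussian noise is added to every pixel of every frame of both channels.
#' The returned manifest records the exact compartment masks and noise-free
#' traces used for rendering.
#'
#' @param scene A [scene_config()].
#' @param cells Optional list of per-cell specifications, each a list with
#'   `class` (`"microglia"`/`"neuron"`), `condition`, optional `params`
#'   (defaults to [make_default_parameters()]), optional `y`, `x` centre (px)
#'   and `amplitude_scale`. By default `n_microglia` LPS microglia and
#'   `n_neurons` LPS neurons are placed automatically.
#' @return List with `stack` (an [image_stack()]) and `manifest` (scene
#'   parameters plus one record per cell: id, class, condition, disjoint
#'   compartment masks, and noise-free per-compartment traces in a.u.).
#' @export
render_stack <- function(scene, cells = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  ny <- nx <- scene$field_size
  ps <- scene$pixel_size
  if (is.null(cells)) {
    cells <- c(
      lapply(seq_len(scene$n_microglia), function(i)
        list(class = "microglia", condition = "lps")),
      lapply(seq_len(scene$n_neurons), function(i)
        list(class = "neuron", condition = "lps")))
  }
  if (length(cells) == 0) {
    tvec <- seq(0, scene$duration, by = scene$frame_interval) -
      scene$treatment_time
    nt <- length(tvec)
    arr <- array(scene$background, c(nt, 2, ny, nx))
    arr <- with_seed(scene$seed,
                     arr + array(rnorm(length(arr), 0, scene$noise_sd),
                                 dim(arr)))
    arr[arr < 0] <- 0
    return(list(stack = image_stack(arr, scene$frame_interval, ps,
                                    scene$treatment_time),
                manifest = list(scene = unclass(scene), cells = list())))
  }
  pos <- default_cell_positions(
    scene, vapply(cells, function(cl) cl$class, ""))
  tvec <- seq(0, scene$duration, by = scene$frame_interval) -
    scene$treatment_time
  nt <- length(tvec)

  records <- list()
  occupied <- matrix(FALSE, ny, nx)
  collisions <- character(0)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    cy <- cl$y %||% pos[i, 1]; cx <- cl$x %||% pos[i, 2]
    params <- cl$params %||% make_default_parameters(cl$condition, cl$class)
    if (cl$class == "microglia") {
      mk <- microglia_masks(ny, nx, cy, cx,
                            scene$soma_radius / ps, scene$branch_count,
                            scene$branch_length / ps, scene$branch_width / ps,
                            scene$endfoot_radius / ps,
                            rotation = (i - 1) * pi / 7)
      masks <- mk[c("soma", "branches", "endfeet")]
      cellmask <- mk$cell
      comps <- c("soma", "branches", "endfeet")
    } else {
      cellmask <- disc_mask(ny, nx, cy, cx, scene$neuron_radius / ps)
      masks <- list(soma = cellmask)
      comps <- "soma"
    }
    if (any(cellmask & occupied))
      collisions <- c(collisions, sprintf("cell %d at (%g, %g)", i, cy, cx))
    occupied <- occupied | cellmask
    traces <- lapply(comps, function(cp)
      simulate_trace(params, cp, scene$frame_interval, scene$duration,
                     scene$treatment_time, noise_sd = 0,
                     amplitude_scale = cl$amplitude_scale %||% 1)$intensity)
    names(traces) <- comps
    records[[i]] <- list(cell_id = sprintf("cell_%02d", i),
                         cell_class = cl$class, condition = cl$condition,
                         center = c(y = cy, x = cx), masks = masks,
                         cell_mask = cellmask, traces = traces)
  }
  if (length(collisions))
    stop("overlapping cell positions: ", paste(collisions, collapse = "; "))

  ch1_base <- matrix(scene$background, ny, nx)
  ch1_base[occupied] <- scene$cell_brightness
  arr <- array(0, c(nt, 2, ny, nx))
  ch2_t <- matrix(scene$background, ny, nx)
  for (t in seq_len(nt)) {
    fr <- ch2_t
    for (rec in records)
      for (cp in names(rec$masks))
        fr[rec$masks[[cp]]] <- rec$traces[[cp]][t]
    arr[t, 1, , ] <- ch1_base
    arr[t, 2, , ] <- fr
  }
  arr <- with_seed(scene$seed,
                   arr + array(rnorm(length(arr), 0, scene$noise_sd), dim(arr)))
  arr[arr < 0] <- 0
  list(stack = image_stack(arr, scene$frame_interval, ps,
                           scene$treatment_time),
       manifest = list(scene = unclass(scene), time = tvec, cells = records))
}
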
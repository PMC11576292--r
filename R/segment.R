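# Morphology-channel segmentation and trace extraction.

shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  yi <- seq_len(ny); xi <- seq_len(nx)
  vy <- yi + dy >= 1 & yi + dy <= ny
  vx <- xi + dx >= 1 & xi + dx <= nx
  out[yi[vy], xi[vx]] <- m[yi[vy] + dy, xi[vx] + dx]
  out
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels that do not break 8-connectivity until
#' a one-pixel-wide skeleton remains.
#'
#' @param mask Logical `[Y, X]` matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  img <- mask != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { img[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Geodesic distance (in pixels scaled by `step`) along the skeleton from its
# tips (pixels with <= 1 skeleton neighbour; optionally restricted by
# `tip_ok`, a predicate on (y, x) -- used to reject pseudo-tips at the soma
# junction). Returns a vector aligned with `coords` rows; Inf where
# unreachable (e.g. pure loops without tips).
skeleton_tip_distance <- function(skel, step = 1, tip_ok = NULL) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) return(numeric(0))
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[coords] <- seq_len(n)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  nbrs <- vector("list", n)
  deg <- integer(n)
  for (k in seq_len(nrow(offs))) {
    ys <- coords[, 1] + offs$dy[k]; xs <- coords[, 2] + offs$dx[k]
    ok <- ys >= 1 & ys <= nrow(skel) & xs >= 1 & xs <= ncol(skel)
    hit <- integer(n); hit[ok] <- id[cbind(ys[ok], xs[ok])]
    w <- sqrt(offs$dy[k]^2 + offs$dx[k]^2) * step
    for (i in which(hit > 0)) {
      nbrs[[i]] <- rbind(nbrs[[i]], c(hit[i], w))
      deg[i] <- deg[i] + 1L
    }
  }
  seeds <- deg <= 1
  if (!is.null(tip_ok) && any(seeds))
    seeds <- seeds & vapply(seq_len(n), function(i)
      tip_ok(coords[i, 1], coords[i, 2]), TRUE)
  dist <- rep(Inf, n)
  dist[seeds] <- 0
  done <- rep(FALSE, n)
  # Dijkstra, O(n^2): skeletons are small
  repeat {
    i <- which.min(ifelse(done, Inf, dist))
    if (!length(i) || !is.finite(dist[i])) break
    done[i] <- TRUE
    nb <- nbrs[[i]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      j <- nb[r, 1]; w <- nb[r, 2]
      if (!done[j] && dist[i] + w < dist[j]) dist[j] <- dist[i] + w
    }
    if (all(done | !is.finite(dist))) break
  }
  dist
}

#' Segment cells from a morphology image
#'
#' Global threshold (Otsu by default) followed by connected-component
#' labelling; components smaller than `min_area_px` are discarded and labels
#' compacted to `1..K` (0 = background). An all-constant image yields zero
#' cells; NaN pixels are an error. Touching cells are merged into one label
#' (no watershed splitting).
#'
#' @param morphology 2-D numeric matrix (time-averaged EGFP frame).
#' @param min_area_px Minimum component area (px).
#' @param threshold_method `"otsu"`, or a numeric threshold in image units.
#' @return Integer label matrix.
#' @export
segment_cells <- function(morphology, min_area_px = 50,
                          threshold_method = "otsu") {
  if (any(is.nan(morphology))) stop("morphology image contains NaN pixels")
  if (any(!is.finite(morphology)) || any(morphology < 0))
    stop("morphology image must be finite and non-negative")
  rng <- range(morphology)
  if (diff(rng) == 0)
    return(matrix(0L, nrow(morphology), ncol(morphology)))
  if (is.numeric(threshold_method)) {
    mask <- morphology > threshold_method
  } else if (identical(threshold_method, "otsu")) {
    norm <- (morphology - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm))
    mask <- norm > th
  } else stop("unknown threshold_method: ", threshold_method)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

#' Partition a cell mask into soma, branches and endfeet
#'
#' The soma is the largest connected component surviving a morphological
#' opening with a disc of radius `soma_open_radius`; the remainder is
#' skeletonized, and skeleton leaf segments within `endfoot_len` (path length
#' along the skeleton) of a branch tip define the endfeet: every non-soma
#' cell pixel whose nearest skeleton pixel belongs to a leaf segment is an
#' endfoot pixel, the rest are branches. The three masks are disjoint and
#' exhaustive. If nothing survives the opening, the whole mask is assigned to
#' the soma and a warning record is attached (attribute `"warning"`).
#'
#' @param cell_mask Logical `[Y, X]` matrix, one connected component.
#' @param pixel_size Pixel size (um).
#' @param soma_open_radius Opening disc radius (um).
#' @param endfoot_len Maximum leaf-segment path length from a tip (um).
#' @param cell_id Optional identifier stored in the result.
#' @return Object of class `compartment_masks`: list with `soma`, `branches`,
#'   `endfeet` logical masks and `cell_id`.
#' @export
partition_compartments <- function(cell_mask, pixel_size = 0.5,
                                   soma_open_radius = 3, endfoot_len = 4,
                                   cell_id = NA_character_) {
  cell_mask <- cell_mask != 0
  if (!any(cell_mask)) stop("cell_mask is empty")
  ny <- nrow(cell_mask); nx <- ncol(cell_mask)
  empty <- matrix(FALSE, ny, nx)
  r_px <- max(1, round(soma_open_radius / pixel_size))
  opened <- EBImage::opening(cell_mask * 1,
                             EBImage::makeBrush(2 * r_px + 1, "disc")) > 0.5
  warn <- NULL
  if (!any(opened)) {
    res <- list(cell_id = cell_id, soma = cell_mask, branches = empty,
                endfeet = empty)
    warn <- "no pixels survived the soma opening; whole mask assigned to soma"
  } else {
    lab <- EBImage::bwlabel(opened * 1)
    sizes <- tabulate(lab[lab > 0])
    soma <- lab == which.max(sizes)
    soma <- matrix(as.vector(soma), ny, nx)
    rest <- cell_mask & !soma
    branches <- empty; endfeet <- empty
    if (any(rest)) {
      skel <- skeletonize(rest)
      tipdist <- numeric(0)
      if (any(skel)) {
        # a skeleton endpoint abutting the soma is a cut artefact, not a
        # branch tip: reject endpoints within the opening radius of the soma
        soma_px <- which(soma, arr.ind = TRUE)
        tip_ok <- function(y, x) {
          min((soma_px[, 1] - y)^2 + (soma_px[, 2] - x)^2) > (r_px + 1)^2
        }
        tipdist <- skeleton_tip_distance(skel, step = pixel_size,
                                         tip_ok = tip_ok)
      }
      # components of the remainder without any true branch tip are slivers
      # of the soma boundary left by the opening: return them to the soma
      restlab <- EBImage::bwlabel(rest * 1)
      restlab <- matrix(as.integer(round(restlab)), ny, nx)
      sc <- which(skel, arr.ind = TRUE)
      tipped <- unique(restlab[sc[is.finite(tipdist), , drop = FALSE]])
      sliver <- rest & !(restlab %in% tipped)
      soma <- soma | sliver
      rest <- rest & !sliver
      if (any(rest)) {
        keep_sk <- is.finite(tipdist)
        sck <- sc[keep_sk, , drop = FALSE]
        leaf <- tipdist[keep_sk] <= endfoot_len
        if (all(leaf)) {
          endfeet <- rest
        } else if (any(leaf)) {
          rc <- which(rest, arr.ind = TRUE)
          d2 <- outer(rc[, 1], sck[, 1], "-")^2 +
            outer(rc[, 2], sck[, 2], "-")^2
          nearest <- max.col(-d2, ties.method = "first")
          is_end <- leaf[nearest]
          endfeet[rc[is_end, , drop = FALSE]] <- TRUE
          branches <- rest & !endfeet
        } else {
          branches <- rest
        }
      }
    }
    res <- list(cell_id = cell_id, soma = soma, branches = branches,
                endfeet = endfeet)
  }
  class(res) <- "compartment_masks"
  if (!is.null(warn)) attr(res, "warning") <- warn
  res
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat("<compartment_masks>", x$cell_id, ":",
      sum(x$soma), "soma px,", sum(x$branches), "branch px,",
      sum(x$endfeet), "endfoot px\n")
  invisible(x)
}

#' Extract the mean-intensity trace of a mask from a stack
#'
#' Per-frame arithmetic mean of the chosen channel over the mask pixels,
#' timestamped from the stack's frame interval (time relative to treatment).
#' Deterministic and linear in the pixel values.
#'
#' @param stack An [image_stack()].
#' @param mask Logical `[Y, X]` matrix, non-empty, matching the stack grid.
#' @param channel Channel label or index (default `"TMRE"`).
#' @param metadata Extra metadata stored on the trace.
#' @return A [fluorescence_trace()].
#' @export
extract_trace <- function(stack, mask, channel = "TMRE", metadata = list()) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty")
  if (nrow(mask) != d[3] || ncol(mask) != d[4])
    stop("mask dimensions do not match the stack")
  ci <- if (is.character(channel)) match(channel, stack$channels)
  else as.integer(channel)
  if (is.na(ci) || ci < 1 || ci > d[2]) stop("unknown channel: ", channel)
  idx <- which(mask)
  vals <- vapply(seq_len(d[1]),
                 function(t) mean(stack$data[t, ci, , ][idx]), 0)
  fluorescence_trace(stack$time, vals,
                     metadata = c(metadata, list(channel = stack$channels[ci],
                                                 n_pixels = length(idx))))
}

#' Intersection-over-union of two masks
#' @param a,b Logical matrices of equal dimension.
#' @return IoU in `[0, 1]` (1 for two empty masks).
#' @export
iou <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Match segmented labels to ground-truth cell masks
#'
#' For each ground-truth mask, finds the label with maximal overlap and
#' reports the IoU (0 if no label overlaps).
#'
#' @param labels Integer label matrix from [segment_cells()].
#' @param gt_masks List of logical ground-truth cell masks.
#' @return Data frame with columns `gt`, `label`, `iou`.
#' @export
match_labels <- function(labels, gt_masks) {
  out <- data.frame(gt = seq_along(gt_masks), label = NA_integer_, iou = 0)
  for (i in seq_along(gt_masks)) {
    gm <- gt_masks[[i]] != 0
    labs <- labels[gm]
    labs <- labs[labs > 0]
    if (!length(labs)) next
    best <- as.integer(names(which.max(table(labs))))
    out$label[i] <- best
    out$iou[i] <- iou(labels == best, gm)
  }
  out
}
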
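test_that("cell segmentation labels bright components and guards inputs", {
  expect_equal(max(segment_cells(matrix(0, 50, 50))), 0)
  expect_error(segment_cells(matrix(NaN, 5, 5)), "NaN")
  img <- matrix(10, 80, 80)
  img[disc_px(80, 20, 20, 8)] <- 100
  img[disc_px(80, 60, 60, 8)] <- 100
  lab <- segment_cells(img)
  expect_equal(max(lab), 2)
  # small specks below min_area_px are discarded
  img[disc_px(80, 40, 70, 2)] <- 100
  expect_equal(max(segment_cells(img, min_area_px = 50)), 2)
  # touching cells merge into one label (documented: no watershed)
  img2 <- matrix(10, 80, 80)
  img2[disc_px(80, 40, 35, 8)] <- 100
  img2[disc_px(80, 40, 45, 8)] <- 100
  expect_equal(max(segment_cells(img2)), 1)
})

test_that("compartment partition is disjoint and exhaustive for any mask", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(FALSE, 64, 64)
    m[disc_px(64, 32, 32, 6 + rep)] <- TRUE
    # random straight processes
    for (b in 1:3) {
      th <- stats::runif(1, 0, 2 * pi)
      for (r in seq(0, 24, by = 0.5)) {
        y <- round(32 + r * sin(th)); x <- round(32 + r * cos(th))
        if (y >= 2 && y <= 63 && x >= 2 && x <= 63) m[y, x] <- TRUE
      }
    }
    cm <- partition_compartments(m, pixel_size = 0.5)
    expect_true(all((cm$soma | cm$branches | cm$endfeet) == m))
    expect_equal(sum(cm$soma & cm$branches), 0)
    expect_equal(sum(cm$soma & cm$endfeet), 0)
    expect_equal(sum(cm$branches & cm$endfeet), 0)
  }
})

test_that("degenerate morphologies fall back sensibly", {
  # disc-only cell: everything is soma, no warning
  disc <- matrix(FALSE, 40, 40)
  disc[disc_px(40, 20, 20, 10)] <- TRUE
  cm <- partition_compartments(disc, pixel_size = 0.5)
  expect_true(all(cm$soma == disc))
  expect_equal(sum(cm$branches) + sum(cm$endfeet), 0)
  expect_null(attr(cm, "warning"))
  # a mask thinner than the opening disc: assigned to soma with a warning
  thin <- matrix(FALSE, 40, 40)
  thin[20, 5:35] <- TRUE
  cm2 <- partition_compartments(thin, pixel_size = 0.5, soma_open_radius = 3)
  expect_true(all(cm2$soma == thin))
  expect_match(attr(cm2, "warning"), "soma")
  expect_error(partition_compartments(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeletonization thins to a centred single-pixel path", {
  m <- matrix(FALSE, 30, 60)
  m[14:17, 5:55] <- TRUE
  sk <- skeletonize(m)
  expect_true(all(m[sk]))
  expect_lt(sum(sk), sum(m) / 2)
  # one skeleton pixel per column along the bar interior
  expect_true(all(colSums(sk[, 10:50]) == 1))
})

test_that("trace extraction is an exact mask mean and linear", {
  arr <- array(7, c(3, 2, 10, 10))
  st <- image_stack(arr, frame_interval = 1, pixel_size = 0.5)
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  expect_true(all(extract_trace(st, mask, "TMRE")$intensity == 7))
  # single-pixel mask equals the pixel's series
  arr2 <- array(stats::rnorm(3 * 2 * 10 * 10, 50, 5)^2, c(3, 2, 10, 10))
  st2 <- image_stack(arr2, 1, 0.5)
  one <- matrix(FALSE, 10, 10); one[4, 6] <- TRUE
  expect_equal(extract_trace(st2, one, 2)$intensity, arr2[, 2, 4, 6])
  # linearity: trace(a * X) = a * trace(X)
  st3 <- image_stack(arr2 * 2.5, 1, 0.5)
  expect_equal(extract_trace(st3, mask, 2)$intensity,
               2.5 * extract_trace(st2, mask, 2)$intensity, tolerance = 1e-12)
  # independent pixel-loop oracle for the mask mean
  manual <- sapply(1:3, function(t) {
    tot <- 0; np <- 0
    for (y in 1:10) for (x in 1:10) if (mask[y, x]) {
      tot <- tot + arr2[t, 2, y, x]; np <- np + 1
    }
    tot / np
  })
  expect_equal(extract_trace(st2, mask, 2)$intensity, manual,
               tolerance = 1e-12)
  expect_error(extract_trace(st2, matrix(FALSE, 10, 10)), "empty")
  expect_error(extract_trace(st2, mask, "DAPI"), "channel")
})

test_that("rendered stacks honour the scene contract", {
  sc <- scene_config(field_size = 128, duration = 420, treatment_time = 60,
                     frame_interval = 30, n_microglia = 1, n_neurons = 1,
                     seed = 3)
  r <- render_stack(sc)
  avg <- apply(r$stack$data[, 1, , ], c(2, 3), mean)
  expect_equal(max(segment_cells(avg)), 2)
  # channel-2 mask mean tracks the manifest's noise-free soma trace
  g <- r$manifest$cells[[1]]
  tr <- extract_trace(r$stack, g$masks$soma, "TMRE")
  se <- sc$noise_sd / sqrt(sum(g$masks$soma))
  expect_lt(max(abs(tr$intensity - g$traces$soma)), 5 * se)
  # empty scene renders pure background + noise
  sc0 <- scene_config(field_size = 64, duration = 120, treatment_time = 60,
                      frame_interval = 30, n_microglia = 0, n_neurons = 0)
  r0 <- render_stack(sc0)
  expect_equal(mean(r0$stack$data), sc0$background, tolerance = 0.5)
  expect_length(r0$manifest$cells, 0)
  # deterministic for a fixed seed
  r2 <- render_stack(sc)
  expect_identical(r$stack$data, r2$stack$data)
})

test_that("stacks round-trip through TIFF with sidecar metadata", {
  sc <- scene_config(field_size = 64, duration = 120, treatment_time = 60,
                     frame_interval = 30, n_microglia = 0, n_neurons = 1,
                     seed = 9)
  r <- render_stack(sc)
  f <- file.path(withr_like_tempdir(), "stack.tif")
  write_stack_tiff(r$stack, f)
  back <- read_stack_tiff(f)
  expect_equal(back$data, r$stack$data, tolerance = 1e-6)
  expect_equal(back$time, r$stack$time)
  # masks round-trip through run-length JSON
  fm <- file.path(dirname(f), "masks.json")
  ms <- list(cell_01 = r$manifest$cells[[1]]$masks)
  write_masks_json(ms, fm)
  back_m <- read_masks_json(fm)
  expect_identical(back_m$cell_01$soma, ms$cell_01$soma)
})
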
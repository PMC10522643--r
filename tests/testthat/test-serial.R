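# serial labeling: threshold -> clean -> centroid -> track -> interpolation

disk_image <- function(h = 100, w = 100, cx = 40, cy = 60, r = 8,
                       fg = 0.9, bg = 0.05) {
  img <- matrix(bg, h, w)
  d2 <- outer(((seq_len(h) - 1) - cy)^2, ((seq_len(w) - 1) - cx)^2, "+")
  img[d2 <= r^2] <- fg
  img
}

test_that("extract_dye_mask thresholds exactly; cleaning is separate", {
  expect_false(any(extract_dye_mask(matrix(0, 32, 32),
                                    dye_mask_config(threshold = 0.5))))
  img <- disk_image()
  m <- extract_dye_mask(img, dye_mask_config(threshold = 0.5))
  expect_identical(m, img >= 0.5)  # pixelwise oracle

  # hot pixels survive extraction (cleaning is a separate stage)
  img2 <- img
  hot <- cbind(c(5, 90, 10), c(80, 5, 10))
  img2[hot] <- 0.95
  m2 <- extract_dye_mask(img2, dye_mask_config(threshold = 0.5))
  expect_true(all(m2[hot]))
  expect_identical(m2, img2 >= 0.5)

  img2[3, 3] <- NaN
  expect_error(extract_dye_mask(img2, dye_mask_config(threshold = 0.5)),
               "non-finite")
})

test_that("otsu threshold separates planted foreground from background", {
  img <- disk_image(fg = 0.85, bg = 0.1)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.85)
  m <- extract_dye_mask(img)  # default otsu config
  expect_identical(m, img >= 0.5 | m)  # mask contains the disk
  expect_identical(unname(which(m)), unname(which(img >= 0.85)))
})

test_that("clean_mask removes specks, fills holes, respects min area", {
  cfg <- dye_mask_config(threshold = 0.5, open_radius_px = 1,
                         close_radius_px = 1, min_area_px = 10)
  img <- disk_image(r = 8)
  m <- extract_dye_mask(img, cfg)
  m[cbind(c(5, 90, 10), c(80, 5, 10))] <- TRUE
  cleaned <- clean_mask(m, cfg)
  # flood-fill oracle: only the big component remains
  expect_equal(length(flood_areas(cleaned)), 1L)
  expect_true(all(flood_areas(cleaned) >= 10))
  expect_false(cleaned[6, 81])

  holey <- extract_dye_mask(img, cfg)
  holey[61, 41] <- FALSE  # 1-px interior hole
  filled <- clean_mask(holey, cfg)
  expect_true(filled[61, 41])

  empty <- matrix(FALSE, 20, 20)
  expect_identical(clean_mask(empty, cfg), empty)
})

test_that("clean_mask is idempotent", {
  cfg <- dye_mask_config(threshold = 0.5)
  withr::with_seed(7, {
    for (i in 1:5) {
      m <- matrix(runif(40 * 40) > 0.6, 40, 40)
      once <- clean_mask(m, cfg)
      expect_identical(clean_mask(once, cfg), once)
    }
  })
})

test_that("mask_centroid: symmetric disk, empty mask, multi-blob weighting", {
  img <- disk_image(cx = 40, cy = 60, r = 8)
  lab <- mask_centroid(img >= 0.5, 3L)
  expect_equal(lab$frame_index, 3L)
  expect_true(lab$present)
  expect_lt(abs(lab$x - 40), 0.05)
  expect_lt(abs(lab$y - 60), 0.05)

  empty <- mask_centroid(matrix(FALSE, 10, 10), 0L)
  expect_false(empty$present)
  expect_true(is.na(empty$x))

  # weighted mean oracle over two rectangular blobs
  m <- matrix(FALSE, 60, 60)
  blob1 <- as.matrix(expand.grid(r = 9:13, c = 1:21))    # 105 px at (10, 10)
  blob2 <- as.matrix(expand.grid(r = 39:43, c = 37:45))  # 45 px at (40, 40)
  m[blob1] <- TRUE; m[blob2] <- TRUE
  lab2 <- mask_centroid(m, 0L)
  exp_x <- mean(c(blob1[, "c"], blob2[, "c"])) - 1
  exp_y <- mean(c(blob1[, "r"], blob2[, "r"])) - 1
  expect_equal(lab2$x, exp_x)
  expect_equal(lab2$y, exp_y)
  expect_equal(exp_x, (105 * 10 + 45 * 40) / 150)  # hand-derived
})

test_that("label_sequence tracks a moving blob and keeps absences", {
  sim <- gen_serial_sequence(serial_fixture_spec(
    n_frames = 10, occluded_frames = c(4, 5), seed = 11))
  p <- pair_frames(sim$manifest, max_gap_ms = 7.5)
  uv <- sim$uv_frames
  names(uv) <- as.character(sim$manifest$index[
    sim$manifest$illumination == "uv"])
  track <- label_sequence(p$pairs, uv)
  expect_equal(nrow(track), 10L)
  expect_identical(track$present,
                   c(rep(TRUE, 4), FALSE, FALSE, rep(TRUE, 4)))
  err <- sqrt((track$x - sim$truth$x)^2 + (track$y - sim$truth$y)^2)
  expect_lt(max(err, na.rm = TRUE), 0.5)
  # labels attach to visible frame indices
  expect_equal(track$frame_index, p$pairs$visible_index)
})

test_that("label extraction is invariant to monotone intensity rescaling", {
  sim <- gen_serial_sequence(serial_fixture_spec(n_frames = 4, seed = 2))
  img <- sim$uv_frames[[1]]
  cfg <- dye_mask_config()  # otsu adapts to the rescaling
  lab1 <- mask_centroid(clean_mask(extract_dye_mask(img, cfg), cfg), 0L)
  resc <- clamp(img^0.7 * 0.9, 0, 1)   # monotone, separation-preserving
  lab2 <- mask_centroid(clean_mask(extract_dye_mask(resc, cfg), cfg), 0L)
  expect_lt(abs(lab1$x - lab2$x), 0.25)
  expect_lt(abs(lab1$y - lab2$y), 0.25)
})

test_that("unreadable frames are recorded and processing continues", {
  sim <- gen_serial_sequence(serial_fixture_spec(n_frames = 4, seed = 5))
  p <- pair_frames(sim$manifest, max_gap_ms = 7.5)
  uv <- sim$uv_frames
  names(uv) <- as.character(sim$manifest$index[
    sim$manifest$illumination == "uv"])
  uv[["2"]] <- NULL  # drop one frame
  track <- label_sequence(p$pairs, uv)
  expect_equal(nrow(track), 4L)
  expect_false(track$present[2])
  expect_length(attr(track, "errors"), 1L)
})

test_that("interpolation re-estimates labels at the visible shutter time", {
  sched <- build_trigger_schedule(10, "triphasic", 2)
  # linear motion x = y = (t - 2.5) / 1: samples (0,0) at t=2.5, (10,10) at 12.5
  tr <- structure(
    data.frame(frame_index = 0:1, x = c(0, 10), y = c(0, 10),
               present = TRUE, source = "centroid"),
    width = 256L, height = 256L, errors = character(0),
    class = c("label_track", "data.frame"))
  out <- interpolate_track(tr, "linear", sched)
  expect_equal(out$x[1], 5)  # midpoint of the line at t = 7.5
  expect_equal(out$y[1], 5)
  expect_true(all(out$source == "interpolated"))

  const <- tr; const$x <- 4; const$y <- 7
  outc <- interpolate_track(const, "linear", sched)
  expect_true(all(outc$x == 4 & outc$y == 7))
})

test_that("cubic beats linear on a quadratic trajectory", {
  sched <- build_trigger_schedule(10, "triphasic", 2)
  n <- 12
  t_uv <- (0:(n - 1)) * 10 + 2.5
  t_vis <- (0:(n - 1)) * 10 + 7.5
  fx <- function(t) 0.01 * (t - 60)^2 / 10
  tr <- structure(
    data.frame(frame_index = 0:(n - 1), x = fx(t_uv), y = fx(t_uv),
               present = TRUE, source = "centroid"),
    width = 256L, height = 256L, errors = character(0),
    class = c("label_track", "data.frame"))
  lin <- interpolate_track(tr, "linear", sched)
  cub <- interpolate_track(tr, "cubic", sched)
  true_x <- fx(t_vis)
  inner <- 2:(n - 1)  # spline end conditions differ at the boundary
  expect_lt(max(abs(cub$x - true_x)[inner]),
            max(abs(lin$x - true_x)[inner]))
})

test_that("interpolation respects absent runs and support minima", {
  sched <- build_trigger_schedule(10, "triphasic", 2)
  tr <- structure(
    data.frame(frame_index = 0:9, x = c(0:2, NA, NA, 5:9),
               y = 0, present = c(rep(TRUE, 3), FALSE, FALSE, rep(TRUE, 5)),
               source = "centroid"),
    width = 256L, height = 256L, errors = character(0),
    class = c("label_track", "data.frame"))
  tr$y <- tr$x
  filled <- interpolate_track(tr, "linear", sched, max_absent_run = 2L)
  expect_true(all(filled$present))    # short gap filled
  kept <- interpolate_track(tr, "linear", sched, max_absent_run = 1L)
  expect_identical(kept$present, tr$present)  # long-for-config gap stays

  sparse <- tr; sparse$present[] <- FALSE; sparse$present[1] <- TRUE
  expect_warning(same <- interpolate_track(sparse, "linear", sched),
                 "insufficient")
  expect_identical(same, sparse)
})

test_that("label tracks round-trip through CSV", {
  sim <- gen_serial_sequence(serial_fixture_spec(
    n_frames = 6, occluded_frames = 2L, seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_label_track(sim$truth, f)
  back <- read_label_track(f, width = 256L, height = 256L)
  expect_equal(back$x, sim$truth$x)
  expect_identical(back$present, sim$truth$present)
})
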
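# training targets, segmentation, compositing, augmentation, export

test_that("segmentation mask covers the planted region tightly", {
  poly_r <- 60
  spec <- speckle_fixture_spec(
    seed = 6, n_frames = 1, size = c(192L, 192L), n_spots = 400,
    region_polygon = {
      ang <- seq(0, 2 * pi, length.out = 33)[-33]
      cbind(95.5 + poly_r * cos(ang), 95.5 + poly_r * sin(ang))
    },
    warp_type = "identity")
  sc <- gen_speckle_scene(spec)
  mask <- make_segmentation_mask(sc$base_uv, dilation_px = 2,
                                 closing_px = 15)
  region <- sc$base_mask
  expect_gte(sum(mask & region) / sum(region), 0.95)
  # mask stays within the region dilated by a small margin
  grown <- binary_dilate(region, 6)
  expect_true(all(!mask | grown))

  expect_false(any(make_segmentation_mask(matrix(0, 64, 64))))

  solid <- matrix(FALSE, 64, 64); solid[20:44, 20:44] <- TRUE
  again <- make_segmentation_mask(solid * 0.8, dilation_px = 0,
                                  closing_px = 3, threshold = 0.5)
  expect_identical(again, solid)
})

test_that("background compositing preserves foreground exactly", {
  img <- matrix(runif(32 * 32), 32, 32)
  all_fg <- matrix(TRUE, 32, 32)
  expect_identical(composite_background(img, all_fg, "noise", 1), img)

  none <- matrix(FALSE, 32, 32)
  flat <- composite_background(img, none, 0.3)
  expect_true(all(flat == 0.3))

  n1 <- composite_background(img, none, "noise", 7)
  n2 <- composite_background(img, none, "noise", 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, composite_background(img, none, "noise", 8)))

  expect_error(composite_background(img, matrix(TRUE, 4, 4)), "mask size")
})

test_that("training target maps: geometry, absent, and interleaving", {
  cfg <- training_target_config(stride = 8, positive_radius_px = 17,
                                landmark_roster = c("hand", "foot"))
  tt <- make_training_targets(
    data.frame(landmark = "hand", x = 424, y = 424, present = TRUE),
    c(848, 848), cfg)
  expect_equal(dim(tt$maps$hand), c(106, 106))  # ceil(848 / 8)
  expect_equal(tt$maps$hand[54, 54], 1)         # map cell (53, 53) 0-based
  # positive disk radius honored: all positive cell centers within 17 px
  pos <- which(tt$maps$hand == 1, arr.ind = TRUE)
  centers <- (pos - 1) * 8 + 3.5
  expect_true(all(sqrt(rowSums((centers - 424)^2)) <= 17))
  expect_equal(unname(tt$loss_mask), c(1, 0))   # foot unlabeled here

  # absent-labeled landmark: all-zeros map, loss mask 1
  tt2 <- make_training_targets(
    data.frame(landmark = "hand", x = NA_real_, y = NA_real_,
               present = FALSE),
    c(848, 848), cfg)
  expect_equal(sum(tt2$maps$hand), 0)
  expect_equal(unname(tt2$loss_mask), c(1, 0))

  # no labels at all: every loss-mask channel 0
  tt3 <- make_training_targets(
    data.frame(landmark = character(0), x = numeric(0), y = numeric(0),
               present = logical(0)),
    c(848, 848), cfg)
  expect_equal(unname(tt3$loss_mask), c(0, 0))

  expect_error(make_training_targets(
    data.frame(landmark = "hand", x = 9000, y = 0, present = TRUE),
    c(848, 848), cfg), "outside")
})

test_that("identity augmentation is a no-op; translation moves labels", {
  img <- value_noise(48, 48, 5)
  labs <- data.frame(landmark = "a", x = c(10, 30), y = c(12, 30),
                     present = c(TRUE, TRUE))
  out <- augment_image(img, labs, seed = 1, cfg = augment_config_identity())
  expect_equal(out$image, img)
  expect_equal(out$labels$x, labs$x)
  expect_equal(out$labels$y, labs$y)

  shift_cfg <- augment_config_identity()
  shift_cfg$translate_frac <- c(10 / 48, 10 / 48)  # exactly +10 px
  out2 <- augment_image(img, labs, seed = 1, cfg = shift_cfg)
  expect_equal(out2$labels$x, labs$x + 10)
  expect_equal(out2$labels$y, labs$y + 10)

  d1 <- augment_image(img, labs, seed = 42)
  d2 <- augment_image(img, labs, seed = 42)
  expect_identical(d1, d2)
  expect_false(identical(d1$image, augment_image(img, labs, seed = 43)$image))
})

test_that("geometric augmentation commutes with the label transform", {
  # corner-marker oracle: plant a bright spot, augment, re-locate the spot
  base <- matrix(0.05, 96, 96)
  lab <- data.frame(landmark = "spot", x = 38, y = 55, present = TRUE)
  img <- glowlabel:::render_gauss_spot(base, lab$x, lab$y, 2.2, 0.9)
  cfg <- augment_config(blur_sigma = c(0, 0), contrast = c(1, 1),
                        noise_sigma = 0, channel_scale = c(1, 1),
                        crop_frac = c(0, 0), scale = c(0.9, 1.1),
                        rotation_deg = c(-15, 15), shear_deg = c(-8, 8),
                        translate_frac = c(-0.05, 0.05))
  for (sd in 1:4) {
    out <- augment_image(img, lab, seed = sd, cfg = cfg)
    expect_true(out$labels$present)
    mask <- out$image >= 0.5 * max(out$image)
    cen <- mask_centroid(mask, 0L)
    expect_lt(sqrt((cen$x - out$labels$x)^2 + (cen$y - out$labels$y)^2), 1)
  }
})

test_that("labels leaving the frame become absent", {
  img <- matrix(0.5, 40, 40)
  labs <- data.frame(landmark = "a", x = 38, y = 20, present = TRUE)
  cfg <- augment_config_identity()
  cfg$translate_frac <- c(0.25, 0.25)  # +10 px: x -> 48, off frame
  out <- augment_image(img, labs, seed = 1, cfg = cfg)
  expect_false(out$labels$present)
  expect_true(is.na(out$labels$x))
})

test_that("dataset export round-trips and encodes absences per COCO", {
  labels <- data.frame(
    image_id = rep(c("im1", "im2", "im3"), each = 2),
    landmark = rep(c("hand", "foot"), 3),
    x = c(10, 20, 30, NA, 50, 60), y = c(1, 2, 3, NA, 5, 6),
    present = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  f <- withr::local_tempfile(fileext = ".json")
  export_dataset(labels, c(100L, 100L), c("hand", "foot"), f)
  obj <- jsonlite::read_json(f)
  expect_length(obj$images, 3L)
  expect_length(obj$annotations, 3L)
  expect_length(obj$annotations[[1]]$keypoints, 6L)  # 2 landmarks x (x,y,v)
  # absent -> visibility 0 at coordinates (0, 0)
  expect_equal(unlist(obj$annotations[[2]]$keypoints)[4:6], c(0, 0, 0))

  back <- read_dataset(f)
  f2 <- withr::local_tempfile(fileext = ".json")
  export_dataset(back$labels, c(100L, 100L), back$roster, f2)
  expect_identical(readLines(f), readLines(f2))  # byte-identical re-export

  dup <- rbind(labels, labels[1, ])
  expect_error(export_dataset(dup, c(100L, 100L), c("hand", "foot"),
                              withr::local_tempfile(fileext = ".json")),
               "duplicate")

  fcsv <- withr::local_tempfile(fileext = ".csv")
  export_dataset(labels, c(100L, 100L), c("hand", "foot"), fcsv,
                 format = "csv")
  backc <- read_dataset(fcsv, format = "csv")
  expect_equal(backc$labels$x, labels$x)
})
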
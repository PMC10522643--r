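# label propagation: homographies, median pooling, auto landmarks

test_that("fit_homography recovers exact projective maps", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      H <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
      H[3, 1:2] <- rnorm(2, sd = 1e-3)
      H <- H / H[3, 3]
      src <- cbind(runif(12, 0, 200), runif(12, 0, 200))
      dst <- apply_homography(H, src)
      Hf <- fit_homography(src, dst)
      expect_lt(max(abs(Hf - H)), 1e-6)
      expect_lt(max(abs(apply_homography(Hf, src) - dst)), 1e-7)
    }
  })
  # pure translation is a homography
  src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  Ht <- fit_homography(src, src + matrix(c(15, -5), 4, 2, byrow = TRUE))
  expect_equal(apply_homography(Ht, c(3, 4)), cbind(18, -1),
               tolerance = 1e-8)
})

test_that("degenerate homography supports are refused", {
  src <- cbind(0:5, 2 * (0:5) + 1)  # collinear
  dst <- src + 3
  expect_error(fit_homography(src, dst), "degenerate")
  expect_error(fit_homography(src[1:3, ], dst[1:3, ]), ">= 4")
})

test_that("trimmed fit shrugs off a single gross support outlier", {
  withr::with_seed(8, {
    H <- diag(3); H[1, 3] <- 12; H[2, 3] <- -7
    src <- cbind(runif(15, 0, 100), runif(15, 0, 100))
    dst <- apply_homography(H, src)
    dst[4, ] <- dst[4, ] + c(30, -25)   # gross outlier
    plain <- fit_homography(src, dst)
    trimmed <- fit_homography_trimmed(src, dst)
    p <- c(50, 50)
    err_plain <- sqrt(sum((apply_homography(plain, p) -
                             apply_homography(H, p))^2))
    err_trim <- sqrt(sum((apply_homography(trimmed, p) -
                            apply_homography(H, p))^2))
    expect_lt(err_trim, 1e-6)
    expect_gt(err_plain, err_trim)
  })
})

test_that("median pooling follows the >= 5 matches rule", {
  mk <- function(xs, ys) data.frame(left_index = seq_along(xs),
                                    right_index = seq_along(xs),
                                    left_x = 0, left_y = 0,
                                    right_x = xs, right_y = ys, distance = 0)
  regions <- list(
    "1" = mk(1:4, 1:4),                        # 4 matches -> absent
    "2" = mk(10:16, rep(20, 7)),               # odd count median
    "3" = mk(rep(50, 5), rep(50, 5))           # constant
  )
  labs <- pool_manual_neighborhood(regions, neighborhood_label_config(5))
  expect_false(labs$present[labs$region == "1"])
  expect_equal(labs$x[labs$region == "2"], 13)
  expect_equal(labs$y[labs$region == "2"], 20)
  expect_equal(labs$x[labs$region == "3"], 50)
  expect_equal(labs$n_matches, c(4L, 7L, 5L))
})

test_that("region grouping pools matches by left-endpoint region", {
  mask <- matrix(0L, 50, 50)
  mask[1:20, 1:20] <- 1L
  mask[30:50, 30:50] <- 2L
  m <- data.frame(left_index = 1:3, right_index = 1:3,
                  left_x = c(5, 40, 25), left_y = c(5, 40, 25),
                  right_x = 0, right_y = 0, distance = 0)
  g <- group_matches_by_region(m, mask)
  expect_equal(nrow(g[["1"]]), 1L)
  expect_equal(nrow(g[["2"]]), 1L)   # point at (25,25) is unassigned
})

test_that("auto landmark selection is a maximal feasible packing", {
  fs3 <- feature_set(data.frame(x = c(0, 20, 40), y = 0, scale = 1,
                                orientation = 0, response = 1),
                     matrix(0, 3, 4), "t")
  for (sd in 0:6) {
    sel <- select_auto_landmarks(fs3, auto_landmark_config(
      min_spacing_px = 30, min_neighbors = 4, seed = sd))
    xs <- fs3$keypoints$x[sel$landmarks]
    # feasible: pairwise spacing respected
    if (length(xs) > 1) expect_true(min(dist(xs)) > 30)
    # 20-apart pairs never coexist
    expect_false(all(c(0, 20) %in% xs) || all(c(20, 40) %in% xs))
    # maximal: no unselected feature is addable
    others <- setdiff(fs3$keypoints$x, xs)
    if (length(others)) {
      expect_true(all(vapply(others, function(o) any(abs(xs - o) <= 30),
                             logical(1))))
    }
  }

  # everything inside one spacing disk -> exactly one landmark
  tight <- feature_set(data.frame(x = runif(10, 0, 10), y = runif(10, 0, 10),
                                  scale = 1, orientation = 0, response = 1),
                       matrix(0, 10, 4), "t")
  sel1 <- select_auto_landmarks(tight, auto_landmark_config(
    min_spacing_px = 30, min_neighbors = 4, seed = 1))
  expect_length(sel1$landmarks, 1L)

  # determinism and empty candidates
  a <- select_auto_landmarks(tight, auto_landmark_config(min_neighbors = 4,
                                                         seed = 5))
  b <- select_auto_landmarks(tight, auto_landmark_config(min_neighbors = 4,
                                                         seed = 5))
  expect_identical(a, b)
  none <- select_auto_landmarks(tight, auto_landmark_config(
    min_neighbors = 4), region_mask = matrix(0L, 20, 20))
  expect_length(none$landmarks, 0L)
  expect_error(auto_landmark_config(min_neighbors = 3), "4")
})

test_that("propagate_landmark implements the three-way rule", {
  kp <- data.frame(x = c(100, 90, 110, 100, 100, 95), y = c(80, 70, 70, 90, 60, 100),
                   scale = 1, orientation = 0, response = 1)
  fs <- feature_set(kp, matrix(0, 6, 4), "t")
  cfg <- auto_landmark_config(min_neighbors = 4, seed = 0)

  # (1) direct match
  m <- data.frame(left_index = 1L, right_index = 9L, left_x = 100,
                  left_y = 80, right_x = 120, right_y = 80, distance = 0)
  lab <- propagate_landmark(1L, fs, m, neighbors = 2:6, cfg)
  expect_true(lab$present)
  expect_equal(c(lab$x, lab$y), c(120, 80))
  expect_equal(lab$source, "direct")

  # (2) translated neighbors -> homography propagation
  nb <- 2:6
  m2 <- data.frame(left_index = nb, right_index = nb,
                   left_x = kp$x[nb], left_y = kp$y[nb],
                   right_x = kp$x[nb] + 15, right_y = kp$y[nb] - 5,
                   distance = 0)
  lab2 <- propagate_landmark(1L, fs, m2, neighbors = nb,
                             auto_landmark_config(min_neighbors = 5, seed = 0))
  expect_true(lab2$present)
  expect_equal(lab2$source, "propagated")
  expect_equal(c(lab2$x, lab2$y), c(115, 75), tolerance = 1e-6)

  # (3) too few neighbors -> absent
  lab3 <- propagate_landmark(1L, fs, m2[1:3, ], neighbors = nb,
                             auto_landmark_config(min_neighbors = 10,
                                                  seed = 0))
  expect_false(lab3$present)

  # degenerate (collinear) support falls through to absent with a warning
  col_kp <- data.frame(x = c(50, 0, 10, 20, 30), y = c(50, 0, 10, 20, 30),
                       scale = 1, orientation = 0, response = 1)
  col_fs <- feature_set(col_kp, matrix(0, 5, 4), "t")
  mc <- data.frame(left_index = 2:5, right_index = 2:5,
                   left_x = col_kp$x[2:5], left_y = col_kp$y[2:5],
                   right_x = col_kp$x[2:5] + 2, right_y = col_kp$y[2:5] + 2,
                   distance = 0)
  expect_warning(
    labc <- propagate_landmark(1L, col_fs, mc, neighbors = 2:5,
                               auto_landmark_config(min_neighbors = 4,
                                                    seed = 0)),
    "degenerate")
  expect_false(labc$present)
})

test_that("propagation recovers a planted projective warp end to end", {
  sc <- cached("prop_scene", {
    gen_speckle_scene(speckle_fixture_spec(seed = 2, n_frames = 1,
                                           warp_type = "projective"))
  })
  tfs <- cached("prop_tfs", detect_features(sc$base_uv, 0.01))
  cfg <- auto_landmark_config(seed = 0)
  sel <- select_auto_landmarks(tfs, cfg, region_mask = sc$base_mask * 1L)
  ffs <- detect_features(sc$frames_uv[[1]], 0.01)
  m <- coherency_filter(match_features(tfs, ffs), 50, 50)
  labs <- propagate_landmarks(sel, tfs, m, cfg, frame_index = 1L)
  truth <- sc$correspondence(1, cbind(tfs$keypoints$x[sel$landmarks],
                                      tfs$keypoints$y[sel$landmarks]))
  err <- sqrt((labs$x - truth[, 1])^2 + (labs$y - truth[, 2])^2)
  expect_gte(mean(labs$present), 0.95)
  expect_lt(max(err, na.rm = TRUE), 1.5)
  # homography route labels strictly more landmarks than direct-only
  direct <- propagate_landmarks(sel, tfs, m, cfg, frame_index = 1L,
                                use_homography = FALSE)
  expect_gt(mean(labs$present), mean(direct$present))
})
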
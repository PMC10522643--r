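# evaluation: pixel error, PR/AUC, scale optimization, confidence traces

test_that("pixel_error: distance, zero, absent, frame mismatch", {
  t1 <- data.frame(frame_index = 0L, x = 0, y = 0, present = TRUE)
  p1 <- data.frame(frame_index = 0L, x = 3, y = 4, confidence = 1)
  expect_equal(pixel_error(p1, t1), 5)
  expect_equal(pixel_error(data.frame(frame_index = 0L, x = 0, y = 0), t1), 0)
  absent <- data.frame(frame_index = 0L, x = NA, y = NA, present = FALSE)
  expect_true(is.na(pixel_error(p1, absent)))
  expect_error(pixel_error(data.frame(frame_index = 1L, x = 0, y = 0), t1),
               "different frames")
})

test_that("pr_curve reproduces the hand-enumerated example", {
  preds <- data.frame(frame_index = 1:4, x = c(0, 0, 999, 0), y = 0,
                      confidence = c(0.9, 0.8, 0.7, 0.6))
  truths <- data.frame(frame_index = 1:4, x = c(1, 1, 0, NA), y = 0,
                       present = c(TRUE, TRUE, TRUE, FALSE))
  pc <- pr_curve(preds, truths, image_width = 100,
                 error_threshold_frac = 0.05)
  at <- function(th) pc$points[pc$points$threshold == th, ]
  expect_equal(at(0.8)$precision, 1)
  expect_equal(at(0.8)$recall, 2 / 3)
  expect_equal(at(0.6)$precision, 2 / 4)
  expect_equal(at(0.6)$recall, 2 / 3)
})

test_that("perfect predictions give AUC exactly 1; degenerate sweeps work", {
  n <- 10
  preds <- data.frame(frame_index = 1:n, x = 1:n, y = 1:n, confidence = 1)
  truths <- data.frame(frame_index = 1:n, x = 1:n, y = 1:n, present = TRUE)
  expect_identical(pr_curve(preds, truths, 100)$auc, 1)

  flat <- preds; flat$confidence <- 0
  pc0 <- pr_curve(flat, truths, 100)
  expect_equal(nrow(pc0$points), 1L)
  expect_false(is.na(pc0$auc))

  none <- truths; none$present <- FALSE
  expect_error(pr_curve(preds, none, 100), "recall undefined")
})

test_that("pr_curve equals the brute-force oracle; AUC order-invariant", {
  withr::with_seed(33, {
    for (rep in 1:15) {
      n <- sample(5:40, 1)
      truths <- data.frame(frame_index = 1:n, x = runif(n, 0, 100),
                           y = runif(n, 0, 100),
                           present = runif(n) > 0.2)
      truths$x[!truths$present] <- NA
      truths$y[!truths$present] <- NA
      preds <- data.frame(
        frame_index = 1:n,
        x = ifelse(is.na(truths$x), runif(n, 0, 100),
                   truths$x + rnorm(n, 0, 4)),
        y = ifelse(is.na(truths$y), runif(n, 0, 100),
                   truths$y + rnorm(n, 0, 4)),
        confidence = round(runif(n), 2))  # duplicate confidences likely
      if (!any(truths$present)) next
      pc <- pr_curve(preds, truths, 100)
      want <- brute_pr(preds, truths, 100)
      expect_equal(pc$points$recall, want$recall)
      expect_equal(pc$points$precision, want$precision)
      # auc invariant to reordering rows with duplicated confidence
      perm <- sample.int(n)
      pc2 <- pr_curve(preds[perm, ], truths, 100)
      expect_equal(pc2$auc, pc$auc)
    }
  })
})

test_that("two-level scale search equals the exhaustive composite sweep", {
  grid <- scale_grid()
  truth <- data.frame(frame_index = 0:4, x = 1:5, y = 1:5)
  for (peak in c(0.8, 1.0, 1.4)) {
    det <- gen_mock_detector(mock_detector_spec(truth, peak_scale = peak))
    res <- scale_optimize(det, 0:4, level = "clip", grid = grid)
    # oracle: flat sweep over the composite grid actually evaluated
    k_star <- grid$coarse_exponents[which.max(
      vapply(grid$coarse_exponents,
             function(k) det(0, grid$base^k)$confidence, numeric(1)))]
    composite <- c(grid$base^grid$coarse_exponents,
                   grid$base^(k_star + grid$fine_offsets))
    objs <- vapply(composite, function(s) det(0, s)$confidence, numeric(1))
    expect_equal(res$scale, composite[which.max(objs)])
    expect_length(res$scale, 1L)   # clip level: one scale for the clip
    expect_equal(nrow(res$evaluations), 10L)
  }
})

test_that("flat objectives break ties toward the first grid point", {
  truth <- data.frame(frame_index = 0:3, x = 0, y = 0)
  det <- gen_mock_detector(mock_detector_spec(truth, peak_scale = 1,
                                              conf_width = Inf))
  res <- scale_optimize(det, 0:3, level = "clip")
  expect_equal(res$scale, 2^-1)  # first coarse point
  # predictions unchanged by the choice of scale
  expect_equal(res$predictions$x, truth$x)
})

test_that("frame-level tracks alternating optima; clip level compromises", {
  n <- 6
  truth <- data.frame(frame_index = 0:(n - 1), x = 1, y = 1)
  peaks <- rep(c(0.5, 2), n / 2)
  det <- gen_mock_detector(mock_detector_spec(truth, peak_scale = peaks,
                                              conf_width = 1))
  fr <- scale_optimize(det, 0:(n - 1), level = "frame")
  expect_length(fr$scales, n)
  expect_true(all(abs(log2(fr$scales) - log2(peaks)) <= 0.05))
  cl <- scale_optimize(det, 0:(n - 1), level = "clip")
  # wide symmetric bumps: the clip optimum sits between the two peaks
  expect_lte(abs(log2(cl$scale)), 0.35)
})

test_that("mock predictions are scale-invariant (back-projection contract)", {
  truth <- data.frame(frame_index = 0:9, x = sin(1:10), y = cos(1:10))
  det <- gen_mock_detector(mock_detector_spec(truth, noise_sigma_px = 1,
                                              seed = 4))
  p1 <- vapply(0:9, function(f) det(f, 0.5)$x, numeric(1))
  p2 <- vapply(0:9, function(f) det(f, 2.0)$x, numeric(1))
  expect_identical(p1, p2)
})

test_that("detector failures are skipped; all-failure errors", {
  truth <- data.frame(frame_index = 0:4, x = 1, y = 1)
  det <- gen_mock_detector(mock_detector_spec(truth, peak_scale = 1,
                                              failure_frames = 2L))
  res <- scale_optimize(det, 0:4, level = "clip")
  expect_true(res$predictions$failed[res$predictions$frame_index == 2])
  expect_equal(sum(res$predictions$failed), 1L)

  dead <- gen_mock_detector(mock_detector_spec(truth,
                                               failure_frames = 0:4))
  expect_error(scale_optimize(dead, 0:4, level = "clip"), "every frame")
})

test_that("confidence_trace is a pure sliding window", {
  preds <- data.frame(frame_index = 1:5, x = 1:5, y = 1:5,
                      confidence = 0.5)
  expect_equal(nrow(confidence_trace(preds, 100)), 5L)
  long <- data.frame(frame_index = 1:150, x = 1:150, y = 1:150,
                     confidence = 0.5)
  tr <- confidence_trace(long, 100)
  expect_equal(nrow(tr), 100L)
  expect_equal(tr$frame_index, 51:150)
  empty <- preds[integer(0), ]
  expect_equal(nrow(confidence_trace(empty, 10)), 0L)
})
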
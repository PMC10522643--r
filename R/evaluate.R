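# Detector evaluation: pixel error, on-target precision/recall over all
# confidence thresholds, AUC, rolling confidence traces, and test-time
# scale optimization by two-level hierarchical grid search over image
# pre-scaling factors.

#' Pixel error between a prediction and a ground-truth label
#'
#' Euclidean distance when the truth is present; `NA` (excluded from error
#' statistics) when the truth is absent.
#'
#' @param pred one-row data frame (or list) with `frame_index`, `x`, `y`.
#' @param truth one-row data frame with `frame_index`, `x`, `y`, `present`.
#' @return scalar distance, or `NA_real_` when truth is absent.
#' @export
pixel_error <- function(pred, truth) {
  if (!isTRUE(all.equal(as.integer(pred$frame_index),
                        as.integer(truth$frame_index)))) {
    stop("prediction and truth refer to different frames", call. = FALSE)
  }
  if (!truth$present) return(NA_real_)
  sqrt((pred$x - truth$x)^2 + (pred$y - truth$y)^2)
}

#' Precision-recall curve over all confidence thresholds
#'
#' An on-target prediction satisfies three conditions: the ground-truth
#' label is not absent; the prediction confidence is at or above the
#' threshold; and the pixel error is below `error_threshold_frac` times the
#' image width. Recall divides on-target predictions by the number of
#' frames with a visible landmark; precision divides by the number of
#' predictions at or above the threshold. The curve is traced at every
#' distinct confidence value; AUC is the trapezoidal integral over recall
#' with a (recall = 0, first precision) anchor.
#'
#' @param preds data frame `frame_index`, `x`, `y`, `confidence`.
#' @param truths data frame `frame_index`, `x`, `y`, `present` (aligned by
#'   `frame_index`).
#' @param image_width image width in pixels.
#' @param error_threshold_frac on-target distance cutoff as a fraction of
#'   image width (reference value 0.05).
#' @return object of class `pr_curve`: list with `points` (data frame
#'   `threshold`, `recall`, `precision`), `auc`, `error_threshold_frac`.
#' @export
pr_curve <- function(preds, truths, image_width,
                     error_threshold_frac = 0.05) {
  stopifnot(is.data.frame(preds), is.data.frame(truths))
  i <- match(preds$frame_index, truths$frame_index)
  if (anyNA(i)) stop("predictions reference frames missing from truth",
                     call. = FALSE)
  truths <- truths[i, , drop = FALSE]
  n_visible <- sum(truths$present)
  if (n_visible == 0L) {
    stop("recall undefined: no frame has a visible landmark", call. = FALSE)
  }
  err <- sqrt((preds$x - truths$x)^2 + (preds$y - truths$y)^2)
  good <- truths$present & !is.na(err) &
    err < error_threshold_frac * image_width
  thresholds <- sort(unique(preds$confidence), decreasing = TRUE)
  pts <- vapply(thresholds, function(th) {
    sel <- preds$confidence >= th
    on_target <- sum(sel & good)
    c(recall = on_target / n_visible,
      precision = if (sum(sel)) on_target / sum(sel) else NA_real_)
  }, numeric(2))
  points <- data.frame(threshold = thresholds, recall = pts["recall", ],
                       precision = pts["precision", ])
  ord <- order(points$recall, points$precision)
  rr <- c(0, points$recall[ord])
  pp <- c(points$precision[ord][1], points$precision[ord])
  auc <- sum(diff(rr) * (utils::head(pp, -1) + utils::tail(pp, -1)) / 2)
  structure(list(points = points, auc = auc,
                 error_threshold_frac = error_threshold_frac),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve: %d thresholds, AUC = %.4f>\n", nrow(x$points),
              x$auc))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$points$recall, x$points$precision, type = "b",
                 xlim = c(0, 1), ylim = c(0, 1), xlab = "recall",
                 ylab = "precision",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  invisible(x)
}

#' The composite two-level scale grid
#'
#' Coarse scales `base^k` and fine refinements `base^(k* + j)` around the
#' coarse winner. The stated fine upper bound (+0.33) is unreachable from
#' -0.33 in steps of 0.16; exactly five fine offsets are used.
#'
#' @param coarse_exponents coarse exponents k (reference: -1 to 1 by 0.5).
#' @param fine_offsets fine offsets j (reference: -0.33 by 0.16, 5 values).
#' @param base grid base (reference: 2).
#' @export
scale_grid <- function(coarse_exponents = seq(-1, 1, by = 0.5),
                       fine_offsets = seq(-0.33, by = 0.16,
                                          length.out = 5),
                       base = 2) {
  if (!length(coarse_exponents) || !length(fine_offsets)) {
    stop("scale grid must be nonempty", call. = FALSE)
  }
  structure(list(coarse_exponents = sort(coarse_exponents),
                 fine_offsets = sort(fine_offsets), base = base),
            class = "scale_grid")
}

# evaluate detector over frames at one scale; returns predictions and the
# mean confidence (objective), skipping failed frames
eval_at_scale <- function(detector, frames, scale) {
  preds <- lapply(frames, function(fr) detector(fr, scale))
  ok <- !vapply(preds, is.null, logical(1))
  conf <- vapply(preds[ok], function(p) p$confidence, numeric(1))
  list(preds = preds, ok = ok,
       objective = if (any(ok)) mean(conf) else NA_real_)
}

#' Test-time scale optimization
#'
#' Two-level hierarchical search over image pre-scaling factors, maximizing
#' mean prediction confidence. Level 1 evaluates the coarse scales
#' `base^k`; level 2 evaluates `base^(k* + j)` around the coarse winner;
#' the returned scale is the argmax over *all* evaluated grid points (so it
#' equals a flat exhaustive sweep of the same composite grid for unimodal
#' objectives). Ties break toward the earliest evaluated point. At
#' `level = "clip"` the objective is the clip-mean confidence and one scale
#' is returned; at `level = "frame"` the search runs per frame.
#'
#' A smoothness objective (mean adjacent-frame displacement) is available
#' but off by default; confidence is the objective that tracks accuracy.
#'
#' @param detector function `(frame, scale) -> list(x, y, confidence)` or
#'   `NULL` on failure, with predictions in original-image coordinates.
#' @param frames list (or vector) of frames passed to the detector.
#' @param level `"clip"` or `"frame"`.
#' @param grid a [scale_grid()].
#' @param objective `"confidence"` (default) or `"smoothness"` (negated
#'   mean displacement, clip level only).
#' @return for `"clip"`: list with `scale`, `predictions` (data frame),
#'   `evaluations` (data frame `scale`, `objective`). For `"frame"`: list
#'   with `scales` (per frame), `predictions`, `evaluations`.
#' @export
scale_optimize <- function(detector, frames, level = c("clip", "frame"),
                           grid = scale_grid(),
                           objective = c("confidence", "smoothness")) {
  level <- match.arg(level)
  objective <- match.arg(objective)
  stopifnot(is.function(detector), length(frames) >= 1L)
  frame_ids <- if (is.list(frames)) seq_along(frames) else frames

  obj_of <- function(ev) {
    if (objective == "confidence") return(ev$objective)
    ok_preds <- ev$preds[ev$ok]
    if (length(ok_preds) < 2L) return(NA_real_)
    xs <- vapply(ok_preds, function(p) p$x, numeric(1))
    ys <- vapply(ok_preds, function(p) p$y, numeric(1))
    -mean(sqrt(diff(xs)^2 + diff(ys)^2))
  }

  search_one <- function(frs) {
    scales1 <- grid$base^grid$coarse_exponents
    evs1 <- lapply(scales1, function(s) eval_at_scale(detector, frs, s))
    o1 <- vapply(evs1, obj_of, numeric(1))
    if (all(is.na(o1))) stop("detector failed on every frame", call. = FALSE)
    k_star <- grid$coarse_exponents[which.max(o1)]
    scales2 <- grid$base^(k_star + grid$fine_offsets)
    evs2 <- lapply(scales2, function(s) eval_at_scale(detector, frs, s))
    o2 <- vapply(evs2, obj_of, numeric(1))
    all_scales <- c(scales1, scales2)
    all_obj <- c(o1, o2)
    all_evs <- c(evs1, evs2)
    best <- which.max(all_obj)   # earliest evaluated wins ties
    list(scale = all_scales[best], ev = all_evs[[best]],
         evaluations = data.frame(scale = all_scales, objective = all_obj))
  }

  as_pred_df <- function(ev, ids, scale) {
    rows <- lapply(seq_along(ids), function(i) {
      p <- ev$preds[[i]]
      if (is.null(p)) {
        data.frame(frame_index = ids[i], x = NA_real_, y = NA_real_,
                   confidence = NA_real_, scale = scale, failed = TRUE)
      } else {
        data.frame(frame_index = ids[i], x = p$x, y = p$y,
                   confidence = p$confidence, scale = scale, failed = FALSE)
      }
    })
    do.call(rbind, rows)
  }

  if (level == "clip") {
    res <- search_one(frames)
    preds <- as_pred_df(res$ev, frame_ids, res$scale)
    list(scale = res$scale, predictions = preds,
         evaluations = res$evaluations)
  } else {
    if (objective == "smoothness") {
      stop("smoothness objective is defined at clip level only",
           call. = FALSE)
    }
    out <- lapply(seq_along(frame_ids), function(i) {
      fr <- if (is.list(frames)) frames[i] else frames[i]
      res <- tryCatch(search_one(fr), error = function(e) NULL)
      if (is.null(res)) {
        # detector failed on this frame at every scale
        return(list(scale = NA_real_,
                    pred = data.frame(frame_index = frame_ids[i],
                                      x = NA_real_, y = NA_real_,
                                      confidence = NA_real_,
                                      scale = NA_real_, failed = TRUE),
                    evaluations = NULL))
      }
      list(scale = res$scale,
           pred = as_pred_df(res$ev, frame_ids[i], res$scale),
           evaluations = cbind(frame_index = frame_ids[i], res$evaluations))
    })
    scales <- vapply(out, `[[`, numeric(1), "scale")
    if (all(is.na(scales))) {
      stop("detector failed on every frame", call. = FALSE)
    }
    list(scales = scales,
         predictions = do.call(rbind, lapply(out, `[[`, "pred")),
         evaluations = do.call(rbind,
                               Filter(Negate(is.null),
                                      lapply(out, `[[`, "evaluations"))))
  }
}

#' Rolling trace of recent predictions
#'
#' Pure function of the prediction stream: the most recent `window` frames'
#' (x, y, confidence), as displayed by the live camera-adjustment feedback
#' plot (reference window: 100).
#'
#' @param preds data frame `frame_index`, `x`, `y`, `confidence`.
#' @param window number of most recent predictions retained.
#' @return data frame: the last `min(window, n)` rows of `preds`.
#' @export
confidence_trace <- function(preds, window = 100L) {
  stopifnot(is.data.frame(preds))
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  n <- nrow(preds)
  if (n == 0L) return(preds)
  utils::tail(preds[order(preds$frame_index), , drop = FALSE], window)
}
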
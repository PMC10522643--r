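# Training-target construction: fluorescence segmentation masks, background
# compositing, stride-downsampled confidence target maps with interleaved
# loss masks, geometric/photometric augmentation, and dataset export.
# Targets and masks are the deliverable; no network is trained here.

#' Segment the speckled foreground from the background
#'
#' Union of thresholded speckle responses, morphologically closed into a
#' solid region and dilated. Used to replace the background with synthetic
#' imagery during augmentation.
#'
#' @param uv_speckle_image UV image of the speckled subject.
#' @param dilation_px outward dilation of the final mask.
#' @param closing_px closing radius that bridges gaps between speckles
#'   (should exceed half the typical speckle spacing).
#' @param threshold intensity threshold; `"otsu"` or a fixed value.
#' @return logical foreground mask.
#' @export
make_segmentation_mask <- function(uv_speckle_image, dilation_px = 2,
                                   closing_px = 15, threshold = "otsu") {
  check_image(uv_speckle_image, "uv_speckle_image")
  thr <- if (identical(threshold, "otsu")) {
    max(otsu_threshold(uv_speckle_image), 0.1)
  } else {
    threshold
  }
  mask <- uv_speckle_image >= thr
  if (!any(mask)) return(mask)
  mask <- binary_close(mask, closing_px)
  binary_dilate(mask, dilation_px)
}

#' Composite a synthetic background behind a segmented foreground
#'
#' Foreground pixels (mask TRUE) are preserved exactly; background pixels
#' are replaced by a supplied image, a constant, or seeded multi-scale
#' value noise (the "composition of several noise functions" augmentation).
#'
#' @param visible_image image whose background is replaced.
#' @param mask logical foreground mask, same size.
#' @param background a matrix of the same size, a single constant, or
#'   `"noise"` for seeded multi-scale noise.
#' @param seed seed used when `background = "noise"`.
#' @return composited image.
#' @export
composite_background <- function(visible_image, mask, background = "noise",
                                 seed = 0L) {
  check_image(visible_image)
  mask <- as_mask(mask)
  if (!all(dim(mask) == dim(visible_image))) {
    stop("mask size does not match image", call. = FALSE)
  }
  bg <- if (is.matrix(background)) {
    if (!all(dim(background) == dim(visible_image))) {
      stop("background size does not match image", call. = FALSE)
    }
    background
  } else if (is.numeric(background) && length(background) == 1L) {
    matrix(background, nrow(visible_image), ncol(visible_image))
  } else if (identical(background, "noise")) {
    value_noise(nrow(visible_image), ncol(visible_image), seed)
  } else {
    stop("background must be a matrix, a constant, or \"noise\"",
         call. = FALSE)
  }
  out <- bg
  out[mask] <- visible_image[mask]
  out
}

#' Configuration for training-target maps
#'
#' @param stride output-map downsampling factor of the detector network
#'   (reference value 8).
#' @param positive_radius_px radius, in input pixels, of the positive
#'   supervision disk around a present landmark (17 px by convention for
#'   heatmap keypoint training; configurable).
#' @param landmark_roster ordered character vector of landmark names; map
#'   order follows the roster.
#' @export
training_target_config <- function(stride = 8L, positive_radius_px = 17,
                                   landmark_roster = "landmark") {
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(stride = as.integer(stride),
                 positive_radius_px = positive_radius_px,
                 landmark_roster = as.character(landmark_roster)),
            class = "training_target_config")
}

#' Build per-landmark confidence target maps and the interleaved loss mask
#'
#' Map geometry is `ceil(image size / stride)` per side; the cell at map
#' position (i, j) (0-based) covers input pixels
#' `[j * stride, (j+1) * stride)` x likewise in y, and its center is scored
#' against the label. Semantics: a present landmark yields a positive disk
#' (cells whose centers lie within `positive_radius_px` of the label);
#' a landmark labeled *absent* yields an all-zeros map with loss mask 1
#' (the detector must learn to stay silent); a roster landmark not labeled
#' in this image at all yields loss mask 0 (interleaved training: it does
#' not contribute to the loss).
#'
#' @param labels data frame with columns `landmark` (roster name), `x`,
#'   `y`, `present`. One row per labeled landmark; roster landmarks missing
#'   from `labels` are the "not labeled here" case.
#' @param image_size `c(height, width)` in pixels.
#' @param cfg a [training_target_config()].
#' @return list with `maps` (named list of target matrices, one per roster
#'   landmark, dimension `ceil(size/stride)`), and `loss_mask` (named 0/1
#'   vector over the roster).
#' @export
make_training_targets <- function(labels, image_size,
                                  cfg = training_target_config()) {
  stopifnot(is.data.frame(labels))
  h <- image_size[1]; w <- image_size[2]
  mh <- ceiling(h / cfg$stride); mw <- ceiling(w / cfg$stride)
  centers_x <- (seq_len(mw) - 1) * cfg$stride + (cfg$stride - 1) / 2
  centers_y <- (seq_len(mh) - 1) * cfg$stride + (cfg$stride - 1) / 2
  maps <- list()
  loss_mask <- stats::setNames(numeric(length(cfg$landmark_roster)),
                               cfg$landmark_roster)
  for (nm in cfg$landmark_roster) {
    row <- labels[labels$landmark == nm, , drop = FALSE]
    m <- matrix(0, mh, mw)
    if (nrow(row) == 0L) {
      loss_mask[nm] <- 0
    } else if (!row$present[1]) {
      loss_mask[nm] <- 1
    } else {
      if (row$x[1] < 0 || row$x[1] > w - 1 || row$y[1] < 0 ||
          row$y[1] > h - 1) {
        stop("label for '", nm, "' lies outside the image", call. = FALSE)
      }
      d2 <- outer((centers_y - row$y[1])^2, (centers_x - row$x[1])^2, "+")
      m[d2 <= cfg$positive_radius_px^2] <- 1
      loss_mask[nm] <- 1
    }
    maps[[nm]] <- m
  }
  list(maps = maps, loss_mask = loss_mask)
}

#' Augmentation parameter set
#'
#' Ranges follow the reference training recipe: Gaussian blur sigma in
#' [0, 0.5], contrast scaling in [0.75, 1.5], additive Gaussian noise with
#' sigma 5% of maximum intensity, channel (here: intensity) scaling in
#' [0.8, 1.2], cropping 0-10%, affine warps with scale 0.8-1.2, rotation
#' +/-15 degrees, shear +/-8 degrees, and translation of up to 10% of the
#' image size (the reference recipe states the translation range in a different convention;
#' see the methods vignette), plus grayscale conversion with probability
#' 0.5 (a no-op on single-channel images).
#'
#' @param blur_sigma,contrast,noise_sigma,channel_scale,crop_frac,scale,
#'   rotation_deg,shear_deg,translate_frac ranges (length-2) or maxima as
#'   documented; collapse a range to a point (or set a max to 0) to disable
#'   that component.
#' @export
augment_config <- function(blur_sigma = c(0, 0.5), contrast = c(0.75, 1.5),
                           noise_sigma = 0.05, channel_scale = c(0.8, 1.2),
                           crop_frac = c(0, 0.1), scale = c(0.8, 1.2),
                           rotation_deg = c(-15, 15), shear_deg = c(-8, 8),
                           translate_frac = c(-0.1, 0.1)) {
  structure(list(blur_sigma = blur_sigma, contrast = contrast,
                 noise_sigma = noise_sigma, channel_scale = channel_scale,
                 crop_frac = crop_frac, scale = scale,
                 rotation_deg = rotation_deg, shear_deg = shear_deg,
                 translate_frac = translate_frac),
            class = "augment_config")
}

#' Identity augmentation configuration (all ranges collapsed to neutral)
#' @export
augment_config_identity <- function() {
  augment_config(blur_sigma = c(0, 0), contrast = c(1, 1), noise_sigma = 0,
                 channel_scale = c(1, 1), crop_frac = c(0, 0),
                 scale = c(1, 1), rotation_deg = c(0, 0),
                 shear_deg = c(0, 0), translate_frac = c(0, 0))
}

#' Randomly augment an image and its landmark labels consistently
#'
#' One random draw from the augmentation menu. The geometric components
#' (affine warp, crop) are applied identically to the labels; labels that
#' leave the frame become absent. Deterministic given `seed`.
#'
#' @param image single-channel matrix in [0, 1].
#' @param labels data frame with `x`, `y`, `present` (other columns
#'   preserved).
#' @param seed RNG seed.
#' @param cfg an [augment_config()].
#' @return list with `image`, `labels`, and `params` (the drawn values).
#' @export
augment_image <- function(image, labels, seed = 0L, cfg = augment_config()) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  draw <- function(r) if (length(r) == 2L) stats::runif(1, r[1], r[2]) else r
  p <- with_seed(seed, list(
    blur = draw(cfg$blur_sigma),
    contrast = draw(cfg$contrast),
    channel = draw(cfg$channel_scale),
    crop = draw(cfg$crop_frac),
    scale = draw(cfg$scale),
    rot = draw(cfg$rotation_deg) * pi / 180,
    shear = tan(draw(cfg$shear_deg) * pi / 180),
    tx = draw(cfg$translate_frac) * w,
    ty = draw(cfg$translate_frac) * h,
    noise_seed = sample.int(.Machine$integer.max, 1)
  ))
  # forward affine about the image center
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  A <- p$scale * matrix(c(cos(p$rot), sin(p$rot),
                          -sin(p$rot) + p$shear, cos(p$rot)), 2, 2)
  fwd <- function(pts) {
    t(A %*% t(sweep(pts, 2, c(cx, cy)))) +
      matrix(c(cx + p$tx, cy + p$ty), nrow(pts), 2, byrow = TRUE)
  }
  identity_geom <- isTRUE(all.equal(A, diag(2))) && p$tx == 0 && p$ty == 0
  if (identity_geom) {
    out <- image
  } else {
    Ai <- solve(A)
    xs <- rep(0:(w - 1), each = h)
    ys <- rep(0:(h - 1), w)
    q <- t(Ai %*% rbind(xs - cx - p$tx, ys - cy - p$ty))
    out <- matrix(bilinear_sample(image, q[, 1] + cx, q[, 2] + cy,
                                  outside = 0), h, w)
  }
  # crop: zero out a border band and mark labels inside it absent
  crop_px <- round(p$crop / 2 * c(h, w))
  if (any(crop_px > 0)) {
    msk <- matrix(FALSE, h, w)
    msk[seq_len(crop_px[1]), ] <- TRUE
    msk[(h - crop_px[1] + 1):h, ] <- TRUE
    msk[, seq_len(crop_px[2])] <- TRUE
    msk[, (w - crop_px[2] + 1):w] <- TRUE
    out[msk] <- 0
  }
  if (p$blur > 0) out <- gauss_blur(out, p$blur)
  out <- (out - 0.5) * p$contrast + 0.5
  out <- out * p$channel
  if (cfg$noise_sigma > 0) {
    out <- out + with_seed(p$noise_seed,
                           matrix(stats::rnorm(h * w, 0, cfg$noise_sigma),
                                  h, w))
  }
  out <- clamp(out, 0, 1)
  new_labels <- labels
  if (nrow(labels)) {
    pres <- which(labels$present)
    if (length(pres)) {
      moved <- fwd(cbind(labels$x[pres], labels$y[pres]))
      inb <- moved[, 1] >= crop_px[2] & moved[, 1] <= w - 1 - crop_px[2] &
        moved[, 2] >= crop_px[1] & moved[, 2] <= h - 1 - crop_px[1]
      new_labels$x[pres] <- ifelse(inb, moved[, 1], NA_real_)
      new_labels$y[pres] <- ifelse(inb, moved[, 2], NA_real_)
      new_labels$present[pres] <- inb
    }
  }
  list(image = out, labels = new_labels, params = p)
}

#' Export a labeled dataset (COCO keypoints JSON or per-frame CSV)
#'
#' COCO convention: each annotation stores `c(x, y, v)` per roster
#' landmark, with visibility `v = 2` for present and `v = 0` (and
#' coordinates 0, 0) for absent. Exports round-trip losslessly through
#' [read_dataset()].
#'
#' @param labels data frame with `image_id`, `landmark`, `x`, `y`,
#'   `present`.
#' @param image_sizes named list (by image id) of `c(height, width)`, or a
#'   single size shared by all images.
#' @param roster ordered landmark names.
#' @param path output file.
#' @param format `"coco_keypoints"` or `"csv"`.
#' @export
export_dataset <- function(labels, image_sizes, roster, path,
                           format = c("coco_keypoints", "csv")) {
  format <- match.arg(format)
  if (anyDuplicated(labels[, c("image_id", "landmark")])) {
    stop("duplicate (image_id, landmark) rows", call. = FALSE)
  }
  ids <- unique(labels$image_id)
  if (format == "csv") {
    df <- labels[, c("image_id", "landmark", "x", "y", "present")]
    utils::write.csv(df, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  size_of <- function(id) {
    if (is.list(image_sizes)) image_sizes[[as.character(id)]] else image_sizes
  }
  images <- lapply(seq_along(ids), function(i) {
    sz <- size_of(ids[i])
    list(id = i, file_name = as.character(ids[i]),
         height = sz[1], width = sz[2])
  })
  annotations <- lapply(seq_along(ids), function(i) {
    sub <- labels[labels$image_id == ids[i], , drop = FALSE]
    kv <- unlist(lapply(roster, function(nm) {
      row <- sub[sub$landmark == nm, , drop = FALSE]
      if (nrow(row) == 0L || !row$present[1]) c(0, 0, 0) else
        c(row$x[1], row$y[1], 2)
    }))
    list(id = i, image_id = i, category_id = 1,
         keypoints = kv, num_keypoints = sum(kv[seq(3, length(kv), 3)] > 0))
  })
  obj <- list(
    images = images,
    annotations = annotations,
    categories = list(list(id = 1, name = "subject",
                           keypoints = as.list(roster)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset exported by [export_dataset()]
#'
#' @param path file written by [export_dataset()].
#' @param format `"coco_keypoints"` or `"csv"`.
#' @return list with `labels` (data frame `image_id`, `landmark`, `x`, `y`,
#'   `present`), `roster`, and (COCO only) `image_sizes`.
#' @export
read_dataset <- function(path, format = c("coco_keypoints", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$present <- as.logical(df$present)
    return(list(labels = df, roster = unique(df$landmark)))
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  roster <- unlist(obj$categories[[1]]$keypoints)
  rows <- list()
  sizes <- list()
  for (i in seq_along(obj$images)) {
    im <- obj$images[[i]]
    an <- obj$annotations[[i]]
    kv <- unlist(an$keypoints)
    sizes[[im$file_name]] <- c(im$height, im$width)
    for (k in seq_along(roster)) {
      x <- kv[3 * k - 2]; y <- kv[3 * k - 1]; v <- kv[3 * k]
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = im$file_name, landmark = roster[k],
        x = if (v > 0) x else NA_real_, y = if (v > 0) y else NA_real_,
        present = v > 0, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  list(labels = labels, roster = roster, image_sizes = sizes)
}
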
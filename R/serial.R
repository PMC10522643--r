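# Serial labeling: one dyed landmark per recording. Each UV frame is
# thresholded into a binary dye mask, cleaned with morphological operators,
# and reduced to a centroid that labels the subsequent visible frame. Empty
# masks are first-class "absent" labels and are retained as negative
# training examples.

#' Configuration for dye-mask extraction and cleaning
#'
#' @param threshold `"otsu"` (default; the triphasic background is near-black
#'   so a histogram split is reliable) or a fixed intensity in [0, 1].
#' @param threshold_floor minimum threshold applied under `"otsu"`; guards
#'   against splitting pure background noise when no dye is in frame.
#' @param open_radius_px,close_radius_px disk radii for morphological opening
#'   (removes specks) then closing (fills small holes).
#' @param min_area_px connected components smaller than this are dropped.
#' @param max_components largest components kept after cleaning; the serial
#'   pipeline tracks a single dye region, so the default is 1.
#' @param channel for multi-channel UV frames, which channel carries the dye
#'   emission (the dye used in the reference setup emits red).
#' @return a `dye_mask_config` list.
#' @export
dye_mask_config <- function(threshold = "otsu", threshold_floor = 0.1,
                            open_radius_px = 1, close_radius_px = 2,
                            min_area_px = 20, max_components = 1,
                            channel = 1L) {
  if (is.character(threshold)) {
    threshold <- match.arg(threshold, c("otsu", "fixed"))
    if (threshold == "fixed") {
      stop("fixed thresholding requires a numeric threshold value",
           call. = FALSE)
    }
  } else if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be 'otsu' or a value in [0, 1]", call. = FALSE)
  }
  if (open_radius_px < 0 || close_radius_px < 0) {
    stop("morphology radii must be >= 0", call. = FALSE)
  }
  if (min_area_px < 1) stop("min_area_px must be >= 1", call. = FALSE)
  structure(list(threshold = threshold, threshold_floor = threshold_floor,
                 open_radius_px = open_radius_px,
                 close_radius_px = close_radius_px,
                 min_area_px = min_area_px, max_components = max_components,
                 channel = channel),
            class = "dye_mask_config")
}

#' Threshold a UV frame into a binary dye mask
#'
#' Simple thresholding suffices under triphasic illumination because the
#' background is near-black. Cleaning is a separate stage
#' ([clean_mask()]).
#'
#' @param uv_image single-channel intensity matrix in [0, 1] (3-d arrays are
#'   reduced to the configured dye-emission channel).
#' @param cfg a [dye_mask_config()].
#' @return logical matrix marking pixels at or above the threshold.
#' @export
extract_dye_mask <- function(uv_image, cfg = dye_mask_config()) {
  if (is.array(uv_image) && length(dim(uv_image)) == 3L) {
    uv_image <- uv_image[, , cfg$channel]
  }
  check_image(uv_image, "uv_image")
  thr <- if (identical(cfg$threshold, "otsu")) {
    max(otsu_threshold(uv_image), cfg$threshold_floor)
  } else {
    cfg$threshold
  }
  uv_image >= thr
}

#' Morphologically clean a dye mask
#'
#' Opening then closing with the configured disk radii, removal of
#' components below the minimum area, and retention of at most
#' `max_components` largest components. Idempotent.
#'
#' @param mask logical matrix.
#' @param cfg a [dye_mask_config()].
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, cfg = dye_mask_config()) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  mask <- binary_open(mask, cfg$open_radius_px)
  mask <- binary_close(mask, cfg$close_radius_px)
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= cfg$min_area_px)
  if (length(keep) > cfg$max_components) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(cfg$max_components)]
  }
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Centroid label of a dye mask
#'
#' Unweighted center of mass of the mask pixels, in 0-based pixel-center
#' coordinates. An empty mask yields an absent label.
#'
#' @param mask cleaned logical matrix.
#' @param frame_index frame the label belongs to.
#' @return one-row data frame with `frame_index`, `x`, `y`, `present`,
#'   `source` (a `LandmarkLabel`).
#' @export
mask_centroid <- function(mask, frame_index = 0L) {
  mask <- as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(landmark_label(frame_index, NA_real_, NA_real_, FALSE, "centroid"))
  }
  landmark_label(frame_index,
                 x = mean(idx[, "col"]) - 1,
                 y = mean(idx[, "row"]) - 1,
                 present = TRUE, source = "centroid")
}

landmark_label <- function(frame_index, x, y, present, source) {
  data.frame(frame_index = as.integer(frame_index), x = x, y = y,
             present = present, source = source, stringsAsFactors = FALSE)
}

#' Label a paired UV/visible sequence
#'
#' Runs mask extraction, cleaning and centroid computation on every UV frame
#' and attaches the label to the paired visible frame's index. Absent labels
#' are retained (they are the negative training examples). Unreadable frames
#' are recorded and processing continues.
#'
#' @param pairs data frame from [pair_frames()] (`$pairs`), or any data frame
#'   with `uv_index` and `visible_index`.
#' @param uv_frames list of UV image matrices named/indexed by `uv_index`, or
#'   a function `(uv_index) -> matrix`, or `NULL` to read from `uv_path`.
#' @param cfg a [dye_mask_config()].
#' @return a `label_track`: data frame of landmark labels (one per pair,
#'   `frame_index` = visible frame index) with attributes `width`, `height`,
#'   and `errors` (character vector of per-frame failures).
#' @export
label_sequence <- function(pairs, uv_frames, cfg = dye_mask_config()) {
  stopifnot(is.data.frame(pairs), all(c("uv_index", "visible_index") %in%
                                        names(pairs)))
  fetch <- if (is.function(uv_frames)) {
    uv_frames
  } else if (is.list(uv_frames)) {
    function(i) uv_frames[[as.character(i)]]
  } else if (is.null(uv_frames)) {
    if (is.null(pairs$uv_path)) {
      stop("uv_frames is NULL and pairs carry no uv_path", call. = FALSE)
    }
    function(i) read_image_file(pairs$uv_path[match(i, pairs$uv_index)])
  } else {
    stop("uv_frames must be a list, function, or NULL", call. = FALSE)
  }
  labels <- vector("list", nrow(pairs))
  errors <- character(0)
  wh <- NULL
  for (r in seq_len(nrow(pairs))) {
    ui <- pairs$uv_index[r]
    vi <- pairs$visible_index[r]
    img <- tryCatch(fetch(ui), error = function(e) e)
    if (inherits(img, "error") || is.null(img)) {
      errors <- c(errors, sprintf("uv frame %s: %s", ui,
                                  if (is.null(img)) "missing" else conditionMessage(img)))
      labels[[r]] <- landmark_label(vi, NA_real_, NA_real_, FALSE, "centroid")
      next
    }
    if (is.null(wh)) wh <- dim(img)
    if (!all(dim(img)[1:2] == wh[1:2])) {
      stop("all UV frames must have the same size", call. = FALSE)
    }
    mask <- clean_mask(extract_dye_mask(img, cfg), cfg)
    labels[[r]] <- mask_centroid(mask, vi)
  }
  track <- do.call(rbind, labels)
  rownames(track) <- NULL
  structure(track, width = if (is.null(wh)) NA_integer_ else wh[2],
            height = if (is.null(wh)) NA_integer_ else wh[1],
            errors = errors, class = c("label_track", "data.frame"))
}

#' Re-estimate labels at visible shutter times by temporal interpolation
#'
#' The centroid measured at the UV shutter instant is, strictly, the landmark
#' position a few milliseconds before the visible exposure. This operation
#' re-estimates each label at the visible shutter time from the neighboring
#' UV-time samples. Interpolation is off by default in the pipeline because
#' it generally does not improve final metrics at high frame rates.
#'
#' @param track a `label_track` whose rows correspond to consecutive pairs.
#' @param method `"linear"` or `"cubic"` (natural cubic spline per
#'   coordinate along time; the 1-D reading of "bicubic").
#' @param schedule `trigger_schedule` giving UV and visible shutter times;
#'   pair `i` (0-based row `i - 1`) is assumed captured in cycle `i`.
#' @param max_absent_run absent runs longer than this many frames are kept
#'   absent; shorter gaps are filled in.
#' @return a `label_track` with `source = "interpolated"` on re-estimated
#'   rows. Returned unchanged with a warning when too few present labels
#'   support the method (2 for linear, 4 for cubic).
#' @export
interpolate_track <- function(track, method = c("linear", "cubic"),
                              schedule = build_trigger_schedule(10, "triphasic", 2),
                              max_absent_run = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(track, "label_track") || is.data.frame(track))
  need <- if (method == "linear") 2L else 4L
  pres <- which(track$present)
  if (length(pres) < need) {
    warning("insufficient present labels for ", method,
            " interpolation; track returned unchanged")
    return(track)
  }
  cyc <- schedule$cycle_ms
  t_uv <- (seq_len(nrow(track)) - 1) * cyc + schedule$shutter_times_ms[1]
  t_vis <- (seq_len(nrow(track)) - 1) * cyc + schedule$shutter_times_ms[2]
  interp1 <- function(v) {
    if (method == "linear") {
      stats::approx(t_uv[pres], v[pres], xout = t_vis, rule = 2)$y
    } else {
      stats::spline(t_uv[pres], v[pres], xout = t_vis, method = "natural")$y
    }
  }
  new_x <- interp1(track$x)
  new_y <- interp1(track$y)
  # decide which frames may carry a label: present frames always; absent
  # frames only when inside a short gap between present samples
  fill_ok <- track$present
  r <- rle(!track$present)
  pos <- cumsum(c(1L, r$lengths))
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    run <- seq(pos[j], length.out = r$lengths[j])
    interior <- min(run) > min(pres) && max(run) < max(pres)
    if (interior && r$lengths[j] <= max_absent_run) fill_ok[run] <- TRUE
  }
  out <- track
  out$x[fill_ok] <- new_x[fill_ok]
  out$y[fill_ok] <- new_y[fill_ok]
  out$present <- fill_ok
  out$x[!fill_ok] <- NA_real_
  out$y[!fill_ok] <- NA_real_
  out$source[fill_ok] <- "interpolated"
  out
}

#' Read and write label tracks as CSV
#'
#' Columns `frame_index,x,y,present,source`; absent rows have empty
#' coordinates.
#' @param track a `label_track` or compatible data frame.
#' @param path CSV file path.
#' @export
write_label_track <- function(track, path) {
  df <- as.data.frame(track)[, c("frame_index", "x", "y", "present", "source")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param width,height image dimensions recorded on the returned track.
#' @rdname write_label_track
#' @export
read_label_track <- function(path, width = NA_integer_, height = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$present <- as.logical(df$present)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  structure(df, width = width, height = height, errors = character(0),
            class = c("label_track", "data.frame"))
}
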
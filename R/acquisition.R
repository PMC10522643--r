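# Acquisition model: strobed illumination/capture schedules and pairing of
# UV frames with their subsequent visible frames.
#
# The reference capture runs on a 10 ms cycle at 200 Hz: UV and visible
# illumination alternate, camera shutters fire at the midpoint of each half
# cycle (2.5 ms and 7.5 ms) with a 2 ms exposure. In the triphasic variant
# the UV source is extinguished at the first shutter trigger, so the UV image
# is captured from dye afterglow alone and background fluorescence and source
# bleed are gone.

#' Build a strobed illumination/capture schedule
#'
#' @param cycle_ms duration of one UV+visible cycle in milliseconds.
#' @param scheme `"biphasic"` (UV lit during UV capture) or `"triphasic"`
#'   (UV extinguished at the first shutter trigger; dye afterglow is imaged).
#' @param exposure_ms shutter-open duration; must be shorter than half the
#'   cycle.
#' @param uv_fraction fraction of the cycle during which the UV source is on.
#'   Under the biphasic scheme this is 0.5; under triphasic the UV interval
#'   must end at or before the first shutter trigger (0.25 of the cycle
#'   reproduces the reference timing).
#' @return an object of class `trigger_schedule` with fields `cycle_ms`,
#'   `scheme`, `uv_on`, `visible_on` (half-open intervals in ms),
#'   `shutter_times_ms` (UV then visible shutter instants, at the midpoints of
#'   the two half cycles), and `exposure_ms`.
#' @examples
#' build_trigger_schedule(10, "biphasic", 2, 0.5)
#' @export
build_trigger_schedule <- function(cycle_ms, scheme = c("biphasic", "triphasic"),
                                   exposure_ms, uv_fraction = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(cycle_ms) || cycle_ms <= 0) {
    stop("invalid schedule: cycle_ms must be positive", call. = FALSE)
  }
  if (!is.numeric(exposure_ms) || exposure_ms <= 0 ||
      exposure_ms >= cycle_ms / 2) {
    stop("invalid schedule: exposure must be shorter than half the cycle",
         call. = FALSE)
  }
  if (is.null(uv_fraction)) {
    uv_fraction <- if (scheme == "biphasic") 0.5 else 0.25
  }
  if (uv_fraction <= 0 || uv_fraction >= 1) {
    stop("invalid schedule: uv_fraction must lie in (0, 1)", call. = FALSE)
  }
  shutters <- c(cycle_ms / 4, 3 * cycle_ms / 4)
  uv_end <- uv_fraction * cycle_ms
  if (scheme == "biphasic") {
    # illumination phases split the cycle in half regardless of uv_fraction
    uv_on <- c(0, cycle_ms / 2)
  } else {
    if (uv_end > shutters[1] + 1e-9) {
      stop("invalid schedule: triphasic UV must end at or before the first ",
           "shutter trigger", call. = FALSE)
    }
    uv_on <- c(0, uv_end)
  }
  visible_on <- c(cycle_ms / 2, cycle_ms)
  # both exposures must fit inside the cycle
  if (shutters[2] + exposure_ms > cycle_ms + 1e-9) {
    stop("invalid schedule: exposure extends past end of cycle", call. = FALSE)
  }
  structure(
    list(cycle_ms = cycle_ms, scheme = scheme, uv_on = uv_on,
         visible_on = visible_on, shutter_times_ms = shutters,
         exposure_ms = exposure_ms, uv_fraction = uv_fraction),
    class = "trigger_schedule"
  )
}

#' @export
print.trigger_schedule <- function(x, ...) {
  cat(sprintf("<trigger_schedule: %s, %.3g ms cycle>\n", x$scheme, x$cycle_ms))
  cat(sprintf("  UV on      [%.3g, %.3g) ms\n", x$uv_on[1], x$uv_on[2]))
  cat(sprintf("  visible on [%.3g, %.3g) ms\n", x$visible_on[1], x$visible_on[2]))
  cat(sprintf("  shutters at %s ms, exposure %.3g ms\n",
              paste(x$shutter_times_ms, collapse = ", "), x$exposure_ms))
  invisible(x)
}

#' Offset between the visible and UV shutters of a schedule
#' @param schedule a `trigger_schedule`.
#' @return the visible-minus-UV shutter offset in ms.
#' @export
shutter_offset_ms <- function(schedule) {
  stopifnot(inherits(schedule, "trigger_schedule"))
  diff(schedule$shutter_times_ms)
}

#' Pair UV frames with their subsequent visible frames
#'
#' Each UV frame's dye centroid serves as a proxy label for the next visible
#' frame from the same camera, provided the two capture instants are no more
#' than `max_gap_ms` apart. Pairing is per camera; pairs never share a
#' visible frame. Frames that cannot be paired are returned with a reason.
#'
#' @param stream data frame with columns `index`, `timestamp_ms`,
#'   `illumination` (`"uv"` or `"visible"`), `camera_id`, and optionally
#'   `path`. Must be sorted by timestamp within each camera. If
#'   `timestamp_ms` is absent, frame indices are used in its place with a
#'   warning and the gap tolerance is not enforced.
#' @param max_gap_ms maximum allowed visible-minus-UV gap. Defaults to
#'   1.5 times the shutter offset of `schedule` when one is supplied, so a
#'   single dropped frame is detected rather than silently bridged.
#' @param schedule optional `trigger_schedule` used to derive the default
#'   tolerance.
#' @return a list with `pairs` (data frame: `uv_index`, `visible_index`,
#'   `camera_id`, `uv_timestamp_ms`, `visible_timestamp_ms`, `gap_ms`, plus
#'   `uv_path`/`visible_path` when paths are present) and `rejected`
#'   (data frame: `index`, `camera_id`, `illumination`, `reason`).
#' @examples
#' stream <- data.frame(index = 0:3, timestamp_ms = c(2.5, 7.5, 12.5, 17.5),
#'                      illumination = c("uv", "visible", "uv", "visible"),
#'                      camera_id = "cam0")
#' pair_frames(stream, max_gap_ms = 7.5)$pairs
#' @export
pair_frames <- function(stream, max_gap_ms = NULL, schedule = NULL) {
  stopifnot(is.data.frame(stream))
  empty_pairs <- data.frame(
    uv_index = integer(0), visible_index = integer(0),
    camera_id = character(0), uv_timestamp_ms = numeric(0),
    visible_timestamp_ms = numeric(0), gap_ms = numeric(0),
    stringsAsFactors = FALSE
  )
  empty_rej <- data.frame(index = integer(0), camera_id = character(0),
                          illumination = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  if (nrow(stream) == 0L) {
    return(list(pairs = empty_pairs, rejected = empty_rej))
  }
  req <- c("index", "illumination")
  if (!all(req %in% names(stream))) {
    stop("stream must have columns index and illumination", call. = FALSE)
  }
  if (!all(stream$illumination %in% c("uv", "visible"))) {
    stop("illumination must be 'uv' or 'visible'", call. = FALSE)
  }
  if (is.null(stream$camera_id)) stream$camera_id <- "cam0"
  check_gaps <- TRUE
  if (is.null(stream$timestamp_ms)) {
    warning("stream has no timestamps; using frame indices, gap checks skipped")
    stream$timestamp_ms <- as.numeric(stream$index)
    check_gaps <- FALSE
  }
  if (is.null(max_gap_ms)) {
    max_gap_ms <- if (!is.null(schedule)) 1.5 * shutter_offset_ms(schedule) else Inf
  }
  has_path <- !is.null(stream$path)

  pair_rows <- list()
  rej_rows <- list()
  for (cam in unique(stream$camera_id)) {
    sub <- stream[stream$camera_id == cam, , drop = FALSE]
    if (is.unsorted(sub$timestamp_ms, strictly = FALSE)) {
      stop("stream is not sorted by timestamp within camera ", cam,
           call. = FALSE)
    }
    pending <- NULL  # row index into sub of most recent unpaired uv frame
    for (i in seq_len(nrow(sub))) {
      if (sub$illumination[i] == "uv") {
        if (!is.null(pending)) {
          rej_rows[[length(rej_rows) + 1L]] <- data.frame(
            index = sub$index[pending], camera_id = cam,
            illumination = "uv", reason = "superseded by newer UV frame",
            stringsAsFactors = FALSE)
        }
        pending <- i
      } else {
        if (is.null(pending)) {
          rej_rows[[length(rej_rows) + 1L]] <- data.frame(
            index = sub$index[i], camera_id = cam,
            illumination = "visible", reason = "no preceding UV frame",
            stringsAsFactors = FALSE)
          next
        }
        gap <- sub$timestamp_ms[i] - sub$timestamp_ms[pending]
        if (check_gaps && gap > max_gap_ms) {
          rej_rows[[length(rej_rows) + 1L]] <- data.frame(
            index = c(sub$index[pending], sub$index[i]), camera_id = cam,
            illumination = c("uv", "visible"),
            reason = "gap exceeds tolerance", stringsAsFactors = FALSE)
          pending <- NULL
          next
        }
        row <- data.frame(
          uv_index = sub$index[pending], visible_index = sub$index[i],
          camera_id = cam, uv_timestamp_ms = sub$timestamp_ms[pending],
          visible_timestamp_ms = sub$timestamp_ms[i], gap_ms = gap,
          stringsAsFactors = FALSE)
        if (has_path) {
          row$uv_path <- sub$path[pending]
          row$visible_path <- sub$path[i]
        }
        pair_rows[[length(pair_rows) + 1L]] <- row
        pending <- NULL
      }
    }
    if (!is.null(pending)) {
      rej_rows[[length(rej_rows) + 1L]] <- data.frame(
        index = sub$index[pending], camera_id = cam, illumination = "uv",
        reason = "no following visible frame", stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pairs
  rejected <- if (length(rej_rows)) do.call(rbind, rej_rows) else empty_rej
  rownames(pairs) <- NULL
  rownames(rejected) <- NULL
  list(pairs = pairs, rejected = rejected)
}

#' Serialize a trigger schedule to YAML (or JSON fallback)
#' @param schedule a `trigger_schedule`.
#' @param path output file; `.yaml`/`.yml` requires the `yaml` package,
#'   `.json` always works.
#' @export
write_trigger_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "trigger_schedule"))
  x <- unclass(schedule)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML output requires the 'yaml' package; use .json", call. = FALSE)
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
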
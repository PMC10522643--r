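# Configuration-driven pipeline: chains simulation, pairing, serial
# labeling, interpolation and export with provenance (content-hashed
# manifest, run log, per-stage seeds derived from the master seed).

.pipeline_stage_params <- list(
  simulate_serial = c("n_frames", "size", "blob_sigma", "blob_intensity",
                      "background", "texture_amplitude", "path_from",
                      "path_to", "occluded_frames", "write_frames"),
  pair = c("max_gap_ms"),
  serial_label = c("threshold", "threshold_floor", "open_radius_px",
                   "close_radius_px", "min_area_px", "max_components"),
  interpolate = c("method", "max_absent_run"),
  export = c("format", "landmark_name")
)

#' Validate a pipeline configuration
#'
#' Unknown keys (top-level or per stage) are rejected before any stage
#' runs.
#'
#' @param config nested list: `seed`, `out_dir`, `stages` (list of blocks,
#'   each with a `stage` name and that stage's parameters).
#' @return the validated config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  known_top <- c("seed", "out_dir", "stages", "log_level")
  extra <- setdiff(names(config), known_top)
  if (length(extra)) {
    stop("config error: unknown key(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config error: out_dir is required",
                                    call. = FALSE)
  if (is.null(config$stages) || !length(config$stages)) {
    stop("config error: stages must be a nonempty list", call. = FALSE)
  }
  for (blk in config$stages) {
    nm <- blk$stage
    if (is.null(nm) || !nm %in% names(.pipeline_stage_params)) {
      stop("config error: unknown stage '", nm %||% "<missing>", "'",
           call. = FALSE)
    }
    extra <- setdiff(setdiff(names(blk), "stage"),
                     .pipeline_stage_params[[nm]])
    if (length(extra)) {
      stop("config error: unknown key(s) in stage '", nm, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline config from JSON or YAML
#' @param path `.json` (always supported) or `.yaml`/`.yml` (requires the
#'   `yaml` package).
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the 'yaml' package; use JSON", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

#' Run the serial labeling pipeline from a configuration
#'
#' Stages execute in the order given (a missing upstream artifact is a
#' config error). Every output file is listed in a manifest with its MD5
#' content hash; identical config + seed reproduce identical hashes.
#' Per-stage seeds are derived from the master seed by stable string
#' hashing, so any stage can be reproduced in isolation.
#'
#' @param config config list or path (see [read_pipeline_config()]).
#' @return list with `manifest` (data frame `file`, `md5`), `log`
#'   (character vector), and `artifacts` (in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  seed <- as.integer(config$seed %||% 0L)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  art <- list()
  files <- character(0)
  schedule <- build_trigger_schedule(10, "triphasic", 2)

  for (blk in config$stages) {
    nm <- blk$stage
    say("stage %s: start", nm)
    stage_seed <- derive_seed(seed, nm)
    res <- tryCatch(switch(
      nm,
      simulate_serial = {
        args <- blk[setdiff(names(blk), c("stage", "write_frames"))]
        args$seed <- stage_seed
        if (!is.null(args$size)) args$size <- as.integer(unlist(args$size))
        for (f in c("path_from", "path_to", "occluded_frames")) {
          if (!is.null(args[[f]])) args[[f]] <- as.numeric(unlist(args[[f]]))
        }
        spec <- do.call(serial_fixture_spec, args)
        sim <- gen_serial_sequence(spec, schedule)
        mf <- file.path(out_dir, "frames.csv")
        utils::write.csv(sim$manifest, mf, row.names = FALSE)
        files <- c(files, mf)
        if (isTRUE(blk$write_frames)) {
          fdir <- file.path(out_dir, "frames")
          dir.create(fdir, showWarnings = FALSE)
          for (t in seq_along(sim$uv_frames)) {
            fp <- file.path(fdir, sprintf("uv_%04d.pgm", t - 1L))
            write_pgm(sim$uv_frames[[t]], fp)
            files <- c(files, fp)
          }
        }
        art$simulation <- sim
        sprintf("%d frame pairs", sim$spec$n_frames)
      },
      pair = {
        if (is.null(art$simulation)) {
          stop("pair stage needs a simulate_serial stage first",
               call. = FALSE)
        }
        gap <- blk$max_gap_ms %||% (1.5 * shutter_offset_ms(schedule))
        pr <- pair_frames(art$simulation$manifest, max_gap_ms = gap)
        pf <- file.path(out_dir, "pairs.csv")
        utils::write.csv(pr$pairs, pf, row.names = FALSE)
        files <- c(files, pf)
        art$pairs <- pr
        sprintf("%d pairs, %d rejected", nrow(pr$pairs), nrow(pr$rejected))
      },
      serial_label = {
        if (is.null(art$pairs)) {
          stop("serial_label stage needs a pair stage first", call. = FALSE)
        }
        cfg_args <- blk[setdiff(names(blk), "stage")]
        cfg <- do.call(dye_mask_config, cfg_args)
        uv <- art$simulation$uv_frames
        names(uv) <- as.character(art$simulation$manifest$index[
          art$simulation$manifest$illumination == "uv"])
        track <- label_sequence(art$pairs$pairs, uv, cfg)
        tf <- file.path(out_dir, "track.csv")
        write_label_track(track, tf)
        files <- c(files, tf)
        art$track <- track
        sprintf("%d labels, %d present", nrow(track), sum(track$present))
      },
      interpolate = {
        if (is.null(art$track)) {
          stop("interpolate stage needs a serial_label stage first",
               call. = FALSE)
        }
        art$track <- interpolate_track(
          art$track, method = blk$method %||% "linear", schedule = schedule,
          max_absent_run = blk$max_absent_run %||% 2L)
        tf <- file.path(out_dir, "track_interpolated.csv")
        write_label_track(art$track, tf)
        files <- c(files, tf)
        "interpolated"
      },
      export = {
        if (is.null(art$track)) {
          stop("export stage needs labels to export", call. = FALSE)
        }
        lname <- blk$landmark_name %||% "landmark"
        labels <- data.frame(image_id = sprintf("frame_%04d",
                                                art$track$frame_index),
                             landmark = lname, x = art$track$x,
                             y = art$track$y, present = art$track$present,
                             stringsAsFactors = FALSE)
        fmt <- blk$format %||% "coco_keypoints"
        df <- file.path(out_dir,
                        if (fmt == "csv") "dataset.csv" else "dataset.json")
        sz <- c(attr(art$track, "height"), attr(art$track, "width"))
        export_dataset(labels, sz, lname, df, format = fmt)
        files <- c(files, df)
        sprintf("exported %s", basename(df))
      }
    ), error = function(e) e)
    if (inherits(res, "error")) {
      say("stage %s: FAILED (%s)", nm, conditionMessage(res))
      manifest <- data.frame(file = files,
                             md5 = unname(tools::md5sum(files)),
                             stringsAsFactors = FALSE)
      stop("pipeline aborted at stage '", nm, "': ", conditionMessage(res),
           call. = FALSE)
    }
    say("stage %s: done (%s)", nm, res)
  }
  manifest <- data.frame(file = vapply(files, function(f)
    sub(paste0("^", out_dir, "/?"), "", f), character(1)),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(out_dir, "run.log"))
  list(manifest = manifest, log = log, artifacts = art)
}
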
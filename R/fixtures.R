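# Synthetic fixtures: moving-dye serial sequences, speckle scenes under
# known warps, coherent/spurious match sets, and mock detectors. Every
# fixture ships its own analytic ground truth and is bit-reproducible under
# a fixed seed; no fixture output is ever used as its own oracle.

#' Specification for a serial moving-dye sequence
#'
#' Defaults emulate the triphasic regime: UV frames contain only the dye
#' blob over a near-black background, visible frames contain a textured
#' scene with no dye.
#'
#' @param n_frames number of UV/visible pairs.
#' @param size `c(height, width)` in pixels.
#' @param blob_sigma Gaussian radius of the rendered dye blob (px).
#' @param blob_intensity peak blob intensity in [0, 1].
#' @param background UV background level (near-black under triphasic).
#' @param texture_amplitude amplitude of UV background texture noise.
#' @param path_from,path_to endpoints of a linear motion path (0-based
#'   pixel coordinates), used when `waypoints` is `NULL`.
#' @param waypoints optional n x 2 matrix of per-frame blob centers.
#' @param occluded_frames 0-based frame (pair) indices on which the blob is
#'   absent.
#' @param seed RNG seed.
#' @return a `serial_fixture_spec` list.
#' @export
serial_fixture_spec <- function(n_frames = 50L, size = c(256L, 256L),
                                blob_sigma = 4, blob_intensity = 0.9,
                                background = 0.02, texture_amplitude = 0.01,
                                path_from = c(40, 40), path_to = c(216, 216),
                                waypoints = NULL,
                                occluded_frames = integer(0), seed = 0L) {
  if (is.null(waypoints)) {
    tt <- if (n_frames > 1) (0:(n_frames - 1)) / (n_frames - 1) else 0
    waypoints <- cbind(path_from[1] + tt * (path_to[1] - path_from[1]),
                       path_from[2] + tt * (path_to[2] - path_from[2]))
  }
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) != n_frames) {
    stop("waypoints must have one row per frame", call. = FALSE)
  }
  margin <- 3 * blob_sigma
  vis <- setdiff(seq_len(n_frames) - 1L, occluded_frames)
  inb <- waypoints[vis + 1L, , drop = FALSE]
  if (length(vis) && (any(inb[, 1] < margin) || any(inb[, 2] < margin) ||
                      any(inb[, 1] > size[2] - 1 - margin) ||
                      any(inb[, 2] > size[1] - 1 - margin))) {
    stop("blob path leaves the image on a non-occluded frame", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames), size = as.integer(size),
                 blob_sigma = blob_sigma, blob_intensity = blob_intensity,
                 background = background,
                 texture_amplitude = texture_amplitude,
                 waypoints = waypoints,
                 occluded_frames = as.integer(occluded_frames),
                 seed = as.integer(seed)),
            class = "serial_fixture_spec")
}

render_gauss_spot <- function(img, x, y, sigma, intensity) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  cs <- max(1L, floor(x) - r + 1L):min(w, ceiling(x) + r + 1L)
  rs <- max(1L, floor(y) - r + 1L):min(h, ceiling(y) + r + 1L)
  dx <- (cs - 1) - x
  dy <- (rs - 1) - y
  patch <- intensity * exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma^2))
  img[rs, cs] <- img[rs, cs] + patch
  img
}

#' Generate a serial moving-dye fixture
#'
#' @param spec a [serial_fixture_spec()].
#' @param schedule `trigger_schedule` used to stamp manifest timestamps.
#' @return list with `uv_frames` (list of matrices), `visible_frames`,
#'   `truth` (a `label_track` of planted blob centers, absent on occluded
#'   frames), `manifest` (frame manifest in the acquisition CSV schema), and
#'   `spec`.
#' @export
gen_serial_sequence <- function(spec = serial_fixture_spec(),
                                schedule = build_trigger_schedule(10, "triphasic", 2)) {
  stopifnot(inherits(spec, "serial_fixture_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  n <- spec$n_frames
  uv <- vector("list", n)
  vis <- vector("list", n)
  scene <- value_noise(h, w, derive_seed(spec$seed, "scene")) * 0.7 + 0.15
  labels <- vector("list", n)
  for (t in seq_len(n)) {
    occluded <- (t - 1L) %in% spec$occluded_frames
    tex <- value_noise(h, w, derive_seed(spec$seed, paste0("uvtex", t)),
                       scales = c(16, 8))
    frame <- matrix(spec$background, h, w) + spec$texture_amplitude * tex
    cx <- spec$waypoints[t, 1]; cy <- spec$waypoints[t, 2]
    if (!occluded) {
      frame <- render_gauss_spot(frame, cx, cy, spec$blob_sigma,
                                 spec$blob_intensity)
    }
    uv[[t]] <- clamp(frame, 0, 1)
    # visible frame: the textured scene, slightly varying illumination
    vis[[t]] <- clamp(scene * (0.9 + 0.2 * ((t - 1) %% 5) / 4), 0, 1)
    labels[[t]] <- if (occluded) {
      landmark_label(t - 1L, NA_real_, NA_real_, FALSE, "centroid")
    } else {
      landmark_label(t - 1L, cx, cy, TRUE, "centroid")
    }
  }
  truth <- do.call(rbind, labels)
  truth <- structure(truth, width = w, height = h, errors = character(0),
                     class = c("label_track", "data.frame"))
  cyc <- schedule$cycle_ms
  manifest <- data.frame(
    index = 0:(2L * n - 1L),
    timestamp_ms = rep((seq_len(n) - 1) * cyc, each = 2) +
      rep(schedule$shutter_times_ms, n),
    illumination = rep(c("uv", "visible"), n),
    camera_id = "cam0",
    stringsAsFactors = FALSE
  )
  list(uv_frames = uv, visible_frames = vis, truth = truth,
       manifest = manifest, spec = spec)
}

#' Specification for a warped speckle scene
#'
#' The base texture is a field of Gaussian spots ("speckles") confined to a
#' foreground polygon; each frame is the base texture mapped through a known
#' invertible warp, so the exact template-to-frame correspondence is
#' available analytically. Spots are rendered with smooth Gaussian profiles
#' so keypoints stay stable under resampling.
#'
#' @param size `c(height, width)`.
#' @param n_spots number of speckle spots.
#' @param spot_sigma_range,spot_intensity_range ranges for per-spot Gaussian
#'   radius (px) and peak intensity.
#' @param region_polygon n x 2 matrix (x, y vertices, 0-based) of the
#'   foreground region; default is a centered octagon.
#' @param n_frames number of warped frames.
#' @param warp_type one of `"identity"`, `"translation"`, `"affine"`,
#'   `"projective"`.
#' @param warp_params list of ranges: `translation` (max |shift| px),
#'   `rotation_deg`, `scale` (c(lo, hi)), `shear_deg`, `perspective`
#'   (max absolute perspective coefficient, in units of 1/size).
#' @param background UV background level.
#' @param seed RNG seed.
#' @return a `speckle_fixture_spec` list.
#' @export
speckle_fixture_spec <- function(size = c(256L, 256L), n_spots = 500L,
                                 spot_sigma_range = c(1.2, 2.2),
                                 spot_intensity_range = c(0.45, 1.0),
                                 region_polygon = NULL, n_frames = 3L,
                                 warp_type = c("projective", "identity",
                                               "translation", "affine"),
                                 warp_params = list(), background = 0.02,
                                 seed = 0L) {
  warp_type <- match.arg(warp_type)
  if (is.null(region_polygon)) {
    cx <- (size[2] - 1) / 2; cy <- (size[1] - 1) / 2
    ang <- seq(0, 2 * pi, length.out = 9L)[-9]
    region_polygon <- cbind(cx + 0.38 * size[2] * cos(ang),
                            cy + 0.38 * size[1] * sin(ang))
  }
  defaults <- list(translation = 12, rotation_deg = 8, scale = c(0.92, 1.08),
                   shear_deg = 4, perspective = 0.25)
  warp_params <- utils::modifyList(defaults, warp_params)
  structure(list(size = as.integer(size), n_spots = as.integer(n_spots),
                 spot_sigma_range = spot_sigma_range,
                 spot_intensity_range = spot_intensity_range,
                 region_polygon = as.matrix(region_polygon),
                 n_frames = as.integer(n_frames), warp_type = warp_type,
                 warp_params = warp_params, background = background,
                 seed = as.integer(seed)),
            class = "speckle_fixture_spec")
}

#' Point-in-polygon test (even-odd rule)
#' @keywords internal
#' @noRd
in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# sample a random warp matrix of the requested family about the image center;
# retried by the caller until the foreground stays in frame
sample_warp_matrix <- function(type, params, size) {
  cx <- (size[2] - 1) / 2; cy <- (size[1] - 1) / 2
  tr <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)
  if (type == "identity") return(diag(3))
  dx <- stats::runif(1, -params$translation, params$translation)
  dy <- stats::runif(1, -params$translation, params$translation)
  if (type == "translation") return(tr(dx, dy))
  th <- stats::runif(1, -params$rotation_deg, params$rotation_deg) * pi / 180
  sc <- stats::runif(1, params$scale[1], params$scale[2])
  sh <- tan(stats::runif(1, -params$shear_deg, params$shear_deg) * pi / 180)
  A <- sc * matrix(c(cos(th), sin(th), 0,
                     -sin(th) + sh, cos(th), 0,
                     0, 0, 1 / sc), 3, 3)
  H <- tr(cx + dx, cy + dy) %*% A %*% tr(-cx, -cy)
  if (type == "projective") {
    g <- stats::runif(1, -params$perspective, params$perspective) / max(size)
    hcoef <- stats::runif(1, -params$perspective, params$perspective) / max(size)
    P <- diag(3)
    P[3, 1] <- g; P[3, 2] <- hcoef
    H <- tr(cx, cy) %*% P %*% tr(-cx, -cy) %*% H
  }
  H / H[3, 3]
}

#' Generate a warped speckle scene with analytic correspondences
#'
#' @param spec a [speckle_fixture_spec()].
#' @return list with `base_uv` (template speckle image), `frames_uv` (list
#'   of warped frames), `warps` (list of 3 x 3 matrices mapping template
#'   coordinates to frame coordinates), `correspondence(t, pts)` (applies
#'   warp `t` to an n x 2 matrix of template points), `foreground_masks`
#'   (per-frame logical masks), `base_mask`, and `spec`. Frame `t` equals the
#'   base texture resampled through `warps[[t]]`, restricted to the warped
#'   foreground region.
#' @export
gen_speckle_scene <- function(spec = speckle_fixture_spec()) {
  stopifnot(inherits(spec, "speckle_fixture_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  poly <- spec$region_polygon
  base <- with_seed(derive_seed(spec$seed, "texture"), {
    img <- matrix(spec$background, h, w)
    placed <- 0L
    while (placed < spec$n_spots) {
      px <- stats::runif(1, 0, w - 1)
      py <- stats::runif(1, 0, h - 1)
      if (!in_polygon(px, py, poly)) next
      sg <- stats::runif(1, spec$spot_sigma_range[1], spec$spot_sigma_range[2])
      it <- stats::runif(1, spec$spot_intensity_range[1],
                         spec$spot_intensity_range[2])
      img <- render_gauss_spot(img, px, py, sg, it)
      placed <- placed + 1L
    }
    clamp(img, 0, 1)
  })
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), w)
  base_mask <- matrix(in_polygon(xs, ys, poly), h, w)

  margin <- 4
  warps <- with_seed(derive_seed(spec$seed, "warps"), {
    lapply(seq_len(spec$n_frames), function(t) {
      for (try in 1:100) {
        H <- sample_warp_matrix(spec$warp_type, spec$warp_params, spec$size)
        if (abs(det(H)) < 1e-6) next
        pv <- apply_homography(H, poly)
        if (all(pv[, 1] >= margin) && all(pv[, 1] <= w - 1 - margin) &&
            all(pv[, 2] >= margin) && all(pv[, 2] <= h - 1 - margin)) {
          return(H)
        }
      }
      stop("could not sample an in-bounds invertible warp; loosen warp_params",
           call. = FALSE)
    })
  })
  frames <- vector("list", spec$n_frames)
  fg <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    Hinv <- solve(warps[[t]])
    q <- apply_homography(Hinv, cbind(xs, ys))
    inside <- in_polygon(q[, 1], q[, 2], poly)
    vals <- rep(spec$background, length(xs))
    vals[inside] <- bilinear_sample(base, q[inside, 1], q[inside, 2],
                                    outside = spec$background)
    frames[[t]] <- matrix(vals, h, w)
    fg[[t]] <- matrix(inside, h, w)
  }
  corr <- function(t, pts) apply_homography(warps[[t]], pts)
  list(base_uv = base, frames_uv = frames, warps = warps,
       correspondence = corr, foreground_masks = fg, base_mask = base_mask,
       spec = spec)
}

#' Generate a planted coherent/spurious match configuration
#'
#' True matches are a jittered grid of left endpoints (guaranteeing every
#' true match a coherent neighbor at the reference delta/epsilon of 50 px)
#' mapped through a smooth near-isometric warp; spurious matches are
#' feature-level injections whose right endpoints are placed independently
#' of the warp. Used to measure the coherency filter's removal behavior
#' directly.
#'
#' @param n_true,n_spurious counts of planted true and spurious matches.
#' @param size extent of the left-endpoint region (px).
#' @param grid_pitch,jitter jittered-grid geometry for the true matches.
#' @param seed RNG seed.
#' @return match data frame with an extra `planted` column
#'   (`"true"`/`"spurious"`).
#' @export
gen_coherent_matches <- function(n_true = 200L, n_spurious = 20L, size = 480,
                                 grid_pitch = 30, jitter = 4, seed = 0L) {
  with_seed(seed, {
    gx <- seq(grid_pitch / 2, size - grid_pitch / 2, by = grid_pitch)
    grid <- as.matrix(expand.grid(x = gx, y = gx))
    if (nrow(grid) < n_true) {
      stop("region too small for n_true at this grid pitch", call. = FALSE)
    }
    # keep a contiguous block of grid points so neighbors stay adjacent
    ord <- order(grid[, 2], grid[, 1])
    grid <- grid[ord, , drop = FALSE][seq_len(n_true), , drop = FALSE]
    left <- grid + matrix(stats::runif(2 * n_true, -jitter, jitter), ncol = 2)
    th <- stats::runif(1, -6, 6) * pi / 180
    sc <- stats::runif(1, 0.95, 1.05)
    R <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- stats::runif(2, -20, 20)
    right <- t(R %*% t(left)) + matrix(shift, n_true, 2, byrow = TRUE)
    sp_left <- matrix(stats::runif(2 * n_spurious, 0, size), ncol = 2)
    sp_right <- matrix(stats::runif(2 * n_spurious, 0, size), ncol = 2)
    df <- data.frame(
      left_index = seq_len(n_true + n_spurious),
      right_index = seq_len(n_true + n_spurious),
      left_x = c(left[, 1], sp_left[, 1]),
      left_y = c(left[, 2], sp_left[, 2]),
      right_x = c(right[, 1], sp_right[, 1]),
      right_y = c(right[, 2], sp_right[, 2]),
      distance = 0,
      planted = rep(c("true", "spurious"), c(n_true, n_spurious)),
      stringsAsFactors = FALSE)
    # shuffle so the filter cannot rely on input order
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Specification for a mock detector
#'
#' @param truth data frame `frame_index`, `x`, `y` of true positions.
#' @param noise_sigma_px per-axis Gaussian positional noise (drawn once per
#'   frame at construction, so predictions are scale-invariant, as the
#'   back-projection contract requires).
#' @param peak_scale scale (or per-frame vector of scales) at which the
#'   confidence response is maximal.
#' @param conf_width width of the confidence response in log2-scale units.
#' @param conf_max peak confidence in [0, 1].
#' @param failure_frames frame indices on which the detector fails.
#' @param seed RNG seed.
#' @return a `mock_detector_spec` list.
#' @export
mock_detector_spec <- function(truth, noise_sigma_px = 0, peak_scale = 1,
                               conf_width = 0.35, conf_max = 0.9,
                               failure_frames = integer(0), seed = 0L) {
  stopifnot(is.data.frame(truth),
            all(c("frame_index", "x", "y") %in% names(truth)))
  if (conf_max < 0 || conf_max > 1) stop("conf_max must be in [0, 1]",
                                         call. = FALSE)
  structure(list(truth = truth, noise_sigma_px = noise_sigma_px,
                 peak_scale = peak_scale, conf_width = conf_width,
                 conf_max = conf_max,
                 failure_frames = as.integer(failure_frames),
                 seed = as.integer(seed)),
            class = "mock_detector_spec")
}

#' Instantiate a mock detector honoring the detector-adapter contract
#'
#' The returned function is called as `detector(frame, scale)` where `frame`
#' is a frame index present in the spec's truth table, and must return a
#' prediction in *original-image* coordinates: a list with `x`, `y`,
#' `confidence`, or `NULL` to signal failure.
#'
#' @param spec a [mock_detector_spec()].
#' @return a detector function.
#' @export
gen_mock_detector <- function(spec) {
  stopifnot(inherits(spec, "mock_detector_spec"))
  n <- nrow(spec$truth)
  noise <- with_seed(spec$seed, matrix(stats::rnorm(2 * n, 0,
                                                    spec$noise_sigma_px),
                                       ncol = 2))
  peaks <- rep_len(spec$peak_scale, n)
  function(frame, scale = 1) {
    i <- match(frame, spec$truth$frame_index)
    if (is.na(i)) stop("mock detector: unknown frame ", frame, call. = FALSE)
    if (frame %in% spec$failure_frames) return(NULL)
    conf <- spec$conf_max *
      exp(-(log2(scale) - log2(peaks[i]))^2 / (2 * spec$conf_width^2))
    list(x = spec$truth$x[i] + noise[i, 1],
         y = spec$truth$y[i] + noise[i, 2],
         confidence = conf)
  }
}
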
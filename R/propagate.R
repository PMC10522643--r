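# Label propagation: template matches -> training labels. Two routes:
# manual-neighborhood median pooling (a hand-drawn template region votes with
# the per-axis median of its filtered matches) and automatic-neighborhood
# propagation (spacing-constrained landmark features whose missing matches
# are recovered by a local homography fitted to neighboring matches).

#' Apply a 3 x 3 homography to points
#'
#' @param H 3 x 3 matrix mapping source to destination in homogeneous
#'   coordinates.
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  ph <- cbind(pts, 1) %*% t(H)
  cbind(ph[, 1] / ph[, 3], ph[, 2] / ph[, 3])
}

#' Fit a homography by normalized direct linear transform
#'
#' Least squares over all correspondences (no internal RANSAC: supports are
#' assumed already coherency-filtered). Hartley normalization is applied to
#' both point sets for conditioning.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 4.
#' @param degeneracy_tol ratio of the two smallest singular values of the
#'   design matrix below which the support is declared degenerate
#'   (e.g. collinear points).
#' @return 3 x 3 homography with `H[3, 3] == 1` mapping `src` to `dst`.
#' @export
fit_homography <- function(src, dst, degeneracy_tol = 1e-6) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n) {
    stop("homography requires >= 4 correspondences", call. = FALSE)
  }
  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums((p - matrix(ctr, n, 2, byrow = TRUE))^2))
    s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(T = T, p = apply_homography(T, p))
  }
  ns <- normalize(src); nd <- normalize(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)  # nv = 9: the null vector is needed even
  d <- sv$d                     # when A has only 8 rows (n = 4)
  # with >= 4 general-position points the null space is 1-dimensional; a
  # (near-)zero second-smallest singular value signals degenerate support
  if (d[8] <= degeneracy_tol * max(d[1], 1e-300)) {
    stop("degenerate correspondence geometry (collinear support?)",
         call. = FALSE)
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  H / H[3, 3]
}

#' Fit a homography with trimmed least squares
#'
#' Plain DLT, then one round of residual trimming and refit. The coherency
#' filter admits support matches inconsistent by up to delta/epsilon
#' (tens of pixels), which an untrimmed least-squares fit cannot absorb;
#' trimming drops supports whose residual exceeds
#' `max(trim_factor * median residual, trim_floor_px)` while keeping at
#' least 4 correspondences. Not RANSAC: a single deterministic refit.
#'
#' @inheritParams fit_homography
#' @param trim_factor multiple of the median residual tolerated.
#' @param trim_floor_px residual floor below which nothing is trimmed.
#' @return 3 x 3 homography matrix.
#' @export
fit_homography_trimmed <- function(src, dst, trim_factor = 3,
                                   trim_floor_px = 1) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  H <- fit_homography(src, dst)
  resid <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
  cut <- max(trim_factor * stats::median(resid), trim_floor_px)
  keep <- resid <= cut
  if (sum(keep) >= 4L && any(!keep)) {
    H <- fit_homography(src[keep, , drop = FALSE], dst[keep, , drop = FALSE])
  }
  H
}

#' Configuration for manual-neighborhood median pooling
#'
#' @param min_matches minimum filtered matches a region needs to produce a
#'   label (reference value 5).
#' @param pool_statistic only `"median"` (per-axis) is defined.
#' @export
neighborhood_label_config <- function(min_matches = 5L,
                                      pool_statistic = "median") {
  pool_statistic <- match.arg(pool_statistic, "median")
  if (min_matches < 1L) stop("min_matches must be >= 1", call. = FALSE)
  structure(list(min_matches = as.integer(min_matches),
                 pool_statistic = pool_statistic),
            class = "neighborhood_label_config")
}

#' Group matches by template region
#'
#' @param matches filtered match data frame (left endpoints on the template).
#' @param region_mask integer region-id matrix (0 = background).
#' @return named list of match data frames, one per region id present in the
#'   mask (possibly zero-row).
#' @export
group_matches_by_region <- function(matches, region_mask) {
  ids <- sort(unique(as.integer(region_mask[region_mask > 0])))
  r <- round(matches$left_y) + 1
  c <- round(matches$left_x) + 1
  inside <- r >= 1 & r <= nrow(region_mask) & c >= 1 & c <= ncol(region_mask)
  reg <- rep(0L, nrow(matches))
  reg[inside] <- as.integer(region_mask[cbind(
    pmax(r[inside], 1), pmax(c[inside], 1))])
  out <- lapply(ids, function(id) matches[reg == id, , drop = FALSE])
  names(out) <- ids
  out
}

#' Median-pool region matches into one label per region
#'
#' A region with at least `min_matches` filtered matches (pooled across all
#' templates supplying that region) is labeled at the per-axis median of the
#' right endpoints; otherwise it is recorded absent.
#'
#' @param matches_by_region named list of filtered match data frames, one
#'   entry per region; multiple templates contributing to the same region
#'   must be pooled (rbound) before calling.
#' @param cfg a [neighborhood_label_config()].
#' @param frame_index index stamped on the returned labels.
#' @return data frame `region`, `frame_index`, `x`, `y`, `present`,
#'   `n_matches`, `source`.
#' @export
pool_manual_neighborhood <- function(matches_by_region,
                                     cfg = neighborhood_label_config(),
                                     frame_index = 0L) {
  stopifnot(is.list(matches_by_region))
  rows <- lapply(names(matches_by_region), function(id) {
    m <- matches_by_region[[id]]
    n <- if (is.null(m)) 0L else nrow(m)
    if (n >= cfg$min_matches) {
      data.frame(region = id, frame_index = as.integer(frame_index),
                 x = stats::median(m$right_x), y = stats::median(m$right_y),
                 present = TRUE, n_matches = n, source = "pooled",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(region = id, frame_index = as.integer(frame_index),
                 x = NA_real_, y = NA_real_, present = FALSE, n_matches = n,
                 source = "pooled", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for automatic-neighborhood propagation
#'
#' @param min_spacing_px minimum spacing between selected landmark features
#'   (reference value 30).
#' @param neighborhood_radius_px homography support radius around each
#'   landmark, measured on the template (reference value 30).
#' @param min_neighbors minimum matched neighbors (k) needed to fit the
#'   local homography (reference value 10; values below 4 are refused since
#'   a homography needs 4 correspondences).
#' @param robust `"trim"` (default; one trimmed least-squares refit, see
#'   [fit_homography_trimmed()]) or `"none"` (plain DLT on all supports).
#' @param max_scale_px landmark candidates whose keypoint scale exceeds
#'   this are skipped (default `neighborhood_radius_px / 5`). A keypoint
#'   whose support region dwarfs its own pooling neighborhood is a
#'   composite blob, not a point-like landmark, and its match position
#'   localizes too coarsely to serve as a label; such features still
#'   participate as homography-support neighbors.
#' @param seed seed for the random candidate order of landmark selection.
#' @export
auto_landmark_config <- function(min_spacing_px = 30,
                                 neighborhood_radius_px = 30,
                                 min_neighbors = 10L,
                                 robust = c("trim", "none"),
                                 max_scale_px = neighborhood_radius_px / 5,
                                 seed = 0L) {
  robust <- match.arg(robust)
  if (min_spacing_px <= 0 || neighborhood_radius_px <= 0) {
    stop("spacing and radius must be positive", call. = FALSE)
  }
  if (min_neighbors < 4L) {
    stop("min_neighbors below 4 cannot support a homography", call. = FALSE)
  }
  structure(list(min_spacing_px = min_spacing_px,
                 neighborhood_radius_px = neighborhood_radius_px,
                 min_neighbors = as.integer(min_neighbors),
                 robust = robust, max_scale_px = max_scale_px,
                 seed = as.integer(seed)),
            class = "auto_landmark_config")
}

#' Select spaced landmark features and their support neighborhoods
#'
#' Iterates over candidate features in a seeded random order, keeping a
#' feature and discarding all remaining candidates within `min_spacing_px`.
#' The result is a maximal packing (no remaining feature could be added).
#' Each landmark's neighbor list contains every template feature (selected
#' or not, excluding itself) within `neighborhood_radius_px`.
#'
#' @param template_features `feature_set` of the template image.
#' @param cfg an [auto_landmark_config()].
#' @param region_mask optional logical/integer matrix restricting candidates
#'   to nonzero pixels.
#' @return list with `landmarks` (indices into the feature set) and
#'   `neighbors` (list of index vectors, parallel to `landmarks`).
#' @export
select_auto_landmarks <- function(template_features,
                                  cfg = auto_landmark_config(),
                                  region_mask = NULL) {
  stopifnot(inherits(template_features, "feature_set"))
  kp <- template_features$keypoints
  cand <- which(kp$scale <= cfg$max_scale_px)
  if (!is.null(region_mask) && length(cand)) {
    r <- clamp(round(kp$y[cand]) + 1, 1, nrow(region_mask))
    c <- clamp(round(kp$x[cand]) + 1, 1, ncol(region_mask))
    cand <- cand[region_mask[cbind(r, c)] != 0]
  }
  if (!length(cand)) return(list(landmarks = integer(0), neighbors = list()))
  ord <- with_seed(cfg$seed, sample(cand))
  alive <- rep(TRUE, length(ord))
  sel <- integer(0)
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    f <- ord[i]
    sel <- c(sel, f)
    d2 <- (kp$x[ord] - kp$x[f])^2 + (kp$y[ord] - kp$y[f])^2
    alive[d2 <= cfg$min_spacing_px^2] <- FALSE
  }
  sel <- sort(sel)
  r2 <- cfg$neighborhood_radius_px^2
  neigh <- lapply(sel, function(f) {
    d2 <- (kp$x - kp$x[f])^2 + (kp$y - kp$y[f])^2
    which(d2 <= r2 & seq_along(d2) != f)
  })
  list(landmarks = sel, neighbors = neigh)
}

#' Propagate one landmark feature into a target frame
#'
#' Three-way rule: (1) the landmark itself matched, its match location is
#' the label; (2) otherwise, if at least `min_neighbors` of its template
#' neighbors matched, a local homography is fitted to those neighbor
#' correspondences and the landmark position is mapped through it;
#' (3) otherwise the landmark is absent. Degenerate neighbor geometry falls
#' through to absent with a warning.
#'
#' @param landmark index of the landmark feature in the template set.
#' @param template_features `feature_set` of the template.
#' @param frame_matches filtered matches template -> target.
#' @param neighbors template feature indices within the support radius of
#'   this landmark (from [select_auto_landmarks()]).
#' @param cfg an [auto_landmark_config()].
#' @param frame_index index stamped on the returned label.
#' @param use_homography set `FALSE` for the direct-match-only ablation.
#' @return one-row label data frame (`frame_index`, `x`, `y`, `present`,
#'   `source` in `{"direct", "propagated"}`).
#' @export
propagate_landmark <- function(landmark, template_features, frame_matches,
                               neighbors, cfg = auto_landmark_config(),
                               frame_index = 0L, use_homography = TRUE) {
  kp <- template_features$keypoints
  hit <- match(landmark, frame_matches$left_index)
  if (!is.na(hit)) {
    out <- landmark_label(frame_index, frame_matches$right_x[hit],
                          frame_matches$right_y[hit], TRUE, "direct")
    return(out)
  }
  if (use_homography) {
    sup <- which(frame_matches$left_index %in% neighbors)
    if (length(sup) >= cfg$min_neighbors) {
      src <- cbind(frame_matches$left_x[sup], frame_matches$left_y[sup])
      dst <- cbind(frame_matches$right_x[sup], frame_matches$right_y[sup])
      fitter <- if (identical(cfg$robust, "none")) fit_homography else
        fit_homography_trimmed
      H <- tryCatch(fitter(src, dst), error = function(e) {
        warning("homography support degenerate for landmark ", landmark,
                "; recording absent", call. = FALSE)
        NULL
      })
      if (!is.null(H)) {
        p <- apply_homography(H, c(kp$x[landmark], kp$y[landmark]))
        return(landmark_label(frame_index, p[1], p[2], TRUE, "propagated"))
      }
    }
  }
  landmark_label(frame_index, NA_real_, NA_real_, FALSE, "propagated")
}

#' Propagate all selected landmarks into a target frame
#'
#' @param selection result of [select_auto_landmarks()].
#' @inheritParams propagate_landmark
#' @return data frame with one row per landmark (`landmark` column added).
#' @export
propagate_landmarks <- function(selection, template_features, frame_matches,
                                cfg = auto_landmark_config(),
                                frame_index = 0L, use_homography = TRUE) {
  rows <- lapply(seq_along(selection$landmarks), function(i) {
    lab <- propagate_landmark(selection$landmarks[i], template_features,
                              frame_matches, selection$neighbors[[i]], cfg,
                              frame_index, use_homography)
    cbind(data.frame(landmark = selection$landmarks[i]), lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
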